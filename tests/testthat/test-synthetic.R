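test_that("ROI generation is deterministic and has the right shape", {
  cs <- coupling_spec(n_rois = 3, noise_sd = 0.5)
  a <- generate_roi_timeseries(cs, 20, 250, seed = 42)
  b <- generate_roi_timeseries(cs, 20, 250, seed = 42)
  d <- generate_roi_timeseries(cs, 20, 250, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$data, d$data))
  expect_equal(dim(a$data), c(3L, 5000L))

  # seven minutes at the ROI-level rate of 250 Hz
  long <- generate_roi_timeseries(coupling_spec(n_rois = 2), 420, 250,
                                  seed = 1)
  expect_equal(ncol(long$data), 105000L)
  expect_equal(nrow(long$data), 2L)
})

test_that("26-ROI default labelling covers both hemispheres", {
  labs <- roi_labels_sensorimotor()
  expect_length(labs, 26L)
  expect_false(anyDuplicated(labs) > 0)
  expect_setequal(substr(labs, nchar(labs), nchar(labs)), c("L", "R"))
  cs <- coupling_spec()
  r <- generate_roi_timeseries(cs, 6, 250, seed = 1)
  expect_identical(r$roi_labels, labs)
})

test_that("noise-free signals concentrate power inside the band", {
  r <- generate_roi_timeseries(coupling_spec(n_rois = 1, noise_sd = 0),
                               20, 250, seed = 3)
  sp <- stats::spec.pgram(stats::ts(as.vector(r$data), frequency = 250),
                          plot = FALSE, taper = 0)
  frac <- sum(sp$spec[sp$freq >= 13 & sp$freq <= 30]) / sum(sp$spec)
  expect_gt(frac, 0.9)
})

test_that("lagged coupling is visible downstream, uncoupled pairs are not", {
  coupled <- coupling_spec(n_rois = 2,
                           edges = data.frame(from = 1, to = 2, gain = 0.8,
                                              lag_ms = 20),
                           noise_sd = 0.1)
  rc <- generate_roi_timeseries(coupled, 120, 250, seed = 7)
  lag_c <- lagged_coherence(cross_spectra(rc, freq_range = c(13, 30)), 1, 2)

  null_spec <- coupling_spec(n_rois = 2, noise_sd = 0.1)
  null_vals <- vapply(seq_len(50), function(s) {
    r0 <- generate_roi_timeseries(null_spec, 120, 250, seed = 1000 + s)
    lagged_coherence(cross_spectra(r0, freq_range = c(13, 30)), 1, 2)
  }, numeric(1))
  expect_gt(lag_c, stats::quantile(null_vals, 0.99))
})

test_that("coupling specifications are validated", {
  expect_error(coupling_spec(edges = data.frame(from = 1, to = 1, gain = .5,
                                                lag_ms = 10)),
               "self-coupling")
  expect_error(coupling_spec(edges = data.frame(from = 1, to = 2, gain = 1.2,
                                                lag_ms = 10)),
               "gains")
  expect_error(coupling_spec(edges = data.frame(from = 1, to = 2, gain = .5,
                                                lag_ms = 0)),
               "strictly positive")
  expect_error(coupling_spec(edges = data.frame(from = 1, to = 99, gain = .5,
                                                lag_ms = 10)),
               "1..n_rois")
  cs <- coupling_spec(n_rois = 2,
                      edges = data.frame(from = 1, to = 2, gain = .5,
                                         lag_ms = 50000))
  expect_error(generate_roi_timeseries(cs, 2, 250, seed = 1),
               "exceeds the series length")
  expect_error(generate_roi_timeseries(coupling_spec(n_rois = 2), 2, 50,
                                       seed = 1),
               "Nyquist")
})

test_that("cohort generation matches the reference-cohort defaults", {
  spec <- cohort_spec(duration_s = 8)
  coh <- generate_cohort(spec, seed = 5)
  s <- coh$subjects
  expect_equal(nrow(s), 29L)
  expect_equal(sum(s$fatigue_group == "low"), 16L)
  expect_equal(sum(s$fatigue_group == "high"), 13L)
  expect_identical(unname(classify_fatigue(s$fss7)), s$fatigue_group)
  expect_equal(as.integer(table(s$sex[s$fatigue_group == "low"])[c("male", "female")]),
               c(13L, 3L))
  expect_equal(as.integer(table(s$sex[s$fatigue_group == "high"])[c("male", "female")]),
               c(5L, 8L))
  expect_true(all(s$hads_dep <= 11))
  expect_length(coh$roi_series, 29L)
  labs <- vapply(coh$roi_series, function(r) paste(r$roi_labels, collapse = ","),
                 character(1))
  expect_length(unique(labs), 1L)
  # bit-reproducible
  coh2 <- generate_cohort(spec, seed = 5)
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$roi_series[[29]]$data, coh2$roi_series[[29]]$data)
})

test_that("degenerate FSS parameters are rejected", {
  spec <- cohort_spec(duration_s = 8,
                      fss_params = list(
                        low = list(mean = 5, sd = 0.5, range = c(4.5, 6)),
                        high = list(mean = 5.6, sd = 0.8, range = c(4.01, 7))))
  expect_error(generate_cohort(spec, seed = 1), "degenerate fss_params")
})

test_that("scalp projection mixes, upsamples and logs artifacts", {
  roi <- generate_roi_timeseries(coupling_spec(n_rois = 4, noise_sd = 0.5),
                                 12, 250, seed = 2)
  out <- project_to_scalp(roi, n_channels = 16, seed = 3,
                          channel_labels = sprintf("CH%02d", 1:16))
  expect_s3_class(out$recording, "eeg_recording")
  expect_equal(dim(out$recording$data), c(16L, 12000L))
  expect_equal(out$recording$rate_hz, 1000)
  expect_equal(nrow(out$artifact_log), 0L)

  withart <- project_to_scalp(roi, n_channels = 16, seed = 3,
                              artifact_spec = list(spike_epochs = c(2, 5),
                                                   spike_sd = 10),
                              channel_labels = sprintf("CH%02d", 1:16))
  expect_equal(withart$artifact_log$epoch, c(2L, 5L))
  expect_equal(withart$artifact_log$type, c("spike", "spike"))
  expect_error(project_to_scalp(roi, n_channels = 2, seed = 1),
               "at least the number of ROIs")
})

test_that("coupling concentration shifts the sensory small-world index monotonically", {
  # under the weight-permutation surrogate null, concentrating coupling into
  # a triad strictly lowers Sw; the mean over seeds must be strictly ordered
  gains <- c(0.25, 0.45, 0.65)
  mean_sw <- vapply(gains, function(g) {
    vals <- vapply(1:20, function(s) {
      cc <- group_coupling("low", sensory_gain = g, motor_gain = 0.25)
      roi <- generate_roi_timeseries(cc, 30, 250, seed = 9000 + s)
      mats <- assemble_networks(roi)
      small_worldness(mats$sensory_left, n_surrogates = 50,
                      seed = 100 + s)$Sw
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(mean_sw[1] > mean_sw[2] && mean_sw[2] > mean_sw[3])
})
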