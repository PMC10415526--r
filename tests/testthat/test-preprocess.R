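make_rec <- function(nch, n, rate, gen = stats::rnorm, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(gen(nch * n), nch, n), rate)
}

test_that("downsampling preserves content and counts samples correctly", {
  rec <- make_rec(2, 10000, 1000)
  dn <- downsample(rec, 250)
  expect_equal(dn$rate_hz, 250)
  expect_equal(ncol(dn$data), 2500L)

  # DC invariance
  const <- eeg_recording(matrix(3.7, 2, 4000), 1000)
  dc <- downsample(const, 250)
  expect_equal(as.vector(dc$data), rep(3.7, 2 * 1000), tolerance = 1e-6)

  # 5 Hz sinusoid survives with amplitude within 1%
  t_in <- seq(0, 10 - 1e-3, by = 1e-3)
  s <- eeg_recording(matrix(sin(2 * pi * 5 * t_in), 1), 1000)
  ds <- downsample(s, 250)
  t_out <- seq_along(ds$data[1, ]) / 250
  fit <- stats::lm(ds$data[1, ] ~ sin(2 * pi * 5 * t_out) +
                     cos(2 * pi * 5 * t_out) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_equal(amp, 1, tolerance = 0.01)

  expect_error(downsample(rec, 1000), "below the current rate")
  expect_error(downsample(rec, 1500), "below the current rate")
  expect_error(downsample(rec, 300), "divide")
})

test_that("band-pass filter passes the band and stops outside it", {
  t <- seq(0, 20 - 1 / 250, by = 1 / 250)
  rms <- function(x) sqrt(mean(x^2))
  s50 <- eeg_recording(matrix(sin(2 * pi * 50 * t), 1), 250)
  out50 <- bandpass_fir(s50, 0.1, 47)
  expect_lt(rms(out50$data), 0.1 * rms(s50$data))

  s10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), 250)
  out10 <- bandpass_fir(s10, 0.1, 47)
  mid <- 1000:4000  # central region away from edge transients
  expect_equal(rms(out10$data[1, mid]), rms(s10$data[1, mid]),
               tolerance = 0.05)

  z <- eeg_recording(matrix(0, 1, 5000), 250)
  expect_equal(max(abs(bandpass_fir(z, 0.1, 47)$data)), 0)

  expect_error(bandpass_fir(s10, 0, 47), "pass band")
  expect_error(bandpass_fir(s10, 0.1, 200), "Nyquist")
  expect_error(bandpass_fir(s10, 47, 0.1), "low < high")
})

test_that("bad-channel detection flags outlier-variance and flat channels", {
  rec <- make_rec(16, 3000, 250, seed = 11)
  expect_identical(detect_bad_channels(rec), character(0))

  noisy <- rec
  noisy$data[5, ] <- 20 * noisy$data[5, ]
  expect_identical(detect_bad_channels(noisy), "CH05")

  flat <- rec
  flat$data[9, ] <- 0
  expect_identical(detect_bad_channels(flat), "CH09")

  allflat <- eeg_recording(matrix(1, 8, 1000), 250)
  expect_error(detect_bad_channels(allflat), "unusable")
  expect_error(detect_bad_channels(make_rec(4, 100, 250)), "at least 8")
})

test_that("epoching splits recordings and discards partial epochs", {
  rec <- make_rec(2, 105000, 250, seed = 2)
  ep <- epoch_recording(rec, 2)
  expect_equal(dim(ep$data), c(210L, 2L, 500L))
  expect_equal(ep$epoch_index, 1:210)

  short <- make_rec(2, 1250, 250, seed = 3)  # 5 s
  expect_equal(dim(epoch_recording(short, 2)$data)[1], 2L)

  tiny <- make_rec(2, 475, 250, seed = 4)    # 1.9 s
  expect_error(epoch_recording(tiny, 2), "shorter than one")
  expect_error(epoch_recording(rec, 0), "positive")
  expect_error(epoch_recording(rec, -2), "positive")

  # epochs reproduce the original samples
  expect_equal(ep$data[3, 1, ], rec$data[1, 1001:1500])
})

test_that("epoch rejection removes high-amplitude epochs and keeps clean ones", {
  const <- eeg_recording(matrix(5, 3, 5000), 250)
  epc <- reject_epochs(epoch_recording(const, 2))
  expect_equal(nrow(epc$rejection_log), 0L)

  set.seed(8)
  x <- matrix(rnorm(4 * 20000), 4, 20000)
  x[, 6001:6500] <- x[, 6001:6500] + 10  # 10-SD step in all channels, epoch 13
  ep <- reject_epochs(epoch_recording(eeg_recording(x, 250), 2))
  expect_true(13L %in% ep$rejection_log$epoch)
  expect_false(13L %in% ep$epoch_index)

  # sample-wise variant also catches it
  eps <- reject_epochs(epoch_recording(eeg_recording(x, 250), 2),
                       variant = "samplewise")
  expect_true(13L %in% eps$rejection_log$epoch)

  # two identical epochs are both retained
  two <- eeg_recording(matrix(rep(sin(2 * pi * 20 * seq(0, 2 - 1 / 250, 1 / 250)), 2),
                              1, 1000, byrow = TRUE), 250)
  ept <- reject_epochs(epoch_recording(two, 2))
  expect_equal(dim(ept$data)[1], 2L)

  # the sample-wise rule on white noise rejects everything -> error
  set.seed(9)
  wn <- eeg_recording(matrix(rnorm(2 * 25000), 2, 25000), 250)
  expect_error(reject_epochs(epoch_recording(wn, 2), variant = "samplewise"),
               "all epochs rejected")
  expect_error(reject_epochs(epoch_recording(make_rec(2, 500, 250), 2)),
               "at least 2")
})

test_that("clean synthetic recordings retain at least 95% of epochs", {
  roi <- generate_roi_timeseries(coupling_spec(n_rois = 4, noise_sd = 0.5),
                                 60, 250, seed = 21)
  labels <- acticap64_labels()[1:16]
  scalp <- project_to_scalp(roi, n_channels = 16, seed = 22,
                            channel_labels = labels)
  ep <- preprocess_pipeline(scalp$recording,
                            positions = standard_1020_positions(labels))
  expect_gte(ep$log$n_epochs_retained / ep$log$n_epochs_total, 0.95)
  # and the common-average reference holds at every sample
  m <- apply(ep$data, c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-10)
})

test_that("channel interpolation reconstructs flagged channels", {
  pos <- data.frame(label = c("A", "B", "C", "D", "E"),
                    x = c(0.5, -0.5, 0, 0, 0),
                    y = c(0, 0, 0.5, -0.5, 0),
                    z = c(0.5, 0.5, 0.5, 0.5, 1))
  # no flagged channels: identity
  rec <- make_rec(3, 1000, 250, seed = 31)
  ep <- epoch_recording(rec, 2)
  expect_identical(interpolate_channels(ep, pos), ep)

  # all good channels carry an identical signal -> interpolation reproduces it
  sig <- sin(2 * pi * 7 * seq(0, 4 - 1 / 250, 1 / 250))
  shared <- eeg_recording(matrix(rep(sig, 4), 4, byrow = TRUE),
                          250, c("A", "B", "C", "D"))
  eps <- epoch_recording(shared, 2)
  eps$bad_channels <- "E"
  eps$all_labels <- c("A", "B", "C", "D", "E")
  fixed <- interpolate_channels(eps, pos, method = "spherical_spline")
  i_e <- match("E", fixed$channel_labels)
  expect_equal(as.vector(t(fixed$data[, i_e, ])), sig[1:1000],
               tolerance = 0.01)

  # inverse-distance weighting among 4 equidistant neighbours: (1,1,3,3) -> 2
  vals <- eeg_recording(matrix(c(1, 1, 3, 3), 4, 500), 250,
                        c("A", "B", "C", "D"))
  epi <- epoch_recording(vals, 2)
  epi$bad_channels <- "E"
  epi$all_labels <- c("A", "B", "C", "D", "E")
  got <- interpolate_channels(epi, pos, method = "idw")
  expect_equal(as.vector(got$data[, match("E", got$channel_labels), ]),
               rep(2, 500), tolerance = 1e-10)

  expect_error(interpolate_channels(epi, pos[1:3, ], method = "idw"),
               "missing montage positions")
})

test_that("average re-referencing annihilates the channel mean and is idempotent", {
  rec <- make_rec(6, 2000, 250, seed = 41)
  ep <- rereference_average(epoch_recording(rec, 2))
  m <- apply(ep$data, c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-12)
  again <- rereference_average(ep)
  expect_equal(again$data, ep$data, tolerance = 1e-14)

  # two channels (a, b) -> ((a-b)/2, (b-a)/2)
  ab <- eeg_recording(matrix(c(3, 1), 2, 500), 250)
  epa <- rereference_average(epoch_recording(ab, 2))
  expect_equal(as.vector(epa$data[1, 1, ]), rep(1, 500))
  expect_equal(as.vector(epa$data[1, 2, ]), rep(-1, 500))
})

test_that("the full preprocessing pipeline restores flagged channels", {
  roi <- generate_roi_timeseries(coupling_spec(n_rois = 4, noise_sd = 0.5),
                                 30, 250, seed = 51)
  labels <- acticap64_labels()[1:16]
  scalp <- project_to_scalp(roi, n_channels = 16, seed = 52,
                            channel_labels = labels)
  rec <- scalp$recording
  rec$data[3, ] <- 25 * rec$data[3, ]  # corrupt one channel
  ep <- preprocess_pipeline(rec, positions = standard_1020_positions(labels))
  expect_identical(ep$log$bad_channels, labels[3])
  expect_identical(ep$interpolated, labels[3])
  expect_equal(dim(ep$data)[2], 16L)
  expect_setequal(ep$channel_labels, labels)
})
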