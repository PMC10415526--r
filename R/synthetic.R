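# Synthetic cohort generator: band-limited, lag-coupled ROI current-density
# time series with known ground truth, plus subject metadata, so that every
# downstream stage (connectivity, graph metrics, group statistics) can be
# exercised without access to real recordings.

#' Canonical sensorimotor ROI labels
#'
#' The 26 region-of-interest labels used throughout the package: 13 Brodmann
#' areas (motor: 4, 6, 8, 9, 24, 32; sensory: 1, 2, 3, 5, 7, 40, 43) in each
#' hemisphere, formatted as \code{BA<k>_<L|R>}.
#'
#' @return Character vector of length 26.
#' @export
roi_labels_sensorimotor <- function() {
  bas <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 24, 32, 40, 43)
  c(paste0("BA", bas, "_L"), paste0("BA", bas, "_R"))
}

#' ROI time-series container
#'
#' @param data numeric matrix, ROIs x samples (current-density amplitude,
#'   arbitrary units).
#' @param rate_hz sampling rate in Hz.
#' @param roi_labels unique ROI labels; defaults to
#'   [roi_labels_sensorimotor()] for 26 rows, else \code{ROI01, ...}.
#' @return An object of class \code{roi_timeseries}.
#' @export
roi_timeseries <- function(data, rate_hz, roi_labels = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("ROI data must be finite and free of NA", call. = FALSE)
  }
  if (!is_scalar_number(rate_hz) || rate_hz <= 0) {
    stop("rate_hz must be a positive number", call. = FALSE)
  }
  if (is.null(roi_labels)) {
    roi_labels <- if (nrow(data) == 26L) roi_labels_sensorimotor()
                  else sprintf("ROI%02d", seq_len(nrow(data)))
  }
  if (length(roi_labels) != nrow(data) || anyDuplicated(roi_labels)) {
    stop("roi_labels must be unique and match the number of rows", call. = FALSE)
  }
  structure(list(data = data, rate_hz = rate_hz,
                 roi_labels = as.character(roi_labels)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d ROIs x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz))
  invisible(x)
}

#' Coupling specification for synthetic ROI signals
#'
#' Describes a set of band-limited oscillators with directed lagged coupling.
#' Each ROI is a band-limited base oscillation; a directed edge adds
#' \code{gain} times the source's base oscillation, delayed by \code{lag_ms},
#' to the target.  An optional shared zero-lag component (a common source
#' added instantaneously to every ROI) emulates volume conduction.
#'
#' @param n_rois number of ROIs (default 26).
#' @param edges \code{data.frame(from, to, gain, lag_ms)} of directed lagged
#'   couplings; \code{gain} in \[0, 1\], \code{lag_ms} strictly positive.
#'   ROI references may be indices or labels.
#' @param band frequency band in Hz of the base oscillations (default beta,
#'   13-30 Hz).
#' @param noise_sd standard deviation of independent additive white noise.
#' @param instantaneous_mix gain in \[0, 1\] of a shared zero-lag component
#'   added to all ROIs (0 disables it).
#' @param amplitude standard deviation of each base oscillation.
#' @return An object of class \code{coupling_spec}.
#' @export
coupling_spec <- function(n_rois = 26L, edges = NULL, band = c(13, 30),
                          noise_sd = 1, instantaneous_mix = 0, amplitude = 1) {
  n_rois <- as.integer(n_rois)
  stopifnot(n_rois >= 1L)
  check_band(band, what = "band")
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a nonnegative number", call. = FALSE)
  }
  if (!is_scalar_number(instantaneous_mix) ||
      instantaneous_mix < 0 || instantaneous_mix > 1) {
    stop("instantaneous_mix must lie in [0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(amplitude) || amplitude <= 0) {
    stop("amplitude must be positive", call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        gain = numeric(0), lag_ms = numeric(0))
  }
  edges <- as.data.frame(edges)
  needed <- c("from", "to", "gain", "lag_ms")
  if (!all(needed %in% names(edges))) {
    stop("edges needs columns from, to, gain, lag_ms", call. = FALSE)
  }
  if (nrow(edges)) {
    labels <- if (n_rois == 26L) roi_labels_sensorimotor()
              else sprintf("ROI%02d", seq_len(n_rois))
    resolve <- function(x) {
      if (is.numeric(x)) return(as.integer(x))
      m <- match(as.character(x), labels)
      if (anyNA(m)) stop("unknown ROI label in edges: ",
                         paste(x[is.na(m)], collapse = ", "), call. = FALSE)
      m
    }
    edges$from <- resolve(edges$from)
    edges$to <- resolve(edges$to)
    if (any(edges$from < 1L | edges$from > n_rois |
            edges$to < 1L | edges$to > n_rois)) {
      stop("edge ROI indices must lie in 1..n_rois", call. = FALSE)
    }
    if (any(edges$from == edges$to)) {
      stop("self-coupling edges are not allowed", call. = FALSE)
    }
    if (any(edges$gain < 0 | edges$gain > 1)) {
      stop("coupling gains must lie in [0, 1]", call. = FALSE)
    }
    if (any(edges$lag_ms <= 0)) {
      stop("lags of lagged edges must be strictly positive", call. = FALSE)
    }
  }
  structure(list(n_rois = n_rois, edges = edges, band = as.numeric(band),
                 noise_sd = noise_sd, instantaneous_mix = instantaneous_mix,
                 amplitude = amplitude),
            class = "coupling_spec")
}

#' Generate coupled band-limited ROI time series
#'
#' Each ROI signal is a zero-phase FIR band-limited Gaussian base oscillation,
#' plus the sum of lagged contributions from coupled ROIs, plus independent
#' white noise, plus (optionally) a shared zero-lag component.  Deterministic
#' given \code{seed}.
#'
#' @param spec a [coupling_spec()].
#' @param duration_s recording duration in seconds.
#' @param rate_hz sampling rate in Hz; must exceed twice the band's upper
#'   edge.
#' @param seed integer RNG seed.
#' @param roi_labels optional label override.
#' @return A [roi_timeseries()] with \code{n_rois} rows and
#'   \code{duration_s * rate_hz} columns.
#' @export
generate_roi_timeseries <- function(spec, duration_s, rate_hz = 250,
                                    seed = 1L, roi_labels = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (rate_hz <= 2 * spec$band[2]) {
    stop("rate_hz = ", rate_hz, " Hz is at or below the Nyquist limit for a ",
         "band reaching ", spec$band[2], " Hz", call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  lag_samp <- integer(0)
  if (nrow(spec$edges)) {
    lag_samp <- as.integer(round(spec$edges$lag_ms / 1000 * rate_hz))
    if (any(lag_samp < 1L)) {
      stop("edge lag below the sampling resolution (", 1000 / rate_hz,
           " ms)", call. = FALSE)
    }
    if (any(lag_samp >= n)) {
      stop("edge lag exceeds the series length", call. = FALSE)
    }
  }
  maxlag <- if (length(lag_samp)) max(lag_samp) else 0L
  h <- fir_design_bandpass(spec$band[1], spec$band[2], rate_hz,
                           transition_hz = 2)
  nr <- spec$n_rois
  with_seed(seed, {
    base <- bandlimited_noise(n + maxlag, nr, h)
    base <- sweep(base, 2L, apply(base, 2L, stats::sd) / spec$amplitude, "/")
    common <- NULL
    if (spec$instantaneous_mix > 0) {
      common <- bandlimited_noise(n, 1L, h)
      common <- spec$amplitude * common / stats::sd(common)
    }
    y <- base[(maxlag + 1L):(maxlag + n), , drop = FALSE]
    if (nrow(spec$edges)) {
      for (e in seq_len(nrow(spec$edges))) {
        lg <- lag_samp[e]
        contrib <- base[(maxlag + 1L - lg):(maxlag + n - lg),
                        spec$edges$from[e]]
        y[, spec$edges$to[e]] <- y[, spec$edges$to[e]] +
          spec$edges$gain[e] * contrib
      }
    }
    if (!is.null(common)) {
      y <- y + spec$instantaneous_mix * as.vector(common)
    }
    if (spec$noise_sd > 0) {
      y <- y + spec$noise_sd * matrix(stats::rnorm(n * nr), n, nr)
    }
    roi_timeseries(t(y), rate_hz, roi_labels)
  })
}

# Frozen default group coupling: the planted effect is topological (a triad
# of strong lagged edges within each target network per hemisphere), because
# the small-world index responds to the arrangement of coupling, not to its
# mean strength.  Under the degree-and-weight-preserving surrogate null a
# concentrated (clustered) triad on an otherwise diffusely coherent network
# *lowers* Sw (the path-length normalization penalty exceeds the clustering
# gain on dense coherence matrices), so the group that should exhibit the
# higher sensory small-worldness -- high fatigue -- carries the diffuse
# sensory coupling and the concentrated motor coupling, and vice versa.
swnet_effect_defaults <- function() {
  list(motor = c(low = 0.25, high = 0.65),
       sensory = c(low = 0.65, high = 0.25),
       lag_ms = 20, noise_sd = 1,
       triads = list(motor = c(4, 6, 8), sensory = c(1, 2, 3)))
}

#' Default per-group coupling specification
#'
#' Builds the frozen default [coupling_spec()] for one fatigue group: one
#' triad of strong lagged edges within the motor network and one within the
#' sensory network of each hemisphere, with gains that differ between groups
#' in a crossover pattern (high fatigue: sensory up, motor down).
#'
#' @param group \code{"low"} or \code{"high"}.
#' @param motor_gain,sensory_gain optional overrides of the triad gains.
#' @param noise_sd,lag_ms generator noise level and coupling lag.
#' @return A [coupling_spec()] for 26 ROIs.
#' @export
group_coupling <- function(group = c("low", "high"), motor_gain = NULL,
                           sensory_gain = NULL, noise_sd = NULL,
                           lag_ms = NULL) {
  group <- match.arg(group)
  def <- swnet_effect_defaults()
  motor_gain <- motor_gain %||% unname(def$motor[group])
  sensory_gain <- sensory_gain %||% unname(def$sensory[group])
  noise_sd <- noise_sd %||% def$noise_sd
  lag_ms <- lag_ms %||% def$lag_ms
  edges <- NULL
  for (hemi in c("L", "R")) {
    for (net in c("motor", "sensory")) {
      nodes <- paste0("BA", def$triads[[net]], "_", hemi)
      g <- if (net == "motor") motor_gain else sensory_gain
      tri <- data.frame(
        from = nodes[c(1, 1, 2)], to = nodes[c(2, 3, 3)],
        gain = g, lag_ms = lag_ms)
      edges <- rbind(edges, tri)
    }
  }
  coupling_spec(n_rois = 26L, edges = edges, noise_sd = noise_sd)
}

#' Cohort specification
#'
#' Reference-cohort defaults: 16 low-fatigue (13 male / 3 female) and 13
#' high-fatigue (5 male / 8 female) subjects; FSS-7 drawn from truncated
#' normals centred near the group medians (low 2.1 on \[1, 4\], high 5.6 on
#' (4, 7\]); 420 s of ROI-level signal at 250 Hz per subject.
#'
#' @param n_low,n_high group sizes (each at least 2).
#' @param sex_counts list with per-group named counts \code{c(male=, female=)}
#'   summing to the group sizes; \code{NULL} (default) uses the reference-cohort
#'   split at the default sizes and a near-balanced split otherwise.
#' @param fss_params per-group truncated-normal parameters
#'   \code{list(mean, sd, range)}; ranges must stay on the group's side of
#'   the FSS-7 > 4 threshold.
#' @param coupling list with one [coupling_spec()] per group.
#' @param duration_s,rate_hz ROI-level recording length and rate.
#' @param band analysis band propagated downstream.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_low = 16L, n_high = 13L,
                        sex_counts = NULL,
                        fss_params = list(
                          low = list(mean = 2.1, sd = 0.8, range = c(1, 4)),
                          high = list(mean = 5.6, sd = 0.8, range = c(4.01, 7))),
                        coupling = list(low = group_coupling("low"),
                                        high = group_coupling("high")),
                        duration_s = 420, rate_hz = 250, band = c(13, 30)) {
  n_low <- as.integer(n_low); n_high <- as.integer(n_high)
  if (n_low < 2L || n_high < 2L) {
    stop("each fatigue group needs at least 2 subjects", call. = FALSE)
  }
  if (is.null(sex_counts)) {
    # reference-cohort split at the default sizes, near-balanced otherwise
    sex_counts <- if (n_low == 16L && n_high == 13L) {
      list(low = c(male = 13L, female = 3L), high = c(male = 5L, female = 8L))
    } else {
      list(low = c(male = as.integer(ceiling(n_low / 2)),
                   female = as.integer(floor(n_low / 2))),
           high = c(male = as.integer(ceiling(n_high / 2)),
                    female = as.integer(floor(n_high / 2))))
    }
  }
  for (g in c("low", "high")) {
    sc <- sex_counts[[g]]
    if (is.null(sc) || !all(c("male", "female") %in% names(sc)) ||
        sum(sc) != if (g == "low") n_low else n_high) {
      stop("sex_counts$", g, " must name male and female counts summing to ",
           "the group size", call. = FALSE)
    }
    fp <- fss_params[[g]]
    if (is.null(fp$mean) || is.null(fp$sd) || is.null(fp$range)) {
      stop("fss_params$", g, " needs mean, sd and range", call. = FALSE)
    }
    if (!inherits(coupling[[g]], "coupling_spec")) {
      stop("coupling$", g, " must be a coupling_spec", call. = FALSE)
    }
  }
  if (duration_s * rate_hz < 2 * 2 * rate_hz) {
    stop("duration_s x rate_hz must yield at least two 2-s epochs",
         call. = FALSE)
  }
  structure(list(n_low = n_low, n_high = n_high, sex_counts = sex_counts,
                 fss_params = fss_params, coupling = coupling,
                 duration_s = duration_s, rate_hz = rate_hz,
                 band = as.numeric(band)),
            class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws subject metadata (FSS-7 consistent with the fatigue group, sex,
#' demographic and clinical covariates) and one ROI time series per subject
#' from the group's coupling specification.  Bit-reproducible given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return An object of class \code{cohort_dataset}: list with
#'   \code{subjects} (data.frame), \code{roi_series} (named list of
#'   [roi_timeseries()]), and \code{provenance}.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_low + spec$n_high
  with_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    group <- rep(c("low", "high"), c(spec$n_low, spec$n_high))
    sex <- c(sample(rep(c("male", "female"), spec$sex_counts$low)),
             sample(rep(c("male", "female"), spec$sex_counts$high)))
    fss <- numeric(n)
    for (g in c("low", "high")) {
      fp <- spec$fss_params[[g]]
      idx <- which(group == g)
      fss[idx] <- rtruncnorm1(length(idx), fp$mean, fp$sd, fp$range)
    }
    if (any(fss < 1 | fss > 7)) {
      stop("fss_params produced scores outside [1, 7]", call. = FALSE)
    }
    if (!identical(classify_fatigue(fss), group)) {
      stop("degenerate fss_params: drawn FSS-7 scores are inconsistent with ",
           "the FSS-7 > 4 group definition", call. = FALSE)
    }
    subjects <- data.frame(
      id = sprintf("sub-%02d", seq_len(n)),
      fss7 = round(fss, 2),
      fatigue_group = group,
      sex = sex,
      age = round(pmin(pmax(stats::rnorm(n, 62, 8), 30), 88), 1),
      grip_pct = round(pmin(pmax(stats::rnorm(n, 95, 10), 60), 130), 1),
      nhpt_pct = round(pmin(pmax(stats::rnorm(n, 90, 12), 60), 130), 1),
      hads_anx = pmin(pmax(round(stats::rnorm(n, 6, 3)), 0L), 15L),
      hads_dep = pmin(pmax(round(stats::rnorm(n, 5, 2.5)), 0L), 11L),
      hemisphere_affected = sample(c("left", "right"), n, TRUE, c(.55, .45)),
      stroke_type = sample(c("ischaemic", "haemorrhagic"), n, TRUE, c(.9, .1)),
      vascular_territory = sample(c("MCA", "PCA", "brainstem_cerebellum"),
                                  n, TRUE, c(.55, .1, .35)),
      time_post_stroke = round(exp(stats::rnorm(n, log(5.5), 0.5)), 1),
      stringsAsFactors = FALSE)
    # a few clinical notes are unretrievable, as in real cohorts
    missing_vt <- sample.int(n, max(1L, round(0.15 * n)))
    subjects$vascular_territory[missing_vt] <- NA_character_
    roi_series <- vector("list", n)
    names(roi_series) <- subjects$id
    for (i in seq_len(n)) {
      roi_series[[i]] <- generate_roi_timeseries(
        spec$coupling[[group[i]]], spec$duration_s, spec$rate_hz,
        seed = subject_seeds[i])
    }
    structure(list(subjects = subjects, roi_series = roi_series,
                   provenance = list(seed = as.integer(seed), spec = spec)),
              class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(x$subjects$fatigue_group)
  cat(sprintf("<cohort_dataset> %d subjects (low %d / high %d), %d ROIs, %g s @ %g Hz\n",
              nrow(x$subjects), tab[["low"]], tab[["high"]],
              nrow(x$roi_series[[1]]$data),
              ncol(x$roi_series[[1]]$data) / x$roi_series[[1]]$rate_hz,
              x$roi_series[[1]]$rate_hz))
  invisible(x)
}

#' Project ROI series to a synthetic scalp recording
#'
#' Mixes the ROI current-density series through a random full-rank matrix to
#' \code{n_channels} scalp channels, upsamples to \code{target_rate_hz}, adds
#' light sensor noise and, optionally, injects artifacts at known positions:
#' epoch-spanning high-amplitude steps (for epoch-rejection tests) and
#' blink-like low-frequency frontal transients.  The ground-truth artifact log
#' is returned alongside the recording.
#'
#' @param roi a [roi_timeseries()].
#' @param n_channels number of scalp channels (>= number of ROIs).
#' @param artifact_spec optional list with elements \code{spike_epochs}
#'   (integer epoch indices, 2-s epochs at the target rate),
#'   \code{spike_sd} (step amplitude in global-SD units, default 10),
#'   \code{blink_times_s} and \code{blink_sd}.
#' @param seed integer RNG seed.
#' @param target_rate_hz scalp sampling rate (default 1000).
#' @param channel_labels defaults to a standard 64-channel 10-20 montage.
#' @return list with \code{recording} (an [eeg_recording()]) and
#'   \code{artifact_log} (data.frame type, epoch, time_s, amplitude_sd).
#' @export
project_to_scalp <- function(roi, n_channels = 64L, artifact_spec = NULL,
                             seed = 1L, target_rate_hz = 1000,
                             channel_labels = NULL) {
  stopifnot(inherits(roi, "roi_timeseries"))
  nr <- nrow(roi$data)
  if (n_channels < nr) {
    stop("n_channels must be at least the number of ROIs", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels == 64L) acticap64_labels()
                      else sprintf("CH%02d", seq_len(n_channels))
  }
  up <- target_rate_hz / roi$rate_hz
  if (abs(up - round(up)) > 1e-8 || up < 1) {
    stop("target_rate_hz must be an integer multiple of the ROI rate",
         call. = FALSE)
  }
  n_in <- ncol(roi$data)
  n_out <- n_in * as.integer(round(up))
  with_seed(seed, {
    A <- matrix(stats::rnorm(n_channels * nr), n_channels, nr) / sqrt(nr)
    mixed <- A %*% roi$data  # channels x samples at ROI rate
    t_in <- (seq_len(n_in) - 1L) / roi$rate_hz
    t_out <- (seq_len(n_out) - 1L) / target_rate_hz
    data <- matrix(0, n_channels, n_out)
    for (ch in seq_len(n_channels)) {
      data[ch, ] <- stats::approx(t_in, mixed[ch, ], xout = t_out,
                                  rule = 2)$y
    }
    s_all <- stats::sd(data)
    data <- data + 0.02 * s_all * matrix(stats::rnorm(length(data)),
                                         n_channels, n_out)
    log <- data.frame(type = character(0), epoch = integer(0),
                      time_s = numeric(0), amplitude_sd = numeric(0))
    if (!is.null(artifact_spec)) {
      spe <- 2 * target_rate_hz  # 2-s epochs at scalp rate
      for (k in artifact_spec$spike_epochs %||% integer(0)) {
        amp <- (artifact_spec$spike_sd %||% 10) * s_all
        idx <- ((k - 1L) * spe + 1L):min(k * spe, n_out)
        data[, idx] <- data[, idx] + amp
        log <- rbind(log, data.frame(type = "spike", epoch = as.integer(k),
                                     time_s = (k - 1L) * 2,
                                     amplitude_sd = artifact_spec$spike_sd %||% 10))
      }
      frontal <- grep("^(Fp|AF)", channel_labels)
      if (!length(frontal)) frontal <- seq_len(min(4L, n_channels))
      for (tb in artifact_spec$blink_times_s %||% numeric(0)) {
        amp <- (artifact_spec$blink_sd %||% 8) * s_all
        dur <- round(0.4 * target_rate_hz)
        i0 <- round(tb * target_rate_hz) + 1L
        idx <- i0:min(i0 + dur - 1L, n_out)
        pulse <- amp * (0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx)))
        data[frontal, idx] <- data[frontal, idx] +
          matrix(pulse, length(frontal), length(idx), byrow = TRUE)
        log <- rbind(log, data.frame(type = "blink",
                                     epoch = as.integer(tb %/% 2 + 1L),
                                     time_s = tb,
                                     amplitude_sd = artifact_spec$blink_sd %||% 8))
      }
    }
    list(recording = eeg_recording(data, target_rate_hz, channel_labels),
         artifact_log = log)
  })
}
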