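# File formats: delimited ROI time series, subject tables, per-network
# matrices with a JSON manifest, minimal BrainVision (.vhdr/.vmrk/.eeg)
# reading and writing, and an idealized spherical 10-20 montage.

#' Write ROI time series as delimited text
#'
#' One row per sample, tab-separated, header row of ROI labels.  The
#' sampling rate is recorded in a \code{#}-prefixed comment on the first
#' line so the file round-trips losslessly.
#'
#' @param roi a [roi_timeseries()].
#' @param path output file path (.tsv).
#' @export
write_roi_series <- function(roi, path) {
  stopifnot(inherits(roi, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g", roi$rate_hz), con)
  writeLines(paste(roi$roi_labels, collapse = "\t"), con)
  utils::write.table(format(t(roi$data), digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ROI time series written by [write_roi_series()]
#'
#' @param path input file path.
#' @param rate_hz sampling rate; taken from the file's comment line when
#'   present.
#' @return A [roi_timeseries()].
#' @export
read_roi_series <- function(path, rate_hz = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("rate_hz=([0-9.]+)", first))[[1]]
    if (length(m) == 2L) rate_hz <- as.numeric(m[2])
  }
  if (is.null(rate_hz)) {
    stop("rate_hz not found in file header; pass it explicitly", call. = FALSE)
  }
  d <- utils::read.delim(path, skip = skip, check.names = FALSE)
  roi_timeseries(t(as.matrix(d)), rate_hz, colnames(d))
}

#' Write / read a cohort to a directory
#'
#' Layout: \code{subjects.csv}, \code{roi/<id>.tsv}, \code{cohort.json}
#' (seed, rate, band).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(file.path(dir, "roi"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (id in names(cohort$roi_series)) {
    write_roi_series(cohort$roi_series[[id]],
                     file.path(dir, "roi", paste0(id, ".tsv")))
  }
  jsonlite::write_json(
    list(seed = cohort$provenance$seed,
         rate_hz = cohort$roi_series[[1]]$rate_hz,
         n_subjects = nrow(cohort$subjects)),
    file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  roi_series <- lapply(subjects$id, function(id) {
    read_roi_series(file.path(dir, "roi", paste0(id, ".tsv")))
  })
  names(roi_series) <- subjects$id
  meta <- if (file.exists(file.path(dir, "cohort.json"))) {
    jsonlite::read_json(file.path(dir, "cohort.json"))
  } else list()
  structure(list(subjects = subjects, roi_series = roi_series,
                 provenance = list(seed = meta$seed, spec = NULL)),
            class = "cohort_dataset")
}

#' Write per-network connectivity matrices
#'
#' One square tab-separated matrix file per network plus a JSON manifest
#' (band, epochs used, estimator settings).
#'
#' @param mats named list of [connectivity_matrix()] objects.
#' @param dir output directory.
#' @param subject subject id used in file names.
#' @export
write_connectivity <- function(mats, dir, subject) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (nm in names(mats)) {
    m <- mats[[nm]]
    path <- file.path(dir, sprintf("%s_%s.tsv", subject, nm))
    utils::write.table(m$W, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    manifest[[nm]] <- list(file = basename(path), band = m$band,
                           n_epochs = m$n_epochs, labels = m$labels)
  }
  jsonlite::write_json(manifest,
                       file.path(dir, sprintf("%s_manifest.json", subject)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# --- BrainVision (minimal: multiplexed IEEE float32) ------------------------

#' Write a recording as a BrainVision triplet
#'
#' Minimal writer: BINARY / MULTIPLEXED / IEEE_FLOAT_32 with a bare marker
#' file.  Suitable for exchanging synthetic recordings with standard EEG
#' tooling.
#'
#' @param rec an [eeg_recording()].
#' @param basename path without extension; \code{.vhdr}, \code{.vmrk} and
#'   \code{.eeg} files are written next to it.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nch <- nrow(rec$data)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$rate_hz, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,\u00b5V", seq_len(nch), rec$channel_labels))
  writeLines(hdr, vhdr)
  writeLines(c("BrainVision Data Exchange Marker File, Version 1.0",
               "",
               "[Common Infos]",
               paste0("DataFile=", basename(eeg)),
               "",
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0"), vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L)  # channel-fastest = multiplexed
  invisible(basename)
}

#' Read a BrainVision triplet
#'
#' Supports the subset written by [write_brainvision()] (binary, multiplexed,
#' IEEE float32), which covers standard resting-state exports.
#'
#' @param vhdr path to the \code{.vhdr} header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get1 <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("missing ", key, " in header", call. = FALSE)
    sub(paste0("^", key, "="), "", hit[1])
  }
  fmt <- get1("BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  if (get1("DataOrientation") != "MULTIPLEXED") {
    stop("unsupported DataOrientation", call. = FALSE)
  }
  nch <- as.integer(get1("NumberOfChannels"))
  rate <- 1e6 / as.numeric(get1("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[[`, character(1), 1L)
  eeg <- file.path(dirname(vhdr), get1("DataFile"))
  sz <- file.info(eeg)$size
  con <- file(eeg, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = sz / 4L, size = 4L)
  eeg_recording(matrix(raw, nrow = nch), rate, labels[seq_len(nch)])
}

# --- montage ----------------------------------------------------------------

#' Standard 64-channel cap labels
#' @return Character vector of 64 labels (10-10 extension of the 10-20
#'   system; FCz and AFz are reserved for reference and ground).
#' @export
acticap64_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8")
}

#' Idealized spherical 10-20 montage positions
#'
#' Places electrodes on a unit sphere using the standard 10-20/10-10
#' construction: sagittal rows at 18-degree steps from the vertex, lateral
#' positions by spherical interpolation between the midline and the 10%%
#' outer ring.  This is the usual spherical head-model idealization, adequate
#' for interpolation weights (not an anatomical digitization).
#'
#' @param labels electrode labels (default [acticap64_labels()]).
#' @return data.frame with columns \code{label, x, y, z} (x right, y
#'   anterior, z superior).
#' @export
standard_1020_positions <- function(labels = acticap64_labels()) {
  row_alpha <- c(Fp = 72, AF = 54, F = 36, FT = 24, FC = 18, C = 0,
                 T = 0, TP = -18, CP = -18, P = -36, PO = -54, O = -72,
                 I = -90)
  parse1 <- function(lab) {
    m <- regmatches(lab, regexec("^(Fp|AF|FT|FC|TP|CP|PO|F|T|C|P|O|I)(z|[0-9]+)$",
                                 lab))[[1]]
    if (length(m) != 3L) stop("cannot parse electrode label: ", lab,
                              call. = FALSE)
    row <- m[2]; num <- m[3]
    alpha <- row_alpha[[row]]
    if (num == "z") return(c(alpha = alpha, t = 0, left = 0))
    k <- as.integer(num)
    left <- k %% 2L == 1L
    t <- switch(as.character(ceiling(k / 2)),
                "1" = 0.25, "2" = 0.5, "3" = 0.75, "4" = 1, "5" = 1.25,
                stop("electrode index out of range: ", lab, call. = FALSE))
    if (row %in% c("T", "FT", "TP")) t <- 1  # temporal row sits on the ring
    if (row %in% c("FT", "TP") && k >= 9L) t <- 1.25
    if (row %in% c("Fp", "O")) t <- -1      # marker: place along the outer ring
    if (row == "PO" && k >= 9L) t <- 1.25
    c(alpha = alpha, t = t, left = as.numeric(left))
  }
  slerp <- function(u, v, t) {
    omega <- acos(pmin(pmax(sum(u * v), -1), 1))
    if (omega < 1e-12) return(u)
    (sin((1 - t) * omega) * u + sin(t * omega) * v) / sin(omega)
  }
  pos <- t(vapply(labels, function(lab) {
    p <- parse1(lab)
    a <- p[["alpha"]] * pi / 180
    mid <- c(0, sin(a), cos(a))
    if (p[["t"]] == 0) return(mid)
    ring_phi_deg <- 90 - (p[["alpha"]] / 72) * 90
    s72 <- sin(72 * pi / 180); c72 <- cos(72 * pi / 180)
    ring <- function(phi_deg) {
      phi <- phi_deg * pi / 180
      c(-s72 * sin(phi), s72 * cos(phi), c72)
    }
    if (p[["t"]] < 0) {
      # Fp1/Fp2, O1/O2: one 10% step along the outer ring from the midline
      out <- ring(ring_phi_deg + 18 * sign(90 - ring_phi_deg))
    } else {
      out <- slerp(mid, ring(ring_phi_deg), p[["t"]])
    }
    if (p[["left"]] == 0) out[1] <- -out[1]
    out / sqrt(sum(out^2))
  }, numeric(3)))
  data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}
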