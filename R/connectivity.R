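# Band-averaged lagged linear coherence between ROI current-density series,
# assembled into per-network weighted adjacency matrices.
#
# The estimator uses only the lagged (imaginary) part of the cross-spectrum,
# which vanishes for any instantaneous (zero-lag) mixture of sources and is
# therefore insensitive to volume conduction:
#   LagR(f) = Im(S_ij)^2 / (S_ii S_jj - Re(S_ij)^2),
# averaged over the frequency bins whose centre lies inside the band.

#' Sensorimotor network definitions
#'
#' Motor networks span Brodmann areas 4, 6, 8, 9, 24 and 32 (6 nodes);
#' sensory networks span areas 1, 2, 3, 5, 7, 40 and 43 (7 nodes), in each
#' hemisphere.
#'
#' @return List of 4 definitions, each a list with \code{name}
#'   (\code{"motor"}/\code{"sensory"}), \code{hemisphere}
#'   (\code{"left"}/\code{"right"}) and \code{brodmann_areas}.
#' @export
network_definitions <- function() {
  out <- list()
  for (net in c("motor", "sensory")) {
    for (hemi in c("left", "right")) {
      out[[paste0(net, "_", hemi)]] <-
        list(name = net, hemisphere = hemi,
             brodmann_areas = if (net == "motor") c(4, 6, 8, 9, 24, 32)
                              else c(1, 2, 3, 5, 7, 40, 43))
    }
  }
  out
}

#' Epoch-averaged cross-spectral matrices
#'
#' Splits the ROI series into consecutive non-overlapping epochs, applies a
#' Hann taper after per-epoch demeaning, and averages the per-epoch discrete
#' Fourier cross-spectra (Welch-style).  With 2-s epochs the frequency
#' resolution is 0.5 Hz.
#'
#' @param roi a [roi_timeseries()] at least two epochs long.
#' @param epoch_length_s epoch length in seconds (default 2).
#' @param taper \code{"hann"} (default) or \code{"none"}.
#' @param freq_range optional \code{c(low, high)} in Hz restricting which
#'   frequency bins are computed and stored (saves time and memory when only
#'   one band is needed).
#' @return An object of class \code{cross_spectra}: complex array \code{S}
#'   (rois x rois x bins, Hermitian at every bin with real nonnegative
#'   diagonal), \code{freqs}, \code{labels}, \code{n_epochs}.
#' @export
cross_spectra <- function(roi, epoch_length_s = 2, taper = c("hann", "none"),
                          freq_range = NULL) {
  stopifnot(inherits(roi, "roi_timeseries"))
  taper <- match.arg(taper)
  spe <- round(epoch_length_s * roi$rate_hz)
  n_ep <- floor(ncol(roi$data) / spe)
  if (n_ep < 2L) {
    stop("cross-spectra need at least 2 epochs (", n_ep, " available)",
         call. = FALSE)
  }
  nr <- nrow(roi$data)
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, spe - 1) / (spe - 1))
  } else rep(1, spe)
  freqs_all <- seq(0, floor(spe / 2)) * roi$rate_hz / spe
  keep <- seq_along(freqs_all)
  if (!is.null(freq_range)) {
    keep <- which(freqs_all >= freq_range[1] - 1e-9 &
                  freqs_all <= freq_range[2] + 1e-9)
    if (!length(keep)) {
      stop("freq_range contains no frequency bins at this resolution",
           call. = FALSE)
    }
  }
  nb <- length(keep)
  # per-epoch tapered DFT coefficients: bins x rois x epochs
  X <- array(0i, c(nb, nr, n_ep))
  for (e in seq_len(n_ep)) {
    seg <- roi$data[, ((e - 1L) * spe + 1L):(e * spe), drop = FALSE]
    seg <- t(seg - rowMeans(seg)) * w
    F <- stats::mvfft(seg)
    X[, , e] <- F[keep, , drop = FALSE]
  }
  scale <- 2 / (roi$rate_hz * sum(w^2) * n_ep)
  S <- array(0i, c(nr, nr, nb))
  for (b in seq_len(nb)) {
    Xb <- matrix(X[b, , ], nrow = nr)       # rois x epochs (complex)
    M <- scale * (Xb %*% Conj(t(Xb)))
    S[, , b] <- (M + Conj(t(M))) / 2        # exactly Hermitian, real diagonal
  }
  structure(list(S = S, freqs = freqs_all[keep], labels = roi$roi_labels,
                 n_epochs = n_ep, rate_hz = roi$rate_hz,
                 epoch_length_s = epoch_length_s, taper = taper),
            class = "cross_spectra")
}

#' Band-averaged lagged linear coherence for one ROI pair
#'
#' Per frequency bin, \code{Im(S_ij)^2 / (S_ii S_jj - Re(S_ij)^2)}; the band
#' value is the arithmetic mean over bins with centre frequency inside
#' \code{band} (inclusive), clipped to \[0, 1\].  A degenerate denominator
#' (perfect instantaneous correlation, e.g. identical signals) yields 0 with
#' a warning.
#'
#' @param cs a [cross_spectra()] object.
#' @param i,j distinct ROI indices or labels.
#' @param band \code{c(low, high)} in Hz (default beta, 13-30).
#' @return Scalar weight in \[0, 1\].
#' @export
lagged_coherence <- function(cs, i, j, band = c(13, 30)) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (is.character(i)) i <- match(i, cs$labels)
  if (is.character(j)) j <- match(j, cs$labels)
  if (anyNA(c(i, j))) stop("unknown ROI label", call. = FALSE)
  if (i == j) stop("lagged coherence needs two distinct ROIs", call. = FALSE)
  bins <- which(cs$freqs >= band[1] - 1e-9 & cs$freqs <= band[2] + 1e-9)
  if (!length(bins)) {
    stop("no frequency bins inside [", band[1], ", ", band[2], "] Hz",
         call. = FALSE)
  }
  Sij <- cs$S[i, j, bins]
  Sii <- Re(cs$S[i, i, bins])
  Sjj <- Re(cs$S[j, j, bins])
  num <- Im(Sij)^2
  den <- Sii * Sjj - Re(Sij)^2
  degenerate <- !is.finite(den) | den <= .Machine$double.eps * Sii * Sjj
  val <- ifelse(degenerate, 0, num / den)
  if (any(degenerate)) {
    warning("degenerate lagged-coherence denominator (perfect instantaneous ",
            "correlation); weight set to 0", call. = FALSE)
  }
  mean(pmin(pmax(val, 0), 1))
}

#' Connectivity matrix container
#'
#' @param W symmetric nonnegative matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @param labels node labels.
#' @param band frequency band in Hz.
#' @param n_epochs epochs used by the spectral estimator.
#' @param name,hemisphere network identity (optional).
#' @return Object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(W, labels, band, n_epochs = NA_integer_,
                                name = NA_character_,
                                hemisphere = NA_character_) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("W must have a zero diagonal", call. = FALSE)
  if (any(W < 0 | W > 1)) stop("W entries must lie in [0, 1]", call. = FALSE)
  if (length(labels) != nrow(W)) stop("labels must match W", call. = FALSE)
  dimnames(W) <- list(labels, labels)
  structure(list(W = W, labels = as.character(labels),
                 band = as.numeric(band), n_epochs = as.integer(n_epochs),
                 name = name, hemisphere = hemisphere),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s/%s: %d nodes, band %g-%g Hz, %d epochs\n",
              x$name, x$hemisphere, nrow(x$W), x$band[1], x$band[2],
              x$n_epochs))
  invisible(x)
}

#' Assemble per-network lagged-coherence matrices
#'
#' Computes epoch-averaged cross-spectra once and fills one weighted
#' adjacency matrix per network definition with band-averaged lagged linear
#' coherence values.
#'
#' @param roi a [roi_timeseries()] containing every needed ROI label.
#' @param defs network definitions, see [network_definitions()].
#' @param band frequency band in Hz (default beta, 13-30).
#' @param epoch_length_s spectral epoch length (default 2 s).
#' @return Named list of [connectivity_matrix()] objects (default: motor and
#'   sensory, left and right: sizes 6, 6, 7, 7).
#' @export
assemble_networks <- function(roi, defs = network_definitions(),
                              band = c(13, 30), epoch_length_s = 2) {
  stopifnot(inherits(roi, "roi_timeseries"))
  check_band(band, nyquist = roi$rate_hz / 2, what = "band")
  cs <- cross_spectra(roi, epoch_length_s, freq_range = band)
  out <- vector("list", length(defs))
  names(out) <- names(defs)
  for (k in seq_along(defs)) {
    def <- defs[[k]]
    hemi <- toupper(substr(def$hemisphere, 1L, 1L))
    labels <- paste0("BA", def$brodmann_areas, "_", hemi)
    idx <- match(labels, cs$labels)
    if (anyNA(idx)) {
      stop("ROI label(s) missing from input: ",
           paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    n <- length(idx)
    W <- matrix(0, n, n)
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        W[a, b] <- W[b, a] <- lagged_coherence(cs, idx[a], idx[b], band)
      }
    }
    out[[k]] <- connectivity_matrix(W, labels, band, cs$n_epochs,
                                    def$name, def$hemisphere)
  }
  out
}
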