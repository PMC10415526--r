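# Weighted graph metrics with a surrogate random-network null.
#
# C_brain: mean Onnela weighted clustering coefficient on max-normalized
# weights.  L_brain: weighted characteristic path length with edge lengths
# 1/weight.  Both are normalized by the means over an ensemble of surrogate
# random networks that preserve node count, binary degree sequence
# (Maslov-Sneppen edge swaps) and the multiset of edge weights; the
# small-world index is Sw = (C_brain/C_random) / (L_brain/L_random).

validate_adjacency <- function(W, what = "W") {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop(what, " must be square", call. = FALSE)
  if (any(!is.finite(W))) stop(what, " must be finite", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10) stop(what, " must be symmetric", call. = FALSE)
  if (any(W < 0)) stop(what, " must be nonnegative", call. = FALSE)
  if (any(diag(W) != 0)) stop(what, " must have a zero diagonal", call. = FALSE)
  W
}

# connected components of the binary graph W > 0 (simple BFS)
graph_components <- function(W) {
  n <- nrow(W)
  A <- W > 0
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        nb <- which(A[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# internal fast kernels (no validation) --------------------------------------

.clustering <- function(W) {
  mx <- max(W)
  if (mx <= 0) return(0)
  Wc <- (W / mx)^(1 / 3)
  num <- diag(Wc %*% Wc %*% Wc)
  k <- rowSums(W > 0)
  Ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(Ci)
}

# all-pairs shortest path lengths by Floyd-Warshall on lengths 1/w
.pathlength <- function(W, return_matrix = FALSE) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    if (any(upd)) D[upd] <- Dk[upd]
  }
  if (return_matrix) return(D)
  off <- D[row(D) != col(D)]
  mean(off)
}

#' Mean weighted clustering coefficient
#'
#' Onnela geometric-mean formulation on weights normalized by the matrix
#' maximum: per node, the sum over neighbour pairs of the geometric mean of
#' the three triangle weights, divided by k(k-1); nodes of degree < 2
#' contribute 0.  The reported value is the mean over nodes.
#'
#' @param W symmetric nonnegative weight matrix with zero diagonal, at least
#'   3 nodes.
#' @return Scalar clustering coefficient in \[0, 1\].
#' @export
weighted_clustering <- function(W) {
  W <- validate_adjacency(W)
  if (nrow(W) < 3L) {
    stop("clustering needs at least 3 nodes (no triangles otherwise)",
         call. = FALSE)
  }
  .clustering(W)
}

#' Weighted characteristic path length
#'
#' Edge lengths are reciprocal weights (1/w); shortest path lengths between
#' all ordered pairs of distinct nodes are averaged.  A disconnected graph is
#' an error (infinite distances are never averaged silently).
#'
#' @param W symmetric nonnegative weight matrix with zero diagonal.
#' @return Scalar characteristic path length (> 0).
#' @export
weighted_path_length <- function(W) {
  W <- validate_adjacency(W)
  if (nrow(W) < 2L) stop("path length needs at least 2 nodes", call. = FALSE)
  comp <- graph_components(W)
  if (max(comp) > 1L) {
    groups <- split(seq_len(nrow(W)), comp)
    stop("graph is disconnected; components: ",
         paste(vapply(groups, function(g) paste0("{", paste(g, collapse = ","), "}"),
                      character(1)), collapse = " "), call. = FALSE)
  }
  .pathlength(W)
}

# one surrogate adjacency: Maslov-Sneppen degree-preserving rewiring of the
# binary topology plus random reassignment of the original weight multiset.
# For a complete topology no swap exists, so the surrogate reduces to a pure
# weight permutation.  Consumes the current RNG stream.
surrogate_once <- function(W, mode, ut, wts, complete_graph) {
  n <- nrow(W)
  if (mode == "weight_shuffle" || complete_graph) {
    Ws <- matrix(0, n, n)
    Ws[ut] <- sample(wts)
    return(Ws + t(Ws))
  }
  E <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(E)
  for (try in 1:5) {
    A <- W > 0
    Et <- E
    swaps <- 0L
    target <- 10L * m
    attempts <- 0L
    max_att <- 40L * target
    while (swaps < target && attempts < max_att) {
      attempts <- attempts + 1L
      pick <- sample.int(m, 2L)
      a <- Et[pick[1L], 1L]; b <- Et[pick[1L], 2L]
      cc <- Et[pick[2L], 1L]; dd <- Et[pick[2L], 2L]
      if (stats::runif(1) < 0.5) { tmp <- cc; cc <- dd; dd <- tmp }
      if (a == cc || a == dd || b == cc || b == dd) next
      if (A[a, dd] || A[cc, b]) next
      A[a, b] <- A[b, a] <- FALSE
      A[cc, dd] <- A[dd, cc] <- FALSE
      A[a, dd] <- A[dd, a] <- TRUE
      A[cc, b] <- A[b, cc] <- TRUE
      Et[pick[1L], ] <- range(c(a, dd))
      Et[pick[2L], ] <- range(c(cc, b))
      swaps <- swaps + 1L
    }
    if (swaps == 0L) return(W)  # no swap admissible; surrogate equals W
    Wb <- matrix(0, n, n)
    Wb[cbind(Et[, 1L], Et[, 2L])] <- 1
    Wb <- Wb + t(Wb)
    if (max(graph_components(Wb)) == 1L) {
      Ws <- matrix(0, n, n)
      Ws[cbind(Et[, 1L], Et[, 2L])] <- sample(wts)
      return(Ws + t(Ws))
    }
  }
  # rewiring kept disconnecting the graph: fall back to weight shuffling on
  # the original topology
  Ws <- matrix(0, n, n)
  Ws[ut] <- 0
  E0 <- which(upper.tri(W) & W > 0)
  Ws[E0] <- sample(wts)
  Ws + t(Ws)
}

#' Surrogate random-network ensemble
#'
#' Generates \code{n_surrogates} random networks that preserve the node
#' count, the binary degree sequence (via Maslov-Sneppen edge swaps) and the
#' exact multiset of edge weights (randomly reassigned to the rewired edges),
#' and returns the ensemble means of the weighted clustering coefficient and
#' characteristic path length.  On a complete topology no degree-preserving
#' swap exists, so surrogates reduce to weight permutations (this is the
#' typical regime for dense coherence matrices).  \code{"weight_shuffle"}
#' mode skips rewiring and permutes weights on the fixed original topology.
#'
#' @param W symmetric nonnegative weight matrix with zero diagonal.
#' @param n_surrogates ensemble size (default 100).
#' @param seed integer RNG seed; the ensemble is deterministic given it.
#' @param mode \code{"degree_preserving"} (default) or
#'   \code{"weight_shuffle"}.
#' @return List with \code{C_random}, \code{L_random} (ensemble means),
#'   per-surrogate vectors \code{C}, \code{L}, and the settings.
#' @export
surrogate_ensemble <- function(W, n_surrogates = 100L, seed = 1L,
                               mode = c("degree_preserving", "weight_shuffle")) {
  W <- validate_adjacency(W)
  mode <- match.arg(mode)
  stopifnot(n_surrogates >= 1L)
  n <- nrow(W)
  ut <- which(upper.tri(W))
  edge_idx <- which(upper.tri(W) & W > 0)
  wts <- W[edge_idx]
  complete_graph <- length(edge_idx) == n * (n - 1L) / 2L
  if (mode == "weight_shuffle" || complete_graph) ut <- edge_idx
  if (mode == "weight_shuffle" || complete_graph) {
    # fixed topology: surrogates are weight permutations; compiled kernel
    edges <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    res <- with_seed(seed, .surrogate_metrics_perm(W, edges - 1L,
                                                   as.integer(n_surrogates)))
    Cs <- res$C
    Ls <- res$L
  } else {
    Cs <- numeric(n_surrogates)
    Ls <- numeric(n_surrogates)
    with_seed(seed, {
      for (s in seq_len(n_surrogates)) {
        Ws <- surrogate_once(W, mode, ut, wts, complete_graph)
        Cs[s] <- .clustering(Ws)
        Ls[s] <- .pathlength(Ws)
      }
    })
  }
  list(C_random = mean(Cs), L_random = mean(Ls), C = Cs, L = Ls,
       n_surrogates = as.integer(n_surrogates), seed = as.integer(seed),
       mode = mode,
       note = if (complete_graph && mode == "degree_preserving")
         "complete topology: rewiring-invariant, weights permuted" else NULL)
}

#' Small-world index with surrogate normalization
#'
#' Computes C_brain and L_brain on the supplied network, the surrogate
#' ensemble means C_random and L_random, and the normalized ratios
#' Cw = C_brain/C_random, Lw = L_brain/L_random and Sw = Cw/Lw.  Sw near 1
#' indicates a random-like network; Sw > 1 indicates strong local clustering
#' combined with short global paths.
#'
#' @inheritParams surrogate_ensemble
#' @return An object of class \code{network_metrics} with fields
#'   \code{C_brain}, \code{L_brain}, \code{C_random}, \code{L_random},
#'   \code{Cw}, \code{Lw}, \code{Sw}, \code{n_surrogates}, \code{seed},
#'   \code{mode}.
#' @export
small_worldness <- function(W, n_surrogates = 100L, seed = 1L,
                            mode = c("degree_preserving", "weight_shuffle")) {
  if (inherits(W, "connectivity_matrix")) W <- W$W
  W <- validate_adjacency(W)
  mode <- match.arg(mode)
  C_brain <- weighted_clustering(W)
  L_brain <- weighted_path_length(W)
  ens <- surrogate_ensemble(W, n_surrogates, seed, mode)
  Cw <- C_brain / ens$C_random
  Lw <- L_brain / ens$L_random
  structure(list(C_brain = C_brain, L_brain = L_brain,
                 C_random = ens$C_random, L_random = ens$L_random,
                 Cw = Cw, Lw = Lw, Sw = Cw / Lw,
                 n_surrogates = ens$n_surrogates, seed = ens$seed,
                 mode = mode, note = ens$note),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("<network_metrics> C_brain=%.4f L_brain=%.4f ",
                     "C_random=%.4f L_random=%.4f\n  Cw=%.4f Lw=%.4f ",
                     "Sw=%.4f (%d surrogates, mode=%s)\n"),
              x$C_brain, x$L_brain, x$C_random, x$L_random,
              x$Cw, x$Lw, x$Sw, x$n_surrogates, x$mode))
  invisible(x)
}
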