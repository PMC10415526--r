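# Independent brute-force oracles and fixture builders used across tests.

# Onnela weighted clustering by explicit neighbour-pair enumeration.
oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx <= 0) return(0)
  Wn <- W / mx
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h && W[j, h] > 0) {
        s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
      }
    }
    Ci[i] <- s / (k * (k - 1))
  }
  mean(Ci)
}

# Shortest path by exhaustive simple-path enumeration (edge length 1/w).
oracle_shortest_path <- function(W, from, to) {
  n <- nrow(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  best <- Inf
  visited <- rep(FALSE, n)
  rec <- function(v, d) {
    if (v == to) {
      best <<- min(best, d)
      return()
    }
    for (w in seq_len(n)) {
      if (!visited[w] && is.finite(len[v, w])) {
        visited[w] <<- TRUE
        rec(w, d + len[v, w])
        visited[w] <<- FALSE
      }
    }
  }
  visited[from] <- TRUE
  rec(from, 0)
  best
}

oracle_pathlength <- function(W) {
  n <- nrow(W)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) tot <- tot + oracle_shortest_path(W, i, j)
  }
  tot / (n * (n - 1))
}

# random connected weighted graph on n nodes
random_connected_graph <- function(n, p = 0.6) {
  repeat {
    m <- n * (n - 1) / 2
    vals <- ifelse(stats::runif(m) < p, stats::runif(m, 0.1, 1), 0)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- vals
    W <- W + t(W)
    if (max(swnet:::graph_components(W)) == 1L && all(rowSums(W > 0) > 0)) {
      return(W)
    }
  }
}

# Classical balanced-design mixed ANOVA by cell-means sums of squares:
# between factors A (fatigue), B (sex); within factors C (network),
# D (hemisphere), all two-level; r subjects per A x B cell.
oracle_mixed_anova <- function(df) {
  df$A <- factor(df$fatigue); df$B <- factor(df$sex)
  df$C <- factor(df$network); df$D <- factor(df$hemisphere)
  N <- nrow(df)
  grand <- mean(df$y)
  facs <- c("A", "B", "C", "D")
  marg <- function(sub) {
    # marginal means over each level combo of factor subset `sub`
    if (!length(sub)) return(grand)
    tapply(df$y, df[sub], mean)
  }
  effect_ss <- list()
  for (sz in 1:4) {
    for (E in utils::combn(facs, sz, simplify = FALSE)) {
      levs <- expand.grid(lapply(E, function(f) levels(df[[f]])),
                          stringsAsFactors = FALSE)
      names(levs) <- E
      tau <- numeric(nrow(levs))
      for (r in seq_len(nrow(levs))) {
        val <- 0
        subsets <- unlist(lapply(0:length(E), function(k)
          utils::combn(E, k, simplify = FALSE)), recursive = FALSE)
        for (S in subsets) {
          mm <- marg(S)
          v <- if (!length(S)) mm else {
            do.call(`[`, c(list(mm),
                           as.list(unlist(levs[r, S, drop = FALSE]))))
          }
          val <- val + (-1)^(length(E) - length(S)) * v
        }
        tau[r] <- val
      }
      effect_ss[[paste(E, collapse = ":")]] <-
        (N / nrow(levs)) * sum(tau^2)
    }
  }
  # per-subject contrast variables (aov-metric scaling, |c|^2 = 1 except M)
  z <- do.call(rbind, lapply(split(df, df$subject), function(s) {
    s <- s[order(s$C, s$D), ]
    y <- s$y
    c(M = mean(y),
      zc = (sum(y[s$C == levels(df$C)[1]]) - sum(y[s$C == levels(df$C)[2]])) / 2,
      zd = (sum(y[s$D == levels(df$D)[1]]) - sum(y[s$D == levels(df$D)[2]])) / 2,
      zcd = (y[s$C == levels(df$C)[1] & s$D == levels(df$D)[1]] -
               y[s$C == levels(df$C)[1] & s$D == levels(df$D)[2]] -
               y[s$C == levels(df$C)[2] & s$D == levels(df$D)[1]] +
               y[s$C == levels(df$C)[2] & s$D == levels(df$D)[2]]) / 2)
  }))
  n_subj <- nrow(z)
  ss_btot <- 4 * sum((z[, "M"] - grand)^2)
  err_b <- ss_btot - effect_ss[["A"]] - effect_ss[["B"]] - effect_ss[["A:B"]]
  err_c <- sum(z[, "zc"]^2) - effect_ss[["C"]] - effect_ss[["A:C"]] -
    effect_ss[["B:C"]] - effect_ss[["A:B:C"]]
  err_d <- sum(z[, "zd"]^2) - effect_ss[["D"]] - effect_ss[["A:D"]] -
    effect_ss[["B:D"]] - effect_ss[["A:B:D"]]
  err_cd <- sum(z[, "zcd"]^2) - effect_ss[["C:D"]] - effect_ss[["A:C:D"]] -
    effect_ss[["B:C:D"]] - effect_ss[["A:B:C:D"]]
  df_err <- n_subj - 4L
  stratum_of <- function(E) {
    hasC <- "C" %in% E; hasD <- "D" %in% E
    if (hasC && hasD) err_cd else if (hasC) err_c else if (hasD) err_d
    else err_b
  }
  out <- NULL
  for (E in names(effect_ss)) {
    parts <- strsplit(E, ":")[[1]]
    err <- stratum_of(parts)
    Fv <- (effect_ss[[E]] / 1) / (err / df_err)
    out <- rbind(out, data.frame(effect = E, ss = effect_ss[[E]],
                                 F = Fv, df_den = df_err))
  }
  out
}

# balanced hand-built toy design: 8 subjects, 2 per fatigue x sex cell
toy_sw_table <- function() {
  subj <- sprintf("s%02d", 1:8)
  fatigue <- rep(c("low", "high"), each = 4)
  sex <- rep(rep(c("male", "female"), each = 2), 2)
  grid <- expand.grid(network = c("sensory", "motor"),
                      hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  vals <- c(
    1.02, 0.95, 1.00, 0.97,   # s1 low male
    1.05, 0.93, 1.01, 0.96,   # s2 low male
    0.99, 0.97, 1.03, 0.95,   # s3 low female
    1.04, 0.92, 0.98, 0.99,   # s4 low female
    1.10, 0.88, 1.06, 0.91,   # s5 high male
    1.08, 0.90, 1.09, 0.89,   # s6 high male
    1.12, 0.86, 1.05, 0.92,   # s7 high female
    1.07, 0.91, 1.11, 0.87)   # s8 high female
  out <- NULL
  k <- 0
  for (s in 1:8) {
    for (g in seq_len(nrow(grid))) {
      k <- k + 1
      out <- rbind(out, data.frame(
        subject = subj[s], fatigue_group = fatigue[s], sex = sex[s],
        network = grid$network[g], hemisphere = grid$hemisphere[g],
        Sw = vals[k], stringsAsFactors = FALSE))
    }
  }
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  out
}

# band-mean ordinary coherence, for volume-conduction contrast tests
ordinary_coherence <- function(cs, i, j, band = c(13, 30)) {
  bins <- which(cs$freqs >= band[1] - 1e-9 & cs$freqs <= band[2] + 1e-9)
  Sij <- cs$S[i, j, bins]
  mean(Mod(Sij)^2 / (Re(cs$S[i, i, bins]) * Re(cs$S[j, j, bins])))
}
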