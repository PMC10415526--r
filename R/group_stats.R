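# Group-level statistics: fatigue grouping, extreme-outlier exclusion,
# assumption checks, three-way mixed ANOVA on the small-world index
# (fatigue and sex between subjects; network and hemisphere within),
# Bonferroni post-hoc contrasts and nonparametric demographic tests.

#' Classify trait fatigue from FSS-7
#'
#' High fatigue is defined by a mean Fatigue Severity Scale (7-item) score
#' strictly greater than 4.
#'
#' @param fss7 numeric vector of FSS-7 scores in \[1, 7\].
#' @return Character vector, \code{"high"} or \code{"low"}.
#' @export
classify_fatigue <- function(fss7) {
  if (any(!is.finite(fss7)) || any(fss7 < 1 | fss7 > 7)) {
    stop("FSS-7 scores must lie in [1, 7]", call. = FALSE)
  }
  ifelse(fss7 > 4, "high", "low")
}

#' Long-format small-world table
#'
#' Joins per-subject network metrics with subject metadata into the long
#' table consumed by the statistical stage (one row per subject x network x
#' hemisphere).
#'
#' @param metrics data.frame with columns \code{subject, network, hemisphere,
#'   Sw} (e.g. from [cohort_metrics()]).
#' @param subjects data.frame with columns \code{id, fss7, fatigue_group,
#'   sex} (extra columns are carried along).
#' @return data.frame with an \code{excluded} flag (all FALSE) and empty
#'   \code{exclusion_reason}.
#' @export
sw_table <- function(metrics, subjects) {
  stopifnot(all(c("subject", "network", "hemisphere", "Sw") %in% names(metrics)))
  stopifnot(all(c("id", "fss7", "fatigue_group", "sex") %in% names(subjects)))
  if (!identical(unname(classify_fatigue(subjects$fss7)),
                 unname(subjects$fatigue_group))) {
    stop("stored fatigue_group is inconsistent with FSS-7 > 4", call. = FALSE)
  }
  out <- merge(metrics, subjects, by.x = "subject", by.y = "id",
               all.x = TRUE, sort = FALSE)
  if (any(table(out$subject) > 4L)) {
    stop("more than 4 rows per subject in the metrics table", call. = FALSE)
  }
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  out
}

#' Flag extreme outliers per design cell
#'
#' Within each network x hemisphere cell, values outside
#' \[Q1 - k IQR, Q3 + k IQR\] (default k = 3, the "extreme outlier"
#' convention) are flagged and excluded from downstream ANOVA input.
#'
#' @param sw long table from [sw_table()].
#' @param k fence multiplier (default 3).
#' @param value column to screen (default \code{"Sw"}).
#' @return \code{sw} with updated \code{excluded}/\code{exclusion_reason}.
#' @export
detect_extreme_outliers <- function(sw, k = 3, value = "Sw") {
  stopifnot(value %in% names(sw))
  cells <- interaction(sw$network, sw$hemisphere, drop = TRUE)
  for (cell in levels(cells)) {
    idx <- which(cells == cell & !sw$excluded)
    v <- sw[[value]][idx]
    if (length(v) < 4L) {
      stop("outlier screening needs at least 4 values per cell (cell ",
           cell, " has ", length(v), ")", call. = FALSE)
    }
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- v < q[1] - k * iqr | v > q[2] + k * iqr
    if (any(out)) {
      sw$excluded[idx[out]] <- TRUE
      sw$exclusion_reason[idx[out]] <-
        sprintf("extreme outlier (> %g IQR) in %s", k, cell)
    }
  }
  sw
}

#' Normality and homogeneity checks
#'
#' Shapiro-Wilk per network x hemisphere x fatigue-group cell and Levene's
#' test (Brown-Forsythe, median-centred) across fatigue x sex groups within
#' each network x hemisphere cell, on the non-excluded rows.
#'
#' @param sw long table (run [detect_extreme_outliers()] first).
#' @param alpha significance level for the pass flags (default 0.05).
#' @param value dependent-variable column (default \code{"Sw"}).
#' @return List with data.frames \code{shapiro} and \code{levene}.
#' @export
check_assumptions <- function(sw, alpha = 0.05, value = "Sw") {
  d <- sw[!sw$excluded, , drop = FALSE]
  sh <- NULL
  for (net in unique(d$network)) {
    for (hemi in unique(d$hemisphere)) {
      for (grp in unique(d$fatigue_group)) {
        v <- d[[value]][d$network == net & d$hemisphere == hemi &
                          d$fatigue_group == grp]
        row <- data.frame(network = net, hemisphere = hemi,
                          fatigue_group = grp, n = length(v),
                          W = NA_real_, p = NA_real_,
                          status = "not_assessable", pass = NA)
        if (length(v) >= 3L && stats::sd(v) > 0) {
          st <- tryCatch(stats::shapiro.test(v), error = function(e) NULL)
          if (!is.null(st)) {
            row$W <- unname(st$statistic)
            row$p <- st$p.value
            row$status <- "ok"
            row$pass <- st$p.value > alpha
          }
        }
        sh <- rbind(sh, row)
      }
    }
  }
  lv <- NULL
  for (net in unique(d$network)) {
    for (hemi in unique(d$hemisphere)) {
      sub <- d[d$network == net & d$hemisphere == hemi, , drop = FALSE]
      g <- interaction(sub$fatigue_group, sub$sex, drop = TRUE)
      row <- data.frame(network = net, hemisphere = hemi,
                        df1 = NA_integer_, df2 = NA_integer_,
                        F = NA_real_, p = NA_real_,
                        status = "not_assessable", pass = NA)
      if (nlevels(g) >= 2L && all(table(g) >= 2L)) {
        # leveneTest warns on near-perfect fits in tiny cells; the F/p are
        # still reported and flagged by the pass column
        lt <- suppressWarnings(car::leveneTest(sub[[value]], g))
        row$df1 <- lt$Df[1]; row$df2 <- lt$Df[2]
        row$F <- lt$`F value`[1]; row$p <- lt$`Pr(>F)`[1]
        row$status <- "ok"; row$pass <- lt$`Pr(>F)`[1] > alpha
      }
      lv <- rbind(lv, row)
    }
  }
  list(shapiro = sh, levene = lv, alpha = alpha)
}

#' Three-way mixed ANOVA on the small-world index
#'
#' Between-subject factors fatigue group and sex; within-subject factors
#' network (sensory/motor) and hemisphere (left/right).  Implemented by the
#' exact contrast decomposition for 2 x 2 within designs: per subject the
#' cell mean, the network difference, the hemisphere difference and their
#' interaction are analysed in four Type-III linear models (sum-to-zero
#' contrasts), which reproduces the classical mixed-model F tests.  With
#' two-level within factors sphericity holds trivially (Greenhouse-Geisser
#' epsilon = 1), so adjusted and unadjusted p-values coincide.  Effect sizes
#' are generalized eta-squared.  Subjects with missing cells are dropped
#' listwise.
#'
#' @param sw long table from [sw_table()] (excluded rows are ignored).
#' @param value dependent-variable column (default \code{"Sw"}).
#' @return An object of class \code{sw_anova}: data.frame with one row per
#'   effect (\code{effect, df_num, df_den, F, p, p_gg, epsilon, ges}) plus
#'   attributes \code{n_subjects} and \code{dropped}.
#' @export
mixed_anova <- function(sw, value = "Sw") {
  d <- sw[!sw$excluded, , drop = FALSE]
  d$cell <- paste(d$network, d$hemisphere, sep = ".")
  wide <- stats::reshape(
    d[, c("subject", "cell", value)], idvar = "subject",
    timevar = "cell", direction = "wide")
  cells <- c("sensory.left", "sensory.right", "motor.left", "motor.right")
  cols <- paste(value, cells, sep = ".")
  if (!all(cols %in% names(wide))) {
    stop("long table must contain sensory/motor x left/right cells",
         call. = FALSE)
  }
  complete <- stats::complete.cases(wide[, cols])
  dropped <- wide$subject[!complete]
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  meta <- d[!duplicated(d$subject), c("subject", "fatigue_group", "sex")]
  meta <- meta[match(wide$subject, meta$subject), ]
  fatigue <- factor(meta$fatigue_group, levels = c("low", "high"))
  sex <- factor(meta$sex, levels = c("male", "female"))
  if (nlevels(droplevels(fatigue)) < 2L || nlevels(droplevels(sex)) < 2L) {
    stop("both between-subject factors need 2 observed levels", call. = FALSE)
  }
  if (any(table(fatigue, sex) < 2L)) {
    stop("every fatigue x sex cell needs at least 2 subjects", call. = FALSE)
  }
  sL <- wide[[cols[1]]]; sR <- wide[[cols[2]]]
  mL <- wide[[cols[3]]]; mR <- wide[[cols[4]]]
  responses <- list(
    between = (sL + sR + mL + mR) / 4,           # |c|^2 = 1/4
    network = (sL + sR - mL - mR) / 2,           # sensory - motor, |c|^2 = 1
    hemisphere = (sL + mL - sR - mR) / 2,        # left - right,    |c|^2 = 1
    net_hemi = (sL - sR - mL + mR) / 2)          # interaction,     |c|^2 = 1
  ss_scale <- c(between = 4, network = 1, hemisphere = 1, net_hemi = 1)
  effect_map <- list(
    between = c("(Intercept)" = NA, "fatigue" = "fatigue", "sex" = "sex",
                "fatigue:sex" = "fatigue:sex"),
    network = c("(Intercept)" = "network", "fatigue" = "network:fatigue",
                "sex" = "network:sex", "fatigue:sex" = "network:fatigue:sex"),
    hemisphere = c("(Intercept)" = "hemisphere",
                   "fatigue" = "hemisphere:fatigue",
                   "sex" = "hemisphere:sex",
                   "fatigue:sex" = "hemisphere:fatigue:sex"),
    net_hemi = c("(Intercept)" = "network:hemisphere",
                 "fatigue" = "network:hemisphere:fatigue",
                 "sex" = "network:hemisphere:sex",
                 "fatigue:sex" = "network:hemisphere:fatigue:sex"))
  rows <- NULL
  ss_err_total <- 0
  fits <- list()
  for (stratum in names(responses)) {
    df0 <- data.frame(y = responses[[stratum]], fatigue = fatigue, sex = sex)
    mod <- stats::lm(y ~ fatigue * sex, data = df0,
                     contrasts = list(fatigue = "contr.sum",
                                      sex = "contr.sum"))
    an <- car::Anova(mod, type = 3)
    ss_err_total <- ss_err_total +
      ss_scale[[stratum]] * an["Residuals", "Sum Sq"]
    fits[[stratum]] <- an
  }
  for (stratum in names(responses)) {
    an <- fits[[stratum]]
    map <- effect_map[[stratum]]
    for (term in names(map)) {
      if (is.na(map[[term]])) next
      ss <- ss_scale[[stratum]] * an[term, "Sum Sq"]
      rows <- rbind(rows, data.frame(
        effect = map[[term]],
        df_num = an[term, "Df"],
        df_den = an["Residuals", "Df"],
        F = an[term, "F value"],
        p = an[term, "Pr(>F)"],
        epsilon = if (stratum == "between") NA_real_ else 1,
        p_gg = an[term, "Pr(>F)"],
        ges = ss / (ss + ss_err_total),
        stringsAsFactors = FALSE))
    }
  }
  rownames(rows) <- NULL
  structure(rows, class = c("sw_anova", "data.frame"),
            n_subjects = n, dropped = dropped,
            sphericity = paste("two-level within factors: sphericity holds",
                               "trivially, Greenhouse-Geisser epsilon = 1"))
}

#' @export
print.sw_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (n = %d subjects%s)\n", attr(x, "n_subjects"),
              if (length(attr(x, "dropped")))
                paste0("; dropped listwise: ",
                       paste(attr(x, "dropped"), collapse = ", ")) else ""))
  df <- as.data.frame(x)
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  df$p_gg <- signif(df$p_gg, 3); df$ges <- signif(df$ges, 3)
  print(df, row.names = FALSE)
  cat(attr(x, "sphericity"), "\n")
  invisible(x)
}

#' Bonferroni-adjusted post-hoc pairwise comparisons
#'
#' Low- versus high-fatigue t-tests within each network x hemisphere cell
#' (family of 4) and, as a separate family, within each cell stratified by
#' sex (family of 8).  Bonferroni adjustment is \code{min(1, p * m)} with m
#' the family size; comparisons with fewer than 2 subjects per group are
#' skipped with a reason.
#'
#' @param sw long table (excluded rows ignored).
#' @param value dependent-variable column (default \code{"Sw"}).
#' @param var_equal pooled-variance t-tests (default TRUE).
#' @return data.frame with columns \code{family, network, hemisphere, sex,
#'   n_low, n_high, t, df, p, m, p_adj, note}.
#' @export
posthoc_pairwise <- function(sw, value = "Sw", var_equal = TRUE) {
  d <- sw[!sw$excluded, , drop = FALSE]
  run_cell <- function(sub, family, net, hemi, sex) {
    lo <- sub[[value]][sub$fatigue_group == "low"]
    hi <- sub[[value]][sub$fatigue_group == "high"]
    row <- data.frame(family = family, network = net, hemisphere = hemi,
                      sex = sex, n_low = length(lo), n_high = length(hi),
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      m = NA_integer_, p_adj = NA_real_,
                      note = NA_character_, stringsAsFactors = FALSE)
    if (length(lo) < 2L || length(hi) < 2L) {
      row$note <- "skipped: fewer than 2 subjects per group"
      return(row)
    }
    tt <- stats::t.test(lo, hi, var.equal = var_equal)
    row$t <- unname(tt$statistic)
    row$df <- unname(tt$parameter)
    row$p <- tt$p.value
    row
  }
  out <- NULL
  for (net in unique(d$network)) {
    for (hemi in unique(d$hemisphere)) {
      sub <- d[d$network == net & d$hemisphere == hemi, , drop = FALSE]
      out <- rbind(out, run_cell(sub, "group", net, hemi, NA_character_))
      for (sx in unique(d$sex)) {
        out <- rbind(out, run_cell(sub[sub$sex == sx, , drop = FALSE],
                                   "group_by_sex", net, hemi, sx))
      }
    }
  }
  for (fam in unique(out$family)) {
    idx <- out$family == fam & is.na(out$note)
    m <- sum(idx)
    out$m[idx] <- m
    out$p_adj[idx] <- pmin(1, out$p[idx] * m)
  }
  out
}

# |Z| from the normal approximation of a two-sample rank-sum test
wilcox_z <- function(x, g) {
  p_norm <- suppressWarnings(
    stats::wilcox.test(x ~ g, exact = FALSE, correct = FALSE))$p.value
  stats::qnorm(1 - p_norm / 2)
}

#' Nonparametric demographic tests against trait fatigue
#'
#' Spearman rank correlations between FSS-7 and each continuous covariate;
#' Wilcoxon rank-sum tests (effect size r = |Z|/sqrt(n)) for two-level
#' categorical covariates; Kruskal-Wallis (effect size eta-squared
#' \code{(H - k + 1)/(n - k)}) for vascular territory, skipped when any
#' territory has fewer than 2 subjects.  Missing values are dropped pairwise
#' per test.
#'
#' @param subjects subject table with \code{fss7} and covariate columns.
#' @param continuous,categorical covariate column names to test (defaults
#'   cover the standard set).
#' @return List of data.frames \code{spearman}, \code{rank_sum},
#'   \code{kruskal}.
#' @export
demographic_tests <- function(subjects,
                              continuous = c("age", "grip_pct", "nhpt_pct",
                                             "hads_anx", "hads_dep",
                                             "time_post_stroke"),
                              categorical = c("sex", "hemisphere_affected",
                                              "stroke_type")) {
  stopifnot("fss7" %in% names(subjects))
  sp <- NULL
  for (v in intersect(continuous, names(subjects))) {
    ok <- stats::complete.cases(subjects[[v]], subjects$fss7)
    row <- data.frame(variable = v, n = sum(ok), rho = NA_real_,
                      p = NA_real_, status = "not_assessable",
                      stringsAsFactors = FALSE)
    if (sum(ok) >= 5L && stats::sd(subjects[[v]][ok]) > 0 &&
        stats::sd(subjects$fss7[ok]) > 0) {
      ct <- suppressWarnings(
        stats::cor.test(subjects$fss7[ok], subjects[[v]][ok],
                        method = "spearman", exact = FALSE))
      row$rho <- unname(ct$estimate)
      row$p <- ct$p.value
      row$status <- "ok"
    }
    sp <- rbind(sp, row)
  }
  rs <- NULL
  for (v in intersect(categorical, names(subjects))) {
    ok <- stats::complete.cases(subjects[[v]], subjects$fss7)
    g <- factor(subjects[[v]][ok])
    x <- subjects$fss7[ok]
    row <- data.frame(variable = v, n = sum(ok), p = NA_real_,
                      effect_r = NA_real_, status = "not_assessable",
                      stringsAsFactors = FALSE)
    if (nlevels(g) == 2L && all(table(g) >= 2L) && sum(ok) >= 5L) {
      wt <- suppressWarnings(stats::wilcox.test(x ~ g))
      row$p <- wt$p.value
      row$effect_r <- wilcox_z(x, g) / sqrt(sum(ok))
      row$status <- "ok"
    }
    rs <- rbind(rs, row)
  }
  kw <- data.frame(variable = "vascular_territory", n = NA_integer_,
                   p = NA_real_, eta_sq = NA_real_,
                   status = "not_assessable", stringsAsFactors = FALSE)
  if ("vascular_territory" %in% names(subjects)) {
    ok <- stats::complete.cases(subjects$vascular_territory, subjects$fss7)
    g <- factor(subjects$vascular_territory[ok])
    kw$n <- sum(ok)
    if (nlevels(g) >= 2L && all(table(g) >= 2L)) {
      kt <- stats::kruskal.test(subjects$fss7[ok], g)
      k <- nlevels(g); n <- sum(ok)
      kw$p <- kt$p.value
      kw$eta_sq <- (unname(kt$statistic) - k + 1) / (n - k)
      kw$status <- "ok"
    } else {
      kw$status <- "skipped: too few in each group"
    }
  }
  list(spearman = sp, rank_sum = rs, kruskal = kw)
}
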