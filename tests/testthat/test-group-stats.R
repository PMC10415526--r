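test_that("fatigue classification uses the strict FSS-7 > 4 threshold", {
  expect_identical(classify_fatigue(5.6), "high")
  expect_identical(classify_fatigue(2.1), "low")
  expect_identical(classify_fatigue(4.0), "low")
  expect_identical(classify_fatigue(c(4.01, 1, 7)), c("high", "low", "high"))
  expect_error(classify_fatigue(0.5), "\\[1, 7\\]")
  expect_error(classify_fatigue(7.2), "\\[1, 7\\]")
})

mini_sw <- function(values_by_cell) {
  # build a long table with given Sw values replicated in each cell
  out <- NULL
  for (net in c("sensory", "motor")) {
    for (hemi in c("left", "right")) {
      v <- values_by_cell
      out <- rbind(out, data.frame(
        subject = sprintf("s%02d", seq_along(v)),
        fatigue_group = rep(c("low", "high"), length.out = length(v)),
        sex = rep(c("male", "male", "female", "female"),
                  length.out = length(v)),
        network = net, hemisphere = hemi, Sw = v,
        excluded = FALSE, exclusion_reason = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

test_that("extreme-outlier fences flag only values beyond 3 IQR", {
  sw <- mini_sw(c(1, 1.1, 0.9, 1.05))
  out <- detect_extreme_outliers(sw)
  expect_false(any(out$excluded))

  sw2 <- mini_sw(c(1, 1.1, 0.9, 1.05, 9))
  out2 <- detect_extreme_outliers(sw2)
  expect_true(all(out2$excluded[out2$Sw == 9]))
  expect_false(any(out2$excluded[out2$Sw != 9]))
  expect_match(out2$exclusion_reason[out2$excluded][1], "extreme outlier")

  sw3 <- mini_sw(rep(1, 6))
  expect_false(any(detect_extreme_outliers(sw3)$excluded))

  expect_error(detect_extreme_outliers(mini_sw(c(1, 2, 3))), "at least 4")
})

test_that("assumption checks report per-cell normality and homogeneity", {
  set.seed(5)
  sw <- mini_sw(rnorm(16, 1, 0.05))
  rep_ <- check_assumptions(sw)
  expect_equal(nrow(rep_$shapiro), 8L)  # 2 networks x 2 hemis x 2 groups
  expect_equal(nrow(rep_$levene), 4L)
  expect_true(all(rep_$shapiro$status == "ok"))
  expect_true(all(rep_$levene$status == "ok"))

  # constant cells are not assessable
  swc <- mini_sw(rep(1, 8))
  repc <- check_assumptions(swc)
  expect_true(all(repc$shapiro$status == "not_assessable"))
})

test_that("Shapiro-Wilk pass rate behaves like its alpha level", {
  set.seed(6)
  pass_gauss <- mean(replicate(200, stats::shapiro.test(rnorm(14))$p.value > 0.05))
  expect_gt(pass_gauss, 0.88)
  expect_lt(pass_gauss, 0.99)
  fail_skew <- mean(replicate(200, stats::shapiro.test(rexp(14))$p.value <= 0.05))
  expect_gt(fail_skew, 0.5)
})

test_that("mixed ANOVA matches the balanced cell-means oracle", {
  sw <- toy_sw_table()
  fit <- mixed_anova(sw)
  odf <- data.frame(subject = sw$subject, fatigue = sw$fatigue_group,
                    sex = sw$sex, network = sw$network,
                    hemisphere = sw$hemisphere, y = sw$Sw)
  oracle <- oracle_mixed_anova(odf)
  map <- c("A" = "fatigue", "B" = "sex", "A:B" = "fatigue:sex",
           "C" = "network", "A:C" = "network:fatigue",
           "B:C" = "network:sex", "A:B:C" = "network:fatigue:sex",
           "D" = "hemisphere", "A:D" = "hemisphere:fatigue",
           "B:D" = "hemisphere:sex", "A:B:D" = "hemisphere:fatigue:sex",
           "C:D" = "network:hemisphere",
           "A:C:D" = "network:hemisphere:fatigue",
           "B:C:D" = "network:hemisphere:sex",
           "A:B:C:D" = "network:hemisphere:fatigue:sex")
  for (key in names(map)) {
    F_oracle <- oracle$F[oracle$effect == key]
    F_impl <- fit$F[fit$effect == map[[key]]]
    expect_equal(F_impl, F_oracle, tolerance = 1e-10, label = map[[key]])
  }
  expect_true(all(fit$df_num == 1))
  expect_true(all(fit$df_den == 4))  # 8 subjects - 4 between cells
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  expect_true(all(fit$p_gg == fit$p))  # epsilon = 1 for 2-level factors
})

test_that("mixed ANOVA rejects underpopulated between-subject cells", {
  sw <- toy_sw_table()
  sw <- sw[sw$subject != "s03", ]  # leaves 1 low-female subject
  expect_error(mixed_anova(sw), "at least 2 subjects")
})

test_that("post-hoc comparisons apply Bonferroni within the right family", {
  set.seed(9)
  sw <- mini_sw(rnorm(12, 1, 0.05))
  ph <- posthoc_pairwise(sw)
  grp <- ph[ph$family == "group", ]
  expect_equal(nrow(grp), 4L)
  expect_true(all(grp$m == 4L))
  expect_equal(grp$p_adj, pmin(1, grp$p * 4))
  bysex <- ph[ph$family == "group_by_sex", ]
  expect_equal(nrow(bysex), 8L)
  expect_true(all(bysex$m[is.na(bysex$note)] == 8L))
  # monotonicity
  ok <- !is.na(ph$p_adj)
  expect_true(all(ph$p_adj[ok] >= ph$p[ok]))
  expect_true(all(ph$p_adj[ok] <= 1))

  # identical groups (low and high share the same values): adjusted p = 1
  swi <- mini_sw(rep(c(0.9, 0.9, 1.1, 1.1, 1.0, 1.0), 2))
  phi <- posthoc_pairwise(swi)
  expect_true(all(phi$p_adj[!is.na(phi$p_adj)] == 1))
})

test_that("a planted single-cell effect lands the smallest adjusted p there", {
  hits <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    sw <- NULL
    for (net in c("sensory", "motor")) for (hemi in c("left", "right")) {
      mu_high <- if (net == "sensory" && hemi == "right") 1.15 else 1
      sw <- rbind(sw, data.frame(
        subject = sprintf("s%02d", 1:14),
        fatigue_group = rep(c("low", "high"), each = 7),
        sex = rep(c("male", "female"), 7),
        network = net, hemisphere = hemi,
        Sw = c(rnorm(7, 1, 0.05), rnorm(7, mu_high, 0.05)),
        excluded = FALSE, exclusion_reason = NA_character_,
        stringsAsFactors = FALSE))
    }
    ph <- posthoc_pairwise(sw)
    grp <- ph[ph$family == "group", ]
    best <- grp[which.min(grp$p_adj), ]
    best$network == "sensory" && best$hemisphere == "right"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("demographic tests cover Spearman, rank-sum and Kruskal-Wallis", {
  n <- 12
  subjects <- data.frame(
    id = sprintf("s%02d", 1:n),
    fss7 = seq(1.5, 6.5, length.out = n),
    fatigue_group = classify_fatigue(seq(1.5, 6.5, length.out = n)),
    sex = rep(c("male", "female"), each = 6),
    age = seq(40, 80, length.out = n),            # perfectly increasing
    grip_pct = seq(110, 70, length.out = n),      # perfectly decreasing
    hemisphere_affected = rep(c("left", "right"), 6),
    stroke_type = rep(c("ischaemic", "haemorrhagic"), 6),
    vascular_territory = rep(c("MCA", "PCA", "BSC"), 4),
    stringsAsFactors = FALSE)
  res <- demographic_tests(subjects)
  expect_equal(res$spearman$rho[res$spearman$variable == "age"], 1)
  expect_equal(res$spearman$rho[res$spearman$variable == "grip_pct"], -1)
  expect_equal(res$kruskal$status, "ok")
  k <- 3; H <- stats::kruskal.test(subjects$fss7, factor(subjects$vascular_territory))$statistic
  expect_equal(res$kruskal$eta_sq, unname((H - k + 1) / (n - k)))
  expect_true(all(res$rank_sum$status == "ok"))
  expect_true(all(res$rank_sum$effect_r >= 0 & res$rank_sum$effect_r <= 1))
})

test_that("a fully separated 3 vs 3 rank-sum comparison has exact p = 0.1", {
  subjects <- data.frame(
    id = sprintf("s%d", 1:6),
    fss7 = c(1.2, 1.5, 1.8, 5.1, 5.6, 6.3),
    fatigue_group = c("low", "low", "low", "high", "high", "high"),
    sex = rep(c("male", "female"), each = 3),
    stringsAsFactors = FALSE)
  res <- demographic_tests(subjects, continuous = character(0),
                           categorical = "sex")
  expect_equal(res$rank_sum$p, 0.1)
})

test_that("Kruskal-Wallis is skipped when a territory has below 2 subjects", {
  subjects <- data.frame(
    id = sprintf("s%d", 1:8),
    fss7 = c(2, 3, 2.5, 5, 6, 5.5, 3.2, 4.6),
    fatigue_group = classify_fatigue(c(2, 3, 2.5, 5, 6, 5.5, 3.2, 4.6)),
    sex = rep(c("male", "female"), 4),
    vascular_territory = c(rep("MCA", 7), "PCA"),
    stringsAsFactors = FALSE)
  res <- demographic_tests(subjects)
  expect_match(res$kruskal$status, "too few")
  expect_true(is.na(res$kruskal$p))
})

test_that("the sw table guards group consistency and row counts", {
  subjects <- data.frame(id = c("a", "b"), fss7 = c(2, 6),
                         fatigue_group = c("low", "low"),  # wrong for b
                         sex = c("male", "female"),
                         stringsAsFactors = FALSE)
  metrics <- data.frame(subject = "a", network = "sensory",
                        hemisphere = "left", Sw = 1)
  expect_error(sw_table(metrics, subjects), "inconsistent")
})
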