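make_profiles <- function(values_by_class, groups = rep(c("patient", "control"), each = 6)) {
  # values_by_class: named list class -> numeric vector (one per subject)
  n <- length(groups)
  ids <- sprintf("s%02d", seq_len(n))
  dplyr::bind_rows(lapply(names(values_by_class), function(cl) {
    tibble::tibble(subject_id = ids, group = factor(groups, c("patient", "control")),
                   class = cl, duration_ms = values_by_class[[cl]],
                   occurrence = values_by_class[[cl]] / 10,
                   coverage = rep(100 / length(values_by_class), n))
  }))
}

test_that("summary-statistic t-test has the pooled-variance closed form", {
  r <- ttest_from_summary(10, 2, 6, 10, 2, 8)
  expect_equal(r$t, 0)
  expect_equal(r$p.value, 1)
  expect_equal(r$df, 12)
  expect_error(ttest_from_summary(5, 0, 6, 5, 0, 6), "zero")
  expect_error(ttest_from_summary(5, 1, 1, 6, 1, 6))
})

test_that("post-hoc t-tests equal the summary-statistic form and a permutation direction check", {
  set.seed(2)
  vals <- list(A = c(rnorm(6, 60, 5), rnorm(6, 50, 5)),
               B = rnorm(12, 55, 5))
  prof <- make_profiles(vals)
  ph <- posthoc_ttests(prof, "duration_ms")
  for (cl in c("A", "B")) {
    x <- vals[[cl]][1:6]; y <- vals[[cl]][7:12]
    ref <- ttest_from_summary(mean(x), sd(x), 6, mean(y), sd(y), 6)
    expect_equal(ph$t[ph$class == cl], ref$t, tolerance = 1e-12)
    expect_equal(ph$p.value[ph$class == cl], ref$p.value, tolerance = 1e-12)
    expect_equal(ph$df[ph$class == cl], 10)
    # and equals stats::t.test with pooled variance
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(ph$t[ph$class == cl], unname(tt$statistic), tolerance = 1e-12)
  }
  # identical groups -> t = 0
  prof0 <- make_profiles(list(A = rep(c(4, 5, 6, 7, 8, 9), 2)))
  expect_equal(posthoc_ttests(prof0, "duration_ms")$t, 0)
  # direction agrees with a 10,000-draw permutation test on the planted effect
  x <- vals$A[1:6]; y <- vals$A[7:12]
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  set.seed(99)
  perm <- replicate(10000, {
    idx <- sample(12, 6)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_perm_gt <- mean(perm >= obs)
  expect_true((p_perm_gt < 0.5) == (ph$t[ph$class == "A"] > 0))
})

test_that("split-plot ANOVA matches the textbook sums-of-squares oracle", {
  set.seed(7)
  for (rep_i in 1:3) {
    n_per <- sample(3:5, 1)
    groups <- rep(c("patient", "control"), each = n_per)
    vals <- list(A = rnorm(2 * n_per, 60, 8), B = rnorm(2 * n_per, 55, 8),
                 C = rnorm(2 * n_per, 65, 8), D = rnorm(2 * n_per, 75, 8))
    prof <- make_profiles(vals, groups)
    got <- mixed_anova(prof, "duration_ms")
    oracle <- splitplot_oracle(data.frame(
      subject = prof$subject_id, group = prof$group,
      class = prof$class, y = prof$duration_ms))
    expect_equal(got$statistic[got$effect == "group"], oracle$F_group,
                 tolerance = 1e-8)
    expect_equal(got$statistic[got$effect == "class"], oracle$F_class,
                 tolerance = 1e-8)
    expect_equal(got$statistic[got$effect == "group:class"], oracle$F_int,
                 tolerance = 1e-8)
    expect_equal(got$df2[got$effect == "group"], oracle$df_subj)
    expect_equal(got$df2[got$effect == "group:class"], oracle$df_err)
    expect_equal(got$df2_alt[got$effect == "group:class"],
                 3 * 2 * n_per) # (k-1) x N alternative convention
  }
})

test_that("a constructed additive null (common subject offsets) has zero interaction F", {
  base <- c(A = 60, B = 55, C = 65, D = 75)
  n_per <- 4
  subj_off <- seq(-3, 4, length.out = 2 * n_per)
  # class-specific residuals with zero mean inside every group x class cell
  # keep the cell means exactly additive while giving a nonzero error term
  eps <- c(-1, 1, -2, 2)
  vals <- lapply(seq_along(base), function(i) {
    base[i] + subj_off + 0.5 * i * rep(eps, 2)
  })
  names(vals) <- names(base)
  prof <- make_profiles(vals, rep(c("patient", "control"), each = n_per))
  got <- mixed_anova(prof, "duration_ms")
  expect_lt(got$statistic[got$effect == "group:class"], 1e-10)
})

test_that("subjects with a missing class value are excluded with a warning", {
  set.seed(1)
  vals <- list(A = rnorm(8, 60, 5), B = rnorm(8, 55, 5),
               C = rnorm(8, 60, 5), D = rnorm(8, 70, 5))
  prof <- make_profiles(vals, rep(c("patient", "control"), each = 4))
  prof$duration_ms[prof$subject_id == "s02" & prof$class == "B"] <- NA
  expect_warning(got <- mixed_anova(prof, "duration_ms"), "s02")
  expect_equal(got$df2[got$effect == "group"], 7 - 2)
})

test_that("null post-hoc false-positive rate sits at the nominal 5%", {
  set.seed(123)
  n_rep <- 250
  pvals <- replicate(n_rep, {
    vals <- list(A = rnorm(36, 60, 10), B = rnorm(36, 55, 10),
                 C = rnorm(36, 65, 10), D = rnorm(36, 75, 10))
    prof <- make_profiles(vals, rep(c("patient", "control"), each = 18))
    posthoc_ttests(prof, "duration_ms")$p.value
  })
  frac <- mean(pvals < 0.05) # 1000 null tests
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("Spearman severity correlation handles monotone and tied data", {
  prof <- tibble::tibble(subject_id = sprintf("p%02d", 1:8),
                         group = "patient", class = "A",
                         duration_ms = c(50, 55, 60, 62, 64, 70, 75, 80),
                         occurrence = 1, coverage = 25)
  sev <- tibble::tibble(subject_id = prof$subject_id,
                        severity = c(1, 1, 2, 2, 3, 3, 4, 4))
  res <- spearman_severity(prof, sev, "duration_ms")
  # oracle: midranks then Pearson
  oracle <- cor(rank(prof$duration_ms), rank(sev$severity))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  expect_equal(res$n, 8)

  sev_rev <- sev
  sev_rev$severity <- rev(sev$severity)
  prof_mono <- prof
  prof_mono$duration_ms <- 1:8
  sev_mono <- sev
  sev_mono$severity <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(spearman_severity(prof_mono, sev_mono, "duration_ms")$rho, 1)
  sev_mono$severity <- rev(sev_mono$severity)
  expect_equal(spearman_severity(prof_mono, sev_mono, "duration_ms")$rho, -1)
  # constant severity -> undefined
  sev$severity <- rep(2, 8)
  expect_true(is.na(spearman_severity(prof, sev, "duration_ms")$rho))
})

test_that("syntax t-tests flag planted excesses and use the df-34 critical value", {
  set.seed(21)
  seqs <- c("A>B", "A>C", "B>A")
  mk_syntax <- function(shift_ab = 0) {
    dplyr::bind_rows(lapply(1:36, function(i) {
      grp <- if (i <= 18) "patient" else "control"
      fr <- c(0.4, 0.3, 0.3) + rnorm(3, 0, 0.03)
      if (grp == "patient") fr[1] <- fr[1] + shift_ab
      fr <- fr / sum(fr)
      tibble::tibble(subject_id = sprintf("s%02d", i),
                     group = factor(grp, c("patient", "control")),
                     type = "doublet", sequence = seqs, fraction = fr)
    }))
  }
  # mirrored identical groups -> t exactly 0
  syn0 <- mk_syntax(0)
  syn0$fraction[syn0$group == "control"] <- syn0$fraction[syn0$group == "patient"]
  res0 <- syntax_ttests(syn0)
  expect_true(all(res0$t == 0))
  # planted A>B excess in patients -> largest |t| at A>B, flagged at df 34
  res1 <- syntax_ttests(mk_syntax(0.15))
  expect_equal(res1$sequence[which.max(abs(res1$t))], "A>B")
  expect_equal(unique(res1$df), 34)
  expect_true(all((abs(res1$t) >= qt(0.975, 34)) == res1$significant))
  expect_gt(res1$t[res1$sequence == "A>B"], 0)
  smry <- attr(res1, "summary")
  expect_equal(smry$expected_by_chance, 0.05 * 3)
})
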