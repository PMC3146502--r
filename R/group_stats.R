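check_profiles <- function(profiles, measure) {
  stopifnot(is.data.frame(profiles),
            all(c("subject_id", "group", "class", measure) %in% names(profiles)))
  profiles
}

#' Split-plot group-by-class ANOVA on microstate profiles
#'
#' Fits the mixed two-way design with subject group as the between-subject
#' factor and microstate class as the within-subject factor, via
#' `stats::aov` with an `Error(subject)` stratum (classical split-plot error
#' terms: group tested against between-subject variation, class and
#' group:class against the within-subject residual with
#' `(k-1)(N-2)` denominator df for two groups).
#'
#' Because reports in this literature sometimes quote the pooled denominator
#' `(k-1) * N` instead, the result also carries `df2_alt = (k-1) * N` and the
#' corresponding `p_alt` for the within-subject effects; the split-plot
#' values are the defaults.
#'
#' Subjects with a missing value of the measure in any class (e.g. a class
#' that never occurred, leaving duration undefined) are excluded with a
#' warning, keeping the design balanced.
#'
#' @param profiles Long profile tibble with columns `subject_id`, `group`,
#'   `class` and the measure columns (`duration_ms`, `occurrence`,
#'   `coverage`), as produced by [run_pipeline()] or [compute_profile()]
#'   plus metadata.
#' @param measure Which measure to analyse: `"duration_ms"`, `"occurrence"`
#'   or `"coverage"`.
#' @return A tibble with one row per effect (`group`, `class`,
#'   `group:class`): `df1`, `df2`, `statistic` (F), `p.value`, `df2_alt`,
#'   `p_alt`.
#' @export
mixed_anova <- function(profiles,
                        measure = c("duration_ms", "occurrence", "coverage")) {
  measure <- match.arg(measure)
  check_profiles(profiles, measure)
  df <- tibble::tibble(
    subject = factor(profiles$subject_id),
    group = factor(profiles$group),
    class = factor(profiles$class),
    y = profiles[[measure]]
  )
  bad <- unique(df$subject[!is.finite(df$y)])
  if (length(bad)) {
    warning("excluding ", length(bad),
            " subject(s) with missing '", measure, "' values: ",
            paste(bad, collapse = ", "), call. = FALSE)
    df <- df[!(df$subject %in% bad), ]
    df$subject <- droplevels(df$subject)
  }
  if (length(unique(df$group)) != 2 ||
      min(table(unique(df[c("subject", "group")])$group)) < 2) {
    stop("need two groups with at least 2 subjects each", call. = FALSE)
  }
  fit <- aov(y ~ group * class + Error(subject), data = df)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  row_of <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    tab[i, , drop = FALSE]
  }
  n_sub <- length(unique(df$subject))
  k <- length(unique(df$class))
  df2_between <- row_of(between, "Residuals")$Df
  df2_within <- row_of(within, "Residuals")$Df
  mk <- function(effect, tab, df2, alt = NA_real_) {
    r <- row_of(tab, effect)
    tibble::tibble(
      effect = sub("group:class", "group:class", effect),
      df1 = r$Df, df2 = df2,
      statistic = r$`F value`, p.value = r$`Pr(>F)`,
      df2_alt = alt,
      p_alt = if (is.na(alt)) NA_real_ else pf(r$`F value`, r$Df, alt,
                                               lower.tail = FALSE)
    )
  }
  out <- dplyr::bind_rows(
    mk("group", between, df2_between),
    mk("class", within, df2_within, alt = (k - 1) * n_sub),
    mk("group:class", within, df2_within, alt = (k - 1) * n_sub)
  )
  out$measure <- measure
  out
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' The classical unpaired Student t-test computed from group means, SDs and
#' sizes: pooled variance with `df = n1 + n2 - 2`, two-tailed p from the t
#' distribution. With n = 18 per group this reproduces published group
#' comparisons (df = 34) directly from printed tables.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A one-row tibble: `t` (sign of `mean1 - mean2`), `df`, `p.value`,
#'   plus the inputs.
#' @examples
#' ttest_from_summary(63.81, 14.71, 18, 54.55, 10.14, 18) # t = 2.20, df = 34
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    stop("pooled variance is zero", call. = FALSE)
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(
    t = t, df = df, p.value = 2 * pt(abs(t), df, lower.tail = FALSE),
    mean1 = mean1, sd1 = sd1, n1 = n1, mean2 = mean2, sd2 = sd2, n2 = n2
  )
}

#' Per-class post-hoc unpaired t-tests
#'
#' For each microstate class, compares the chosen measure between the two
#' groups with an unpaired, two-tailed, pooled-variance Student t-test
#' (`df = n1 + n2 - 2`). The sign convention is first group level minus
#' second (patient minus control for cohorts from this package). Subjects
#' with a missing value for a class are dropped pairwise for that class.
#'
#' @inheritParams mixed_anova
#' @return A tibble, one row per class: `class`, group means/SDs/sizes, `t`,
#'   `df`, `p.value`.
#' @export
posthoc_ttests <- function(profiles,
                           measure = c("duration_ms", "occurrence", "coverage")) {
  measure <- match.arg(measure)
  check_profiles(profiles, measure)
  grp <- factor(profiles$group)
  lv <- levels(grp)
  stopifnot(length(lv) == 2)
  purrr::map_dfr(sort(unique(profiles$class)), function(cl) {
    sel <- profiles$class == cl & is.finite(profiles[[measure]])
    x <- profiles[[measure]][sel & grp == lv[1]]
    y <- profiles[[measure]][sel & grp == lv[2]]
    res <- ttest_from_summary(mean(x), sd(x), length(x),
                              mean(y), sd(y), length(y))
    tibble::tibble(class = cl, measure = measure,
                   mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
                   mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y),
                   t = res$t, df = res$df, p.value = res$p.value)
  })
}

#' Spearman rank correlation between symptom severity and a measure
#'
#' Computes Spearman's rho with midrank handling of ties (ranks via
#' `rank()`, then Pearson correlation of the ranks), and a two-tailed p via
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with `n - 2` df.
#' Only subjects with a severity grade (patients) enter; the full grid of
#' classes is computed for the chosen measure.
#'
#' @inheritParams mixed_anova
#' @param severity Tibble with columns `subject_id` and `severity` (ordinal
#'   1-4; `NA` rows are dropped).
#' @return A tibble, one row per class: `class`, `measure`, `rho`, `n`,
#'   `p.value` (all `NA` when severity is constant or n < 3).
#' @export
spearman_severity <- function(profiles, severity,
                              measure = c("duration_ms", "occurrence", "coverage")) {
  measure <- match.arg(measure)
  check_profiles(profiles, measure)
  sev <- severity[!is.na(severity$severity), c("subject_id", "severity")]
  purrr::map_dfr(sort(unique(profiles$class)), function(cl) {
    d <- dplyr::inner_join(
      profiles[profiles$class == cl, c("subject_id", measure)],
      sev, by = "subject_id"
    )
    d <- d[is.finite(d[[measure]]), ]
    n <- nrow(d)
    if (n < 3 || length(unique(d$severity)) < 2 ||
        length(unique(d[[measure]])) < 2) {
      return(tibble::tibble(class = cl, measure = measure,
                            rho = NA_real_, n = n, p.value = NA_real_))
    }
    rho <- cor(rank(d[[measure]]), rank(d$severity))
    if (abs(rho) >= 1) {
      p <- 2 * pt(Inf, n - 2, lower.tail = FALSE)
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(abs(tval), n - 2, lower.tail = FALSE)
    }
    tibble::tibble(class = cl, measure = measure, rho = rho, n = n,
                   p.value = p)
  })
}

#' Between-group t-tests on transition fractions
#'
#' For every admissible doublet (12) and triplet (36) sequence, compares the
#' per-subject transition fractions between groups with an unpaired,
#' two-tailed pooled-variance t-test, flagging sequences whose |t| exceeds
#' the two-tailed 5% critical value at the test's df. No multiple-testing
#' correction is applied by default (matching the conventional reporting of
#' these 48 uncorrected tests), but a Bonferroni-adjusted p (within doublets
#' and within triplets separately) is included for transparency, along with
#' a summary attribute comparing the number of significant triplet tests to
#' the 36 x 0.05 = 1.8 expected by chance.
#'
#' @param syntax Long tibble with columns `subject_id`, `group`, `type`,
#'   `sequence`, `fraction` (one row per subject x sequence), e.g. from
#'   [run_pipeline()].
#' @return A tibble, one row per sequence: `type`, `sequence`, group means,
#'   `t`, `df`, `p.value`, `significant`, `p_bonferroni`; attribute
#'   `summary` holds per-type significant counts and the chance expectation.
#' @export
syntax_ttests <- function(syntax) {
  stopifnot(all(c("subject_id", "group", "type", "sequence", "fraction")
                %in% names(syntax)))
  grp <- factor(syntax$group)
  lv <- levels(grp)
  stopifnot(length(lv) == 2)
  out <- syntax |>
    dplyr::group_by(.data$type, .data$sequence) |>
    dplyr::group_modify(function(d, key) {
      x <- d$fraction[d$group == lv[1] & is.finite(d$fraction)]
      y <- d$fraction[d$group == lv[2] & is.finite(d$fraction)]
      if (length(x) < 2 || length(y) < 2 || (sd(x) == 0 && sd(y) == 0)) {
        return(tibble::tibble(mean_1 = mean(x), mean_2 = mean(y),
                              t = NA_real_, df = length(x) + length(y) - 2,
                              p.value = NA_real_))
      }
      res <- ttest_from_summary(mean(x), sd(x), length(x),
                                mean(y), sd(y), length(y))
      tibble::tibble(mean_1 = mean(x), mean_2 = mean(y),
                     t = res$t, df = res$df, p.value = res$p.value)
    }) |>
    dplyr::ungroup()
  out$significant <- !is.na(out$t) & abs(out$t) >= qt(0.975, out$df)
  out <- out |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(p_bonferroni = pmin(1, .data$p.value * dplyr::n())) |>
    dplyr::ungroup()
  summary_tbl <- out |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     n_significant = sum(.data$significant, na.rm = TRUE),
                     expected_by_chance = 0.05 * dplyr::n())
  attr(out, "summary") <- summary_tbl
  out
}
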