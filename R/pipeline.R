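#' Run the full microstate analysis pipeline on a cohort
#'
#' Executes, per subject: band-pass filtering and common-average referencing
#' of every epoch, GFP-peak topography extraction, polarity-invariant
#' modified K-means clustering into `k` classes; then cross-subject
#' permutation alignment of the per-subject template sets, canonical letter
#' assignment of the overall mean maps, back-fitting of class labels onto
#' every epoch with the subject's own aligned templates, run segmentation,
#' per-subject duration/occurrence/coverage profiles, transition-syntax
#' fractions, and the group-statistics layer (split-plot ANOVAs, post-hoc
#' t-tests, Spearman severity correlations, per-transition t-tests).
#'
#' @param cohort An `ms_cohort` tibble ([generate_cohort()] /
#'   [read_cohort()]).
#' @param band Band-pass edges in Hz (default `c(2, 20)`); `NULL` skips
#'   filtering (for data already confined to the analysis band).
#' @param k Number of microstate classes (default 4).
#' @param n_restarts Modified K-means restarts per subject.
#' @param seed Integer seed controlling the clustering restarts.
#' @param canonical Canonical maps for letter assignment
#'   (default [prototype_maps()]).
#' @param labeling Back-fitting mode, `"nearest-peak"` or `"per-sample"`.
#' @param run_stats Compute the group-statistics layer (default TRUE;
#'   requires both groups present).
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV/JSON (templates, profiles, syntax, stats, run log).
#' @return Object of class `ms_report`: list with `fits` (per-subject
#'   `ms_fit`), `alignment`, `mean_maps` (overall and per group, lettered),
#'   `letters`, `subject_gev` (tibble), `profiles` (long tibble: subject_id,
#'   group, severity, class, duration_ms, occurrence, coverage, n_runs,
#'   total_time_s), `syntax` (long tibble), and `stats` (list: `anova`,
#'   `posthoc`, `severity`, `syntax_tests`) unless `run_stats = FALSE`.
#' @export
run_pipeline <- function(cohort, band = c(2, 20), k = 4, n_restarts = 20,
                         seed = 1L, canonical = prototype_maps(),
                         labeling = c("nearest-peak", "per-sample"),
                         run_stats = TRUE, out_dir = NULL) {
  labeling <- match.arg(labeling)
  stopifnot(inherits(cohort, "ms_cohort"), nrow(cohort) >= 1)

  preprocess_one <- function(ep) {
    if (!is.null(band)) ep <- bandpass_filter(ep, band[1], band[2])
    average_reference(ep)
  }

  # --- per-subject preprocessing + clustering ------------------------------
  prep <- purrr::map(cohort$epochs, ~ purrr::map(.x, preprocess_one))
  names(prep) <- cohort$subject_id
  peaks <- purrr::map(prep, extract_peak_maps)
  fits <- purrr::imap(peaks, function(pk, sid) {
    modified_kmeans(pk, k = k, n_restarts = n_restarts,
                    seed = seed + match(sid, cohort$subject_id))
  })

  # --- cross-subject alignment and lettering -------------------------------
  tsets <- purrr::map(fits, "templates")
  alignment <- align_subject_templates(tsets)
  letters_map <- assign_class_letters(alignment$mean_maps, canonical)
  class_letters <- letters_map$letter

  mean_maps <- alignment$mean_maps
  rownames(mean_maps) <- class_letters
  group_maps <- purrr::map(split(cohort$subject_id, cohort$group), function(ids) {
    gm <- aligned_mean_maps(tsets, alignment, ids)
    rownames(gm) <- class_letters
    gm
  })

  subject_gev <- tibble::tibble(
    subject_id = cohort$subject_id,
    group = cohort$group,
    gev = purrr::map_dbl(fits[cohort$subject_id], "gev"),
    n_peak_maps = purrr::map_dbl(fits[cohort$subject_id], "n_maps")
  )

  # --- back-fitting, segmentation, profiles, syntax ------------------------
  per_subject <- purrr::map(cohort$subject_id, function(sid) {
    perm <- alignment$permutations[[sid]]
    tmpl <- as_template_matrix(fits[[sid]]$templates)[perm, , drop = FALSE]
    rownames(tmpl) <- class_letters
    runs <- purrr::map(prep[[sid]], function(ep) {
      segment_runs(backfit_labels(ep, tmpl, mode = labeling))
    })
    sf <- prep[[sid]][[1]]$sfreq
    list(profile = compute_profile(runs, sf, classes = sort(class_letters)),
         syntax = transition_stats(runs, classes = sort(class_letters)))
  })
  names(per_subject) <- cohort$subject_id

  meta <- cohort[, c("subject_id", "group", "severity")]
  profiles <- purrr::imap_dfr(per_subject, function(x, sid) {
    dplyr::mutate(x$profile, subject_id = sid, .before = 1)
  }) |>
    dplyr::left_join(meta, by = "subject_id") |>
    dplyr::relocate("subject_id", "group", "severity")
  syntax <- purrr::imap_dfr(per_subject, function(x, sid) {
    dplyr::mutate(x$syntax, subject_id = sid, .before = 1)
  }) |>
    dplyr::left_join(meta, by = "subject_id") |>
    dplyr::relocate("subject_id", "group")

  # --- statistics ----------------------------------------------------------
  stats_out <- NULL
  if (run_stats && length(unique(cohort$group)) == 2) {
    anova_tbl <- purrr::map_dfr(c("duration_ms", "occurrence", "coverage"),
                                ~ mixed_anova(profiles, .x))
    posthoc_tbl <- purrr::map_dfr(c("duration_ms", "occurrence", "coverage"),
                                  ~ posthoc_ttests(profiles, .x))
    severity_tbl <- purrr::map_dfr(c("duration_ms", "occurrence", "coverage"),
                                   ~ spearman_severity(profiles, meta, .x))
    syntax_tbl <- syntax_ttests(syntax)
    stats_out <- list(anova = anova_tbl, posthoc = posthoc_tbl,
                      severity = severity_tbl, syntax_tests = syntax_tbl)
  }

  report <- structure(list(
    fits = fits,
    alignment = alignment,
    mean_maps = mean_maps,
    group_mean_maps = group_maps,
    letters = letters_map,
    subject_gev = subject_gev,
    profiles = profiles,
    syntax = syntax,
    stats = stats_out,
    params = list(band = band, k = k, n_restarts = n_restarts, seed = seed,
                  labeling = labeling)
  ), class = "ms_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf("<ms_report> %d subjects, k = %d, mean GEV = %.3f\n",
              nrow(x$subject_gev), x$params$k, mean(x$subject_gev$gev)))
  cat("classes:", paste(rownames(x$mean_maps), collapse = " "), "\n")
  if (!is.null(x$stats)) {
    inter <- x$stats$anova[x$stats$anova$effect == "group:class", ]
    for (i in seq_len(nrow(inter))) {
      cat(sprintf("  %s group x class: F(%d,%d) = %.2f, p = %.3f\n",
                  inter$measure[i], inter$df1[i], inter$df2[i],
                  inter$statistic[i], inter$p.value[i]))
    }
  }
  invisible(x)
}

#' Write an `ms_report` to a directory of TSV/JSON artifacts
#'
#' Emits `templates_mean.tsv` (+ per-group), `subject_gev.tsv`,
#' `profiles.tsv`, `syntax.tsv`, the statistics tables, and `run_info.json`
#' logging every parameter and seed.
#'
#' @param report An `ms_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_templates_tsv(report$mean_maps, file.path(dir, "templates_mean.tsv"),
                      meta = c(report$params,
                               list(objective = report$alignment$objective)))
  for (g in names(report$group_mean_maps)) {
    write_templates_tsv(report$group_mean_maps[[g]],
                        file.path(dir, sprintf("templates_%s.tsv", g)))
  }
  readr::write_tsv(report$subject_gev, file.path(dir, "subject_gev.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$profiles, file.path(dir, "profiles.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$syntax, file.path(dir, "syntax.tsv"),
                   progress = FALSE)
  if (!is.null(report$stats)) {
    readr::write_tsv(report$stats$anova, file.path(dir, "anova.tsv"),
                     progress = FALSE)
    readr::write_tsv(report$stats$posthoc, file.path(dir, "posthoc_ttests.tsv"),
                     progress = FALSE)
    readr::write_tsv(report$stats$severity,
                     file.path(dir, "severity_correlations.tsv"),
                     progress = FALSE)
    readr::write_tsv(report$stats$syntax_tests,
                     file.path(dir, "syntax_ttests.tsv"), progress = FALSE)
  }
  jsonlite::write_json(
    c(report$params,
      list(package_version = as.character(utils::packageVersion("microstates")),
           alignment_objective = report$alignment$objective,
           letters = report$letters$letter)),
    file.path(dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
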