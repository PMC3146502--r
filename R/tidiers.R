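#' Tidy a microstate K-means fit
#'
#' Returns the fitted class templates in long form, one row per class x
#' channel.
#'
#' @param x An `ms_fit` from [modified_kmeans()].
#' @param ... Unused.
#' @return A tibble with columns `class`, `channel`, `value`.
#' @method tidy ms_fit
#' @export
tidy.ms_fit <- function(x, ...) {
  tm <- as_template_matrix(x$templates)
  tibble::as_tibble(tm, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "channel", values_to = "value")
}

#' Glance at a microstate K-means fit
#'
#' @param x An `ms_fit`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `n_maps`, `gev`, `n_iter`.
#' @method glance ms_fit
#' @export
glance.ms_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n_maps = x$n_maps, gev = x$gev,
                 n_iter = length(x$gev_trace))
}

#' Tidy a template set
#'
#' @param x An `ms_templates` matrix.
#' @param ... Unused.
#' @return Long tibble `class`, `channel`, `value` (joined with montage
#'   `x`/`y` coordinates when available).
#' @method tidy ms_templates
#' @export
tidy.ms_templates <- function(x, ...) {
  tm <- as_template_matrix(x)
  if (is.null(rownames(tm))) rownames(tm) <- paste0("class", seq_len(nrow(tm)))
  out <- tibble::as_tibble(tm, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "channel", values_to = "value")
  montage <- attr(x, "montage")
  if (!is.null(montage)) {
    out <- dplyr::left_join(out, montage, by = "channel")
  }
  out
}

#' Tidy a cross-subject template alignment
#'
#' @param x An `ms_alignment`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `common_class`, `subject_template`.
#' @method tidy ms_alignment
#' @export
tidy.ms_alignment <- function(x, ...) {
  purrr::imap_dfr(x$permutations, function(p, sid) {
    tibble::tibble(subject_id = sid,
                   common_class = seq_along(p),
                   subject_template = p)
  })
}

#' Glance at an alignment
#'
#' @param x An `ms_alignment`.
#' @param ... Unused.
#' @return One-row tibble: `n_subjects`, `k`, `objective`, `n_iter`.
#' @method glance ms_alignment
#' @export
glance.ms_alignment <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$subject_ids),
                 k = nrow(x$mean_maps),
                 objective = x$objective,
                 n_iter = length(x$objective_trace))
}

#' Glance at a pipeline report
#'
#' @param x An `ms_report`.
#' @param ... Unused.
#' @return One-row tibble: subject count, k, mean/sd of per-subject GEV,
#'   alignment objective.
#' @method glance ms_report
#' @export
glance.ms_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subject_gev),
    k = x$params$k,
    mean_gev = mean(x$subject_gev$gev),
    sd_gev = sd(x$subject_gev$gev),
    alignment_objective = x$alignment$objective
  )
}

#' Tidy a pipeline report
#'
#' @param x An `ms_report`.
#' @param ... Unused.
#' @return The long per-subject profile tibble.
#' @method tidy ms_report
#' @export
tidy.ms_report <- function(x, ...) x$profiles
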