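admissible_doublets <- function(classes = MS_CLASSES) {
  g <- expand.grid(from = classes, to = classes, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, ]
  paste(g$from, g$to, sep = ">")
}

admissible_triplets <- function(classes = MS_CLASSES) {
  g <- expand.grid(a = classes, b = classes, c = classes,
                   stringsAsFactors = FALSE)
  g <- g[g$a != g$b & g$b != g$c, ]
  paste(g$a, g$b, g$c, sep = ">")
}

count_sequences <- function(runs_list, order) {
  seqs <- purrr::map(runs_list, "class")
  unlist(purrr::map(seqs, function(s) {
    n <- length(s)
    if (n < order) return(character(0))
    idx <- seq_len(n - order + 1)
    parts <- purrr::map(seq_len(order) - 1L, ~ s[idx + .x])
    do.call(paste, c(parts, sep = ">"))
  }), use.names = FALSE)
}

#' Doublet transition fractions
#'
#' Counts ordered pairs of consecutive microstate runs within each epoch of
#' one subject (transitions are never counted across epoch boundaries, since
#' artifact-free epochs are temporally discontinuous) and normalises by the
#' total number of between-class transitions pooled over the subject's
#' epochs. With four classes there are 4 x 3 = 12 admissible doublets.
#'
#' @param runs_list List of per-epoch run tibbles from [segment_runs()].
#' @param classes Class alphabet (default A-D).
#' @return A tibble with 12 rows: `sequence` (e.g. `"A>B"`), `count`,
#'   `fraction` (`NA` when the subject has no transitions at all).
#' @export
count_doublets <- function(runs_list, classes = MS_CLASSES) {
  obs <- count_sequences(runs_list, 2L)
  keys <- admissible_doublets(classes)
  counts <- table(factor(obs, levels = keys))
  total <- sum(counts)
  tibble::tibble(
    sequence = keys,
    count = as.integer(counts),
    fraction = if (total > 0) as.integer(counts) / total else NA_real_
  )
}

#' Triplet transition fractions
#'
#' Counts ordered triples of consecutive runs within each epoch, pooled over
#' the subject's epochs, and normalises by the total triple count. With four
#' classes there are 4 x 3 x 3 = 36 admissible triplets (no immediate
#' repeats).
#'
#' @inheritParams count_doublets
#' @return A tibble with 36 rows: `sequence` (e.g. `"A>C>B"`), `count`,
#'   `fraction` (`NA` when the subject has no triples).
#' @export
count_triplets <- function(runs_list, classes = MS_CLASSES) {
  obs <- count_sequences(runs_list, 3L)
  keys <- admissible_triplets(classes)
  counts <- table(factor(obs, levels = keys))
  total <- sum(counts)
  tibble::tibble(
    sequence = keys,
    count = as.integer(counts),
    fraction = if (total > 0) as.integer(counts) / total else NA_real_
  )
}

#' Doublet and triplet syntax statistics for one subject
#'
#' Convenience wrapper combining [count_doublets()] and [count_triplets()]
#' into one tidy table.
#'
#' @inheritParams count_doublets
#' @return A tibble with columns `type` (`"doublet"`/`"triplet"`),
#'   `sequence`, `count`, `fraction`.
#' @export
transition_stats <- function(runs_list, classes = MS_CLASSES) {
  dplyr::bind_rows(
    dplyr::mutate(count_doublets(runs_list, classes), type = "doublet"),
    dplyr::mutate(count_triplets(runs_list, classes), type = "triplet")
  ) |>
    dplyr::select("type", "sequence", "count", "fraction")
}
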