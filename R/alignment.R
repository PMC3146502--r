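permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# fix map sign so the largest-magnitude channel is positive
canonical_sign <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) v else v * s
}

# polarity-invariant mean of a set of unit-norm maps (rows): dominant
# eigenvector of their scatter, canonical sign
mean_map <- function(M) {
  canonical_sign(dominant_eigvec(crossprod(M)))
}

#' Align per-subject microstate templates across subjects
#'
#' Individual subjects' template sets are clustered independently, so their
#' class order (and polarity) is arbitrary. This aligns them to common
#' classes with an iterative permutation algorithm that maximises the common
#' variance over subjects: (1) initialise the class-mean maps from the first
#' subject (subjects processed in sorted `subject_id` order for
#' determinism); (2) for each subject, choose among all k! permutations of
#' its templates the one maximising the summed squared spatial correlation
#' with the current mean maps; (3) recompute each class-mean map as the
#' dominant eigenvector of the scatter of the subjects' maps assigned to
#' that class (polarity-invariant mean, sign fixed so the largest-magnitude
#' channel is positive); repeat (2)-(3) until no permutation changes. The
#' objective (mean over subjects and classes of squared spatial correlation
#' with the class mean) is non-decreasing over iterations and the algorithm
#' terminates on the finite permutation lattice.
#'
#' @param subject_templates Named list (names = subject ids) of k x channel
#'   template matrices (`ms_fit$templates` or plain matrices with unit-norm
#'   average-referenced rows).
#' @param max_iter Iteration cap.
#' @return Object of class `ms_alignment`: list with `permutations` (named
#'   list; `perm[j]` gives the subject template index feeding common class
#'   j), `mean_maps` (`ms_templates`, k x channels), `objective` (final
#'   common-variance objective), `objective_trace` and `subject_ids`.
#' @export
align_subject_templates <- function(subject_templates, max_iter = 100) {
  stopifnot(is.list(subject_templates), length(subject_templates) >= 1)
  ids <- names(subject_templates)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("subject_templates must be a named list with unique subject ids",
         call. = FALSE)
  }
  ord <- order(ids)
  tsets <- purrr::map(subject_templates[ord], as_template_matrix)
  ids <- ids[ord]
  k <- nrow(tsets[[1]])
  nch <- ncol(tsets[[1]])
  if (!all(purrr::map_lgl(tsets, ~ nrow(.x) == k && ncol(.x) == nch))) {
    stop("all subjects must share k and montage", call. = FALSE)
  }
  tsets <- purrr::map(tsets, ~ .x / sqrt(rowSums(.x^2)))
  perms_all <- permutations_of(k)
  n_sub <- length(tsets)

  mean_maps <- tsets[[1]]
  perms <- purrr::map(seq_len(n_sub), ~ seq_len(k))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (s in seq_len(n_sub)) {
      # corr2[i, j] = squared correlation of subject template i with mean map j
      corr2 <- (tsets[[s]] %*% t(mean_maps))^2
      scores <- apply(perms_all, 1, function(p) sum(corr2[cbind(p, seq_len(k))]))
      best <- perms_all[which.max(scores), ]
      if (!identical(as.integer(best), as.integer(perms[[s]]))) changed <- TRUE
      perms[[s]] <- as.integer(best)
    }
    for (j in seq_len(k)) {
      M <- do.call(rbind, purrr::map(seq_len(n_sub),
                                     ~ tsets[[.x]][perms[[.x]][j], ]))
      mean_maps[j, ] <- mean_map(M)
    }
    obj <- mean(purrr::map_dbl(seq_len(n_sub), function(s) {
      mean(rowSums(tsets[[s]][perms[[s]], , drop = FALSE] * mean_maps)^2)
    }))
    trace <- c(trace, obj)
    if (!changed && iter > 1) break
  }
  names(perms) <- ids
  rownames(mean_maps) <- paste0("class", seq_len(k))
  structure(list(
    permutations = perms,
    mean_maps = structure(mean_maps, class = c("ms_templates", "matrix", "array")),
    objective = trace[length(trace)],
    objective_trace = trace,
    subject_ids = ids
  ), class = "ms_alignment")
}

#' @export
print.ms_alignment <- function(x, ...) {
  cat(sprintf("<ms_alignment> %d subjects, k = %d, common variance = %.3f\n",
              length(x$subject_ids), nrow(x$mean_maps), x$objective))
  invisible(x)
}

#' Polarity-invariant group-mean maps from aligned subject templates
#'
#' Given an alignment, computes class-mean maps over any subset of subjects
#' (e.g. one group) as the dominant eigenvector of the per-class scatter of
#' the permuted subject maps.
#'
#' @param subject_templates Named list of template matrices (as passed to
#'   [align_subject_templates()]).
#' @param alignment The corresponding `ms_alignment`.
#' @param subjects Character vector of subject ids to average (default all).
#' @return `ms_templates` matrix, k x channels.
#' @export
aligned_mean_maps <- function(subject_templates, alignment, subjects = NULL) {
  if (is.null(subjects)) subjects <- alignment$subject_ids
  stopifnot(all(subjects %in% alignment$subject_ids))
  k <- nrow(alignment$mean_maps)
  out <- t(vapply(seq_len(k), function(j) {
    M <- do.call(rbind, purrr::map(subjects, function(s) {
      tm <- as_template_matrix(subject_templates[[s]])
      tm <- tm / sqrt(rowSums(tm^2))
      tm[alignment$permutations[[s]][j], ]
    }))
    mean_map(M)
  }, numeric(ncol(alignment$mean_maps))))
  dimnames(out) <- dimnames(alignment$mean_maps)
  structure(out, class = c("ms_templates", "matrix", "array"))
}

#' Assign canonical class letters to mean maps
#'
#' Solves the k x k assignment problem matching each empirical mean map to
#' one canonical prototype so that the total squared spatial correlation is
#' maximised (all k! permutations enumerated; k = 4 gives 24). Matching is
#' polarity-free.
#'
#' @param mean_maps `ms_templates` (k x channels) to be lettered.
#' @param canonical Canonical reference maps; default [prototype_maps()]
#'   (rows named A-D). Users may supply their own reference set.
#' @return A tibble with columns `class_index`, `letter`, `match` (the
#'   absolute spatial correlation with the matched canonical map).
#' @export
assign_class_letters <- function(mean_maps, canonical = prototype_maps()) {
  mm <- as_template_matrix(mean_maps)
  cm <- as_template_matrix(canonical)
  stopifnot(nrow(mm) == nrow(cm), ncol(mm) == ncol(cm))
  k <- nrow(mm)
  mm <- mm / sqrt(rowSums(mm^2))
  cm <- cm / sqrt(rowSums(cm^2))
  corr <- mm %*% t(cm)
  perms_all <- permutations_of(k)
  scores <- apply(perms_all, 1, function(p) sum(corr[cbind(seq_len(k), p)]^2))
  best <- perms_all[which.max(scores), ]
  letters_ref <- rownames(cm)
  if (is.null(letters_ref)) letters_ref <- MS_CLASSES[seq_len(k)]
  tibble::tibble(
    class_index = seq_len(k),
    letter = letters_ref[best],
    match = abs(corr[cbind(seq_len(k), best)])
  )
}
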