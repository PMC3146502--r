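#' Collect topographies at GFP peaks across epochs
#'
#' Computes the GFP of every epoch, finds interior GFP maxima and returns the
#' momentary topographies at those samples, with provenance. Only these maps
#' enter clustering: topography is stable around GFP peaks and changes in the
#' troughs, and peak maps have maximal signal-to-noise.
#'
#' @param epochs A list of preprocessed (filtered, average-referenced)
#'   [eeg_epoch()] objects.
#' @return An object of class `ms_peaks`: list with `maps` (n_peaks x
#'   n_channels matrix of unit-norm, average-referenced maps), `gfp` (the GFP
#'   value at each peak, uV), `epoch` and `sample` (provenance indices), and
#'   `sfreq`.
#' @export
extract_peak_maps <- function(epochs) {
  stopifnot(length(epochs) >= 1, all(purrr::map_lgl(epochs, inherits, "eeg_epoch")))
  pieces <- purrr::imap(epochs, function(ep, i) {
    g <- compute_gfp(ep)
    pk <- find_gfp_peaks(g)
    if (!length(pk)) return(NULL)
    m <- t(ep$data[, pk, drop = FALSE])
    m <- m - rowMeans(m)
    list(maps = m, gfp = as.numeric(g)[pk],
         epoch = rep(i, length(pk)), sample = pk)
  })
  pieces <- purrr::compact(pieces)
  if (!length(pieces)) stop("no GFP peaks found in any epoch", call. = FALSE)
  maps <- do.call(rbind, purrr::map(pieces, "maps"))
  gfp <- unlist(purrr::map(pieces, "gfp"), use.names = FALSE)
  keep <- gfp > 0
  maps <- maps[keep, , drop = FALSE] / sqrt(rowSums(maps[keep, , drop = FALSE]^2))
  structure(list(maps = maps,
                 gfp = gfp[keep],
                 epoch = unlist(purrr::map(pieces, "epoch"), use.names = FALSE)[keep],
                 sample = unlist(purrr::map(pieces, "sample"), use.names = FALSE)[keep],
                 sfreq = epochs[[1]]$sfreq),
            class = "ms_peaks")
}

#' @export
print.ms_peaks <- function(x, ...) {
  cat(sprintf("<ms_peaks> %d GFP-peak maps x %d channels from %d epoch(s)\n",
              nrow(x$maps), ncol(x$maps), length(unique(x$epoch))))
  invisible(x)
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of two maps. For average-referenced
#' maps this equals the cosine similarity of the map vectors. Microstate
#' assignment treats a map and its negation as identical, so polarity-free
#' comparisons use the square or absolute value of this quantity.
#'
#' @param a,b Numeric vectors of per-channel potentials on the same montage.
#' @return Scalar in \[-1, 1\].
#' @export
spatial_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) {
    stop("spatial correlation undefined for a zero-variance map", call. = FALSE)
  }
  as.numeric(cor(a, b))
}

# dominant eigenvector of a symmetric scatter matrix, unit norm
dominant_eigvec <- function(S) {
  v <- eigen(S, symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

# GEV of an assignment: maps rows unit-norm & centred, templates rows unit-norm
gev_of <- function(maps, gfp, templates, labels) {
  corr <- rowSums(maps * templates[labels, , drop = FALSE])
  sum((gfp * corr)^2) / sum(gfp^2)
}

#' Polarity-invariant modified K-means clustering of peak maps
#'
#' Clusters GFP-peak topographies into `k` microstate classes, treating a map
#' and its negation as the same state. Each iteration (i) assigns every map
#' to the template with maximal squared spatial correlation and (ii)
#' recomputes each template as the dominant eigenvector of the
#' GFP^2-weighted scatter of its assigned maps (the polarity-invariant mean:
#' an arithmetic mean would cancel polarity-inverted members). With this
#' update the global explained variance (GEV) is non-decreasing over
#' iterations; iteration stops when assignments are unchanged or the
#' relative GEV improvement falls below `tol`. The best of `n_restarts`
#' random initialisations is returned; restarts alternate between seeding
#' the templates from k distinct observed maps and from the polarity-
#' invariant means of a random labelling (the latter reaches optima whose
#' basin contains no single-map seed).
#'
#' @param peaks An `ms_peaks` object from [extract_peak_maps()].
#' @param k Number of classes (default 4, the standard for resting EEG).
#' @param n_restarts Random restarts (default 20).
#' @param seed Optional integer seed for the restarts.
#' @param gfp_weighted If `TRUE` (default) the template update weights each
#'   assigned map by its squared GFP, which is the classical formulation
#'   (eigenvector of the raw-map scatter) and makes GEV provably monotone;
#'   `FALSE` uses the unweighted scatter of normalised maps.
#' @param tol Relative GEV convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap per restart.
#' @return An object of class `ms_fit`: list with `templates` (`ms_templates`
#'   matrix, k x channels, unit-norm rows), `labels` (per-map class index),
#'   `gev`, `gev_trace` (GEV per iteration of the winning restart), `k`,
#'   `n_maps`.
#' @export
modified_kmeans <- function(peaks, k = 4, n_restarts = 20, seed = NULL,
                            gfp_weighted = TRUE, tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(peaks, "ms_peaks"))
  maps <- peaks$maps
  gfp <- peaks$gfp
  n <- nrow(maps)
  if (n < k) stop("need at least k = ", k, " peak maps, got ", n, call. = FALSE)
  w <- if (gfp_weighted) gfp^2 else rep(1, n)

  weighted_templates <- function(labels, tmpl) {
    for (c_i in seq_len(k)) {
      idx <- which(labels == c_i)
      S <- crossprod(maps[idx, , drop = FALSE] * sqrt(w[idx]))
      tmpl[c_i, ] <- dominant_eigvec(S)
    }
    tmpl
  }

  run_once <- function(init_mode) {
    if (init_mode == "maps") {
      tmpl <- maps[sample.int(n, k), , drop = FALSE]
    } else {
      # random labelling with every cluster non-empty and random sizes
      lab0 <- sample(c(seq_len(k), sample.int(k, n - k, replace = TRUE)))
      tmpl <- weighted_templates(lab0, maps[seq_len(k), , drop = FALSE])
    }
    labels <- integer(n)
    gev_prev <- -Inf
    trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      corr <- maps %*% t(tmpl) # cosine = spatial correlation (unit, centred)
      new_labels <- max.col(corr^2, ties.method = "first")
      # re-seed any empty cluster with the worst-explained map
      for (c_i in seq_len(k)) {
        if (!any(new_labels == c_i)) {
          best <- corr[cbind(seq_len(n), new_labels)]
          worst <- which.max(gfp^2 * (1 - best^2))
          new_labels[worst] <- c_i
          tmpl[c_i, ] <- maps[worst, ]
        }
      }
      tmpl <- weighted_templates(new_labels, tmpl)
      gev <- gev_of(maps, gfp, tmpl, new_labels)
      trace <- c(trace, gev)
      converged <- identical(new_labels, labels) ||
        (gev - gev_prev) < tol * max(gev_prev, .Machine$double.eps)
      labels <- new_labels
      gev_prev <- gev
      if (converged) break
    }
    list(templates = tmpl, labels = labels, gev = gev_prev, trace = trace)
  }

  runner <- function() {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      res <- run_once(if (r %% 2 == 1) "maps" else "labels")
      if (is.null(best) || res$gev > best$gev) best <- res
    }
    best
  }
  best <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())

  tmpl <- best$templates
  rownames(tmpl) <- paste0("class", seq_len(k))
  colnames(tmpl) <- colnames(maps)
  structure(list(
    templates = structure(tmpl, class = c("ms_templates", "matrix", "array")),
    labels = best$labels,
    gev = best$gev,
    gev_trace = best$trace,
    k = k,
    n_maps = n
  ), class = "ms_fit")
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("<ms_fit> k = %d classes over %d GFP-peak maps, GEV = %.3f\n",
              x$k, x$n_maps, x$gev))
  invisible(x)
}

#' Global explained variance of a labelled template fit
#'
#' GEV is the GFP-weighted fraction of topographic variance at the GFP peaks
#' explained by assigning each peak map to its class template:
#' `sum((gfp_m * corr(map_m, template_label(m)))^2) / sum(gfp_m^2)`.
#' Polarity does not enter (the correlation is squared).
#'
#' @param peaks An `ms_peaks` object.
#' @param templates Template matrix (`ms_fit$templates` or compatible),
#'   unit-norm average-referenced rows.
#' @param labels Integer class index per peak map.
#' @return Scalar in \[0, 1\].
#' @export
compute_gev <- function(peaks, templates, labels) {
  stopifnot(inherits(peaks, "ms_peaks"),
            length(labels) == nrow(peaks$maps),
            all(labels >= 1), all(labels <= nrow(templates)))
  tm <- as_template_matrix(templates)
  tm <- tm / sqrt(rowSums(tm^2))
  gev_of(peaks$maps, peaks$gfp, tm, labels)
}
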