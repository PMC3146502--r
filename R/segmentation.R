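#' Back-fit microstate class labels onto an epoch
#'
#' Labels every sample of an epoch with one of the template classes. In the
#' default `"nearest-peak"` mode, each GFP peak is labelled with the class of
#' maximal squared spatial correlation (polarity-free), and every non-peak
#' sample inherits the label of its nearest peak; exact midpoints between two
#' peaks go to the earlier peak, samples before the first / after the last
#' peak take that peak's label. This reconstruction is consistent with
#' clustering having used only peak maps. The `"per-sample"` mode instead
#' labels every sample directly by its own maximal squared correlation.
#'
#' @param epoch A preprocessed [eeg_epoch()].
#' @param templates Class templates aligned to common classes (k x channels
#'   matrix; rows may be named with class letters).
#' @param mode `"nearest-peak"` (default) or `"per-sample"`.
#' @return An object of class `ms_labels`: character vector of per-sample
#'   class letters, with attributes `sfreq`, `peaks` (peak indices) and
#'   `peak_labels`.
#' @export
backfit_labels <- function(epoch, templates,
                           mode = c("nearest-peak", "per-sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(epoch, "eeg_epoch"))
  tm <- as_template_matrix(templates)
  tm <- tm / sqrt(rowSums(tm^2))
  cls <- rownames(tm)
  if (is.null(cls)) cls <- MS_CLASSES[seq_len(nrow(tm))]
  n <- ncol(epoch$data)
  centred <- sweep(epoch$data, 2, colMeans(epoch$data))

  label_of <- function(cols) {
    corr2 <- (crossprod(centred[, cols, drop = FALSE], t(tm)))^2
    max.col(corr2, ties.method = "first")
  }

  pk <- integer(0)
  pk_lab <- integer(0)
  if (mode == "per-sample") {
    lab <- cls[label_of(seq_len(n))]
  } else {
    g <- compute_gfp(epoch)
    pk <- find_gfp_peaks(g)
    if (!length(pk)) stop("epoch has no GFP peaks to back-fit", call. = FALSE)
    pk_lab <- label_of(pk)
    # nearest peak per sample; midpoint ties to the earlier peak
    nearest <- findInterval(seq_len(n), pk)      # index of peak at/before sample
    nearest[nearest == 0L] <- 1L
    use_next <- nearest < length(pk) &
      (pk[pmin(nearest + 1L, length(pk))] - seq_len(n)) <
        (seq_len(n) - pk[nearest])
    nearest[use_next] <- nearest[use_next] + 1L
    lab <- cls[pk_lab[nearest]]
  }
  structure(lab, class = "ms_labels", sfreq = epoch$sfreq,
            peaks = pk,
            peak_labels = if (length(pk_lab)) cls[pk_lab] else character(0))
}

#' Segment a label sequence into microstate runs
#'
#' A microstate run is a maximal stretch of consecutive samples carrying the
#' same class label. No minimal duration is imposed and no smoothing or
#' merging is applied; single-sample runs and runs touching the epoch edges
#' are kept.
#'
#' @param labels An `ms_labels` vector (or any character vector plus a
#'   `sfreq` attribute / argument).
#' @param sfreq Sampling rate; taken from `labels` attribute if absent.
#' @return A tibble with one row per run: `class`, `start` (1-based,
#'   inclusive), `end` (exclusive, half-open), `n_samples`, `duration_ms`,
#'   `n_gfp_peaks` (peaks contained, if peak indices are available).
#' @export
segment_runs <- function(labels, sfreq = attr(labels, "sfreq")) {
  if (is.null(sfreq)) stop("sampling rate required", call. = FALSE)
  lab <- as.character(labels)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pk <- attr(labels, "peaks")
  n_pk <- if (is.null(pk) || !length(pk)) {
    NA_integer_
  } else {
    vapply(seq_along(starts),
           function(i) sum(pk >= starts[i] & pk <= ends[i]), integer(1))
  }
  tibble::tibble(
    class = r$values,
    start = as.integer(starts),
    end = as.integer(ends + 1L),
    n_samples = as.integer(r$lengths),
    duration_ms = r$lengths * 1000 / sfreq,
    n_gfp_peaks = n_pk
  )
}

#' Per-subject microstate profile
#'
#' Pools the runs of all of a subject's epochs and computes, per class, the
#' three standard microstate parameters: mean duration (ms, the mean length
#' of that class's runs), occurrence (runs of that class per second of total
#' analysed time) and coverage (percent of total analysed time labelled with
#' that class). Edge-truncated runs are included (no minimal duration is
#' required anywhere in the pipeline).
#'
#' @param runs_list List of per-epoch run tibbles from [segment_runs()].
#' @param sfreq Sampling rate (Hz).
#' @param classes Class letters the profile is computed over (default A-D);
#'   classes with zero runs get `duration_ms = NA`, zero occurrence and zero
#'   coverage.
#' @return A tibble with one row per class: `class`, `duration_ms`,
#'   `occurrence`, `coverage`, `n_runs`, `total_time_s`.
#' @export
compute_profile <- function(runs_list, sfreq, classes = MS_CLASSES) {
  stopifnot(length(runs_list) >= 1)
  runs <- dplyr::bind_rows(runs_list)
  total_samples <- sum(runs$n_samples)
  total_time_s <- total_samples / sfreq
  per_class <- purrr::map_dfr(classes, function(cl) {
    rr <- runs[runs$class == cl, ]
    tibble::tibble(
      class = cl,
      duration_ms = if (nrow(rr)) mean(rr$duration_ms) else NA_real_,
      occurrence = nrow(rr) / total_time_s,
      coverage = 100 * sum(rr$n_samples) / total_samples,
      n_runs = nrow(rr)
    )
  })
  per_class$total_time_s <- total_time_s
  per_class
}
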