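#' Write / read one epoch as a plain TSV matrix
#'
#' The on-disk epoch format is a tab-separated text file with one header row
#' of channel names and one row per sample (columns = channels, values in
#' uV). The sampling rate is not stored in the file and must be supplied at
#' read time (the cohort manifest records it).
#'
#' @param epoch An [eeg_epoch()].
#' @param path Output file path.
#' @return `write_epoch_tsv` returns `path` invisibly; `read_epoch_tsv`
#'   returns an [eeg_epoch()].
#' @export
write_epoch_tsv <- function(epoch, path) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  df <- as.data.frame(t(epoch$data))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_epoch_tsv
#' @param path File to read.
#' @param sfreq Sampling rate in Hz of the stored epoch.
#' @param montage Target montage; file channels are re-ordered to match, and
#'   a missing or unknown channel is a parse error naming it.
#' @export
read_epoch_tsv <- function(path, sfreq, montage = montage_1020()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  chans <- names(df)
  missing <- setdiff(montage$channel, chans)
  if (length(missing)) {
    stop("epoch file ", path, " is missing montage channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(chans, montage$channel)
  if (length(unknown)) {
    stop("epoch file ", path, " has unknown channel(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  data <- t(as.matrix(df[, montage$channel]))
  eeg_epoch(data, sfreq, montage)
}

#' Write / read a cohort as epoch TSV files plus a manifest
#'
#' Writes one TSV matrix file per epoch (see [write_epoch_tsv()]) into
#' `dir/epochs/` and a tab-separated manifest `dir/manifest.tsv` with
#' columns `subject_id`, `group`, `severity`, `epoch`, `sfreq`, `file`.
#' `read_cohort()` reconstructs the cohort tibble from such a manifest.
#'
#' @param cohort An `ms_cohort` tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the manifest path invisibly;
#'   `read_cohort` returns an `ms_cohort` tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::pmap_dfr(
    list(cohort$subject_id, cohort$group, cohort$severity, cohort$epochs),
    function(sid, grp, sev, eps) {
      purrr::imap_dfr(eps, function(ep, i) {
        f <- file.path("epochs", sprintf("%s_ep%03d.tsv", sid, i))
        write_epoch_tsv(ep, file.path(dir, f))
        tibble::tibble(subject_id = sid, group = as.character(grp),
                       severity = sev, epoch = i, sfreq = ep$sfreq, file = f)
      })
    })
  manifest <- file.path(dir, "manifest.tsv")
  readr::write_tsv(rows, manifest, progress = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @param manifest Path to a `manifest.tsv` written by [write_cohort()].
#' @param montage Montage the epochs are mapped onto.
#' @export
read_cohort <- function(manifest, montage = montage_1020()) {
  man <- readr::read_tsv(manifest, show_col_types = FALSE, progress = FALSE)
  base <- dirname(manifest)
  cohort <- man |>
    dplyr::group_by(.data$subject_id, .data$group, .data$severity) |>
    dplyr::summarise(
      n_epochs = dplyr::n(),
      epochs = list(purrr::map2(.data$file, .data$sfreq,
                                ~ read_epoch_tsv(file.path(base, .x), .y, montage))),
      .groups = "drop"
    ) |>
    dplyr::ungroup()
  cohort$group <- factor(cohort$group, levels = c("patient", "control"))
  cohort$severity <- as.integer(cohort$severity)
  cohort <- dplyr::arrange(cohort, .data$group, .data$subject_id)
  class(cohort) <- c("ms_cohort", class(cohort))
  cohort
}

#' Write a template set as TSV with a JSON sidecar
#'
#' Templates are stored as a TSV (rows = classes, columns = channels, header
#' of channel names, first column `class`) with a JSON sidecar recording k,
#' GEV (if known) and provenance fields.
#'
#' @param templates `ms_templates` matrix.
#' @param path TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_templates_tsv <- function(templates, path, meta = list()) {
  tm <- as_template_matrix(templates)
  df <- tibble::as_tibble(tm, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(class = rownames(tm) %||%
                                          paste0("class", seq_len(nrow(tm)))), df)
  readr::write_tsv(df, path, progress = FALSE)
  sidecar <- c(list(k = nrow(tm), channels = colnames(tm)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
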