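#' Configuration for the synthetic EEG cohort generator
#'
#' Describes a two-group resting-state study design: per-group subject
#' counts, epochs per subject, epoch geometry, and per-group/per-class
#' microstate duration distributions. The defaults reproduce a typical
#' two-group design with 18 subjects per group, 2.56 s (512-sample) epochs at
#' 200 Hz, between 18 and 61 epochs per subject, and class mean durations /
#' SDs equal to the package's reference patient/control values (class A
#' longer in patients, all other classes comparable).
#'
#' @param n_subjects_per_group Subjects per group (patient, control).
#' @param epochs_per_subject Either a single count or a length-2 range from
#'   which each subject's epoch count is drawn uniformly. Default `c(18, 61)`.
#' @param sampling_rate Hz; default 200.
#' @param epoch_samples Samples per epoch; default 512 (2.56 s at 200 Hz).
#' @param class_mean_duration_ms 2 x 4 matrix (rows `patient`, `control`;
#'   columns classes A-D) of mean microstate durations in ms.
#' @param class_duration_sd_ms Matching 2 x 4 matrix of duration SDs in ms.
#' @param oscillation_freq_hz Carrier frequency of the within-state
#'   oscillation; default 10 Hz (eyes-closed alpha), giving GFP peaks every
#'   ~50 ms.
#' @param snr Signal-to-noise ratio, defined as the RMS of the noise-free
#'   signal divided by the RMS of the band-limited additive noise over the
#'   epoch; `Inf` disables noise. Default 2 (moderate).
#' @param transition_matrix Optional 4 x 4 class-to-class transition
#'   probability matrix with zero diagonal and unit row sums; default uniform
#'   over the other three classes.
#' @param severity_slope_ms Optional monotone severity effect: each patient's
#'   class A mean duration is shifted by `severity_slope_ms * severity`.
#'   Default 0 (severity independent of dynamics, as in resting studies that
#'   found no severity correlation); set positive to power-test the Spearman
#'   severity stage.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects_per_group = 18,
                         epochs_per_subject = c(18, 61),
                         sampling_rate = 200,
                         epoch_samples = 512,
                         class_mean_duration_ms = default_duration_means(),
                         class_duration_sd_ms = default_duration_sds(),
                         oscillation_freq_hz = 10,
                         snr = 2,
                         transition_matrix = NULL,
                         severity_slope_ms = 0,
                         seed = 1L) {
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / 3, 4, 4,
                                dimnames = list(MS_CLASSES, MS_CLASSES))
    diag(transition_matrix) <- 0
  }
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    epochs_per_subject = as.integer(epochs_per_subject),
    sampling_rate = sampling_rate,
    epoch_samples = as.integer(epoch_samples),
    class_mean_duration_ms = name_duration_matrix(class_mean_duration_ms),
    class_duration_sd_ms = name_duration_matrix(class_duration_sd_ms),
    oscillation_freq_hz = oscillation_freq_hz,
    snr = snr,
    transition_matrix = transition_matrix,
    severity_slope_ms = severity_slope_ms,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_duration_means <- function() {
  matrix(c(63.81, 58.47, 64.21, 83.40,
           54.55, 61.03, 66.63, 74.14),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("patient", "control"), MS_CLASSES))
}

#' @rdname synth_config
#' @export
default_duration_sds <- function() {
  matrix(c(14.71, 10.47, 18.92, 25.34,
           10.14, 13.75, 18.17, 17.62),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("patient", "control"), MS_CLASSES))
}

name_duration_matrix <- function(m) {
  m <- as.matrix(m)
  if (!identical(dim(m), c(2L, 4L))) {
    stop("duration matrices must be 2 groups x 4 classes", call. = FALSE)
  }
  dimnames(m) <- list(c("patient", "control"), MS_CLASSES)
  m
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_subjects_per_group >= 1,
            length(cfg$epochs_per_subject) %in% 1:2,
            all(cfg$epochs_per_subject >= 1),
            cfg$sampling_rate > 0, cfg$epoch_samples >= 3,
            identical(dim(cfg$class_mean_duration_ms), c(2L, 4L)),
            identical(dim(cfg$class_duration_sd_ms), c(2L, 4L)),
            all(cfg$class_mean_duration_ms > 0),
            all(cfg$class_duration_sd_ms >= 0),
            cfg$oscillation_freq_hz > 0,
            cfg$snr > 0)
  tm <- cfg$transition_matrix
  if (!identical(dim(tm), c(4L, 4L)) || any(diag(tm) != 0) ||
      any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0)) {
    stop("transition_matrix must be 4x4, nonnegative, zero diagonal, rows summing to 1",
         call. = FALSE)
  }
  invisible(cfg)
}

# truncated-normal draws via inverse CDF, truncation from below at `lower`
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

# analytic mean of the lower-truncated normal (used as test oracle and docs)
truncnorm_mean <- function(mean, sd, lower) {
  if (sd == 0) return(max(mean, lower))
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

#' Sample a planted microstate state sequence
#'
#' Draws an alternating sequence of microstate classes and durations that
#' exactly fills one epoch. Durations are drawn from a normal distribution
#' with the configured group-by-class mean/SD, truncated below at two
#' sampling intervals; successive classes always differ, with the next class
#' drawn from the configured transition matrix. The final state is truncated
#' so the total equals the epoch length.
#'
#' Uses the current R RNG state; seed externally (e.g. via
#' [generate_cohort()]) for reproducibility.
#'
#' @param config A [synth_config()].
#' @param group `"patient"` or `"control"`.
#' @param mean_override Optional length-4 vector overriding the group's class
#'   mean durations (used internally for severity effects).
#' @return A tibble with columns `class`, `n_samples`, `duration_ms`
#'   (realised duration from the sample count) and `drawn_ms` (the
#'   pre-discretisation draw), with `sum(n_samples) == epoch_samples`.
#' @export
sample_state_sequence <- function(config, group = c("patient", "control"),
                                  mean_override = NULL) {
  group <- match.arg(group)
  fs <- config$sampling_rate
  n_total <- config$epoch_samples
  lower_ms <- 2 * 1000 / fs
  means <- if (is.null(mean_override)) {
    config$class_mean_duration_ms[group, ]
  } else mean_override
  sds <- config$class_duration_sd_ms[group, ]
  tm <- config$transition_matrix

  cls <- integer(0)
  drawn <- numeric(0)
  nsamp <- integer(0)
  cur <- sample.int(4L, 1L)
  filled <- 0L
  while (filled < n_total) {
    d <- rtruncnorm_lower(1L, means[cur], sds[cur], lower_ms)
    ns <- max(2L, as.integer(round(d * fs / 1000)))
    ns <- min(ns, n_total - filled)
    cls <- c(cls, cur)
    drawn <- c(drawn, d)
    nsamp <- c(nsamp, ns)
    filled <- filled + ns
    cur <- sample.int(4L, 1L, prob = tm[cur, ])
  }
  tibble::tibble(
    class = MS_CLASSES[cls],
    n_samples = nsamp,
    duration_ms = nsamp * 1000 / fs,
    drawn_ms = unname(drawn)
  )
}

#' Render one synthetic EEG epoch from a state sequence
#'
#' Within each planted state the signal is the class prototype map modulated
#' by a sinusoidal carrier `a * sin(2*pi*f*t + phi)`, with amplitude and
#' phase drawn afresh at each state boundary (so the topography is fixed
#' within a state while its polarity inverts with the oscillation, and there
#' is no artificial continuity across state changes). Spatially white
#' Gaussian noise, band-limited to the analysis band (2-20 Hz) with the same
#' zero-phase filter used in preprocessing, is added and scaled so that
#' signal RMS / noise RMS equals `config$snr`; the epoch is then
#' average-referenced.
#'
#' @param sequence State sequence tibble from [sample_state_sequence()].
#' @param templates Prototype maps ([prototype_maps()]), rows A-D.
#' @param config A [synth_config()].
#' @return An [eeg_epoch()] of the configured geometry, with the planted
#'   per-sample class labels in attribute `true_labels`.
#' @export
render_epoch <- function(sequence, templates, config) {
  fs <- config$sampling_rate
  n_total <- config$epoch_samples
  if (sum(sequence$n_samples) != n_total) {
    stop("state sequence does not exactly fill the epoch", call. = FALSE)
  }
  tm <- as_template_matrix(templates)
  montage <- attr(templates, "montage")
  n_ch <- ncol(tm)
  base_amp <- 10 # uV scale of the oscillation envelope
  sig <- matrix(0, n_ch, n_total)
  labels <- character(n_total)
  pos <- 0L
  for (i in seq_len(nrow(sequence))) {
    ns <- sequence$n_samples[i]
    idx <- pos + seq_len(ns)
    tt <- (idx - 1) / fs
    a <- base_amp * runif(1, 0.5, 1.5)
    phi <- runif(1, 0, 2 * pi)
    wave <- a * sin(2 * pi * config$oscillation_freq_hz * tt + phi)
    sig[, idx] <- tm[sequence$class[i], ] %o% wave
    labels[idx] <- sequence$class[i]
    pos <- pos + ns
  }
  if (is.finite(config$snr)) {
    noise <- matrix(rnorm(n_ch * n_total), n_ch, n_total)
    noise <- bandpass_matrix(noise, 2, 20, fs)
    sig_rms <- sqrt(mean(sig^2))
    noise_rms <- sqrt(mean(noise^2))
    sig <- sig + noise * (sig_rms / (config$snr * noise_rms))
  }
  sig <- sweep(sig, 2, colMeans(sig))
  ep <- eeg_epoch(sig, fs, montage)
  attr(ep, "true_labels") <- labels
  ep
}

#' Generate a two-group synthetic EEG cohort
#'
#' Produces `n_subjects_per_group` subjects per group. Each subject gets an
#' epoch count drawn uniformly from the configured range, and each epoch is
#' an independently sampled state sequence rendered to multichannel EEG (see
#' [sample_state_sequence()], [render_epoch()]). Patients are assigned a
#' severity grade drawn uniformly from 1-4 (in partial remission = 1, mild =
#' 2, moderate = 3, severe = 4); controls have severity `NA`. The cohort is
#' fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param templates Prototype maps; default [prototype_maps()].
#' @return A tibble of class `ms_cohort`, one row per subject, with columns
#'   `subject_id`, `group`, `severity`, `n_epochs` and a list-column `epochs`
#'   of [eeg_epoch()] objects (each carrying its planted labels).
#' @export
generate_cohort <- function(config, templates = prototype_maps()) {
  validate_synth_config(config)
  withr::with_seed(config$seed, {
    rows <- purrr::map(c("patient", "control"), function(grp) {
      purrr::map(seq_len(config$n_subjects_per_group), function(i) {
        sid <- sprintf("%s%02d", substr(grp, 1, 1), i)
        sev <- if (grp == "patient") sample(1:4, 1) else NA_integer_
        mean_override <- NULL
        if (grp == "patient" && config$severity_slope_ms != 0) {
          mean_override <- config$class_mean_duration_ms[grp, ]
          mean_override[1] <- mean_override[1] + config$severity_slope_ms * sev
        }
        n_ep <- if (length(config$epochs_per_subject) == 2) {
          sample(seq(config$epochs_per_subject[1],
                     config$epochs_per_subject[2]), 1)
        } else config$epochs_per_subject
        eps <- purrr::map(seq_len(n_ep), function(e) {
          seqn <- sample_state_sequence(config, grp, mean_override)
          render_epoch(seqn, templates, config)
        })
        tibble::tibble(subject_id = sid, group = grp,
                       severity = sev, n_epochs = n_ep,
                       epochs = list(eps))
      })
    })
    cohort <- dplyr::bind_rows(purrr::flatten(rows))
  })
  cohort$group <- factor(cohort$group, levels = c("patient", "control"))
  class(cohort) <- c("ms_cohort", class(cohort))
  cohort
}
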