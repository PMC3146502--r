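#' Standard 16-channel 10-20 montage
#'
#' Returns the electrode montage used throughout the package: 16 scalp
#' positions of the International 10-20 System (Fp1, Fp2, F3, F4, Fz, F7, F8,
#' C3, C4, P3, P4, Pz, T5, T6, O1, O2) with schematic 2-D coordinates on the
#' unit disc. `x` is the left-right axis (right positive), `y` the
#' posterior-anterior axis (anterior positive); the head circumference is the
#' unit circle, nose up.
#'
#' @return A tibble of class `ms_montage` with columns `channel`, `x`, `y`.
#' @examples
#' montage_1020()
#' @export
montage_1020 <- function() {
  m <- tibble::tribble(
    ~channel,     ~x,     ~y,
    "Fp1",     -0.28,   0.86,
    "Fp2",      0.28,   0.86,
    "F3",      -0.34,   0.51,
    "F4",       0.34,   0.51,
    "Fz",       0.00,   0.45,
    "F7",      -0.73,   0.53,
    "F8",       0.73,   0.53,
    "C3",      -0.45,   0.00,
    "C4",       0.45,   0.00,
    "P3",      -0.34,  -0.51,
    "P4",       0.34,  -0.51,
    "Pz",       0.00,  -0.45,
    "T5",      -0.73,  -0.53,
    "T6",       0.73,  -0.53,
    "O1",      -0.28,  -0.86,
    "O2",       0.28,  -0.86
  )
  class(m) <- c("ms_montage", class(m))
  m
}

validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage),
            all(c("channel", "x", "y") %in% names(montage)))
  if (anyDuplicated(montage$channel) > 0) {
    stop("montage channel names must be unique", call. = FALSE)
  }
  if (any(montage$x^2 + montage$y^2 > 1 + 1e-12)) {
    stop("all montage positions must lie inside the unit disc", call. = FALSE)
  }
  invisible(montage)
}

#' Canonical microstate prototype topographies
#'
#' Builds the four canonical resting-state microstate map configurations as
#' smooth spatial patterns over the montage positions: class A a diagonal
#' gradient with its positive pole right-anterior (axis right-anterior to
#' left-posterior), class B the mirrored diagonal (left-anterior to
#' right-posterior), class C a symmetric anterior-posterior gradient, and
#' class D a fronto-central radial extreme. Each map is average-referenced
#' and scaled to unit norm; maps are defined only up to polarity.
#'
#' These serve both as planting targets for the synthetic-EEG generator and
#' as the default canonical references for letter assignment of empirical
#' group-mean maps.
#'
#' @param montage A montage tibble as returned by [montage_1020()].
#' @param k Number of prototypes; only `k = 4` is supported.
#' @return A `k` x n-channel matrix of class `ms_templates`, one unit-norm
#'   average-referenced map per row, rownames `A`-`D`.
#' @examples
#' protos <- prototype_maps()
#' rowSums(protos) # ~0: average-referenced
#' @export
prototype_maps <- function(montage = montage_1020(), k = 4) {
  validate_montage(montage)
  if (k != 4) {
    stop("only k = 4 canonical prototypes are defined; supply custom maps for other k",
         call. = FALSE)
  }
  x <- montage$x
  y <- montage$y
  # diagonal axes tilted toward lateral to keep A/B quasi-orthogonal to C
  ang <- 30 * pi / 180
  maps <- rbind(
    A = cos(ang) * x + sin(ang) * y,   # positive pole right-anterior
    B = -cos(ang) * x + sin(ang) * y,  # positive pole left-anterior
    C = y,                             # anterior-posterior
    D = exp(-((x - 0)^2 + (y - 0.35)^2) / (2 * 0.3^2)) # fronto-central blob
  )
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  colnames(maps) <- montage$channel
  structure(maps, class = c("ms_templates", "matrix", "array"),
            montage = montage)
}

as_template_matrix <- function(templates) {
  stopifnot(is.matrix(templates))
  unclass(templates)[, , drop = FALSE]
}
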