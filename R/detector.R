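# Detector response: frequency-dependent DQE filtering of the expected
# electron counts, then Poisson counting noise.

# DQE(q) = dqe0 * (1 - falloff * (q / qN)^2), clipped at >= 0
dqe_curve <- function(detector, q) {
  dqe0 <- detector$dqe$dqe0 %||% 1
  falloff <- detector$dqe$falloff %||% 0
  qn <- 1 / (2 * detector$pixel_size)
  pmax(dqe0 * (1 - falloff * (q / qn)^2), 0)
}

#' Apply the detector model to an intensity image
#'
#' Expected counts per pixel are `intensity * dose * pixel^2`; the DQE is
#' applied as a Fourier filter on the expected counts (so the expectation of
#' the output equals the DQE-filtered expectation, and total expected counts
#' scale with DQE(0)); Poisson noise is then drawn per pixel. Pixels whose
#' filtered expectation is negative (possible for a strongly band-limited
#' DQE) are clipped to zero; the number clipped is returned in the
#' `"clipped"` attribute.
#'
#' @param intensity Real matrix of relative intensities (unit incident
#'   intensity = 1).
#' @param detector Detector model: `nx`, `ny`, `pixel_size` (A), `dqe`
#'   (list with `dqe0` in (0,1] and `falloff`).
#' @param dose Incident electron dose for this image, e-/A^2 (>= 0).
#' @param seed Optional seed; NULL draws from the current RNG stream.
#' @param poisson Set FALSE to return the noise-free expected counts.
#' @return Matrix of electron counts with attribute `clipped`.
#' @export
apply_detector <- function(intensity, detector, dose, seed = NULL,
                           poisson = TRUE) {
  stopifnot(dose >= 0)
  expected <- intensity * dose * detector$pixel_size^2
  q <- freq_grid2(nrow(expected), ncol(expected), detector$pixel_size)
  expected <- fourier_filter(expected, dqe_curve(detector, q))
  nclip <- sum(expected < 0)
  expected[expected < 0] <- 0
  draw <- function() {
    if (!poisson) return(expected)
    matrix(stats::rpois(length(expected), expected),
           nrow(expected), ncol(expected))
  }
  counts <- if (!is.null(seed)) with_seed(seed, draw()) else draw()
  attr(counts, "clipped") <- nclip
  counts
}
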