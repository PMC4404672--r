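#' Bonferroni genome-wide significance threshold
#'
#' @param alpha experiment-wide type-I error rate in (0, 1).
#' @param n_tests number of tests (> 0; real-valued allowed).
#' @return per-test threshold alpha / n_tests.
#' @examples
#' bonferroni(0.05, 265487)  # 1.88e-07
#' @export
bonferroni <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (n_tests <= 0) stop("n_tests must be positive")
  alpha / n_tests
}

#' LD-adjusted significance threshold
#'
#' Correlated SNPs are not independent hypotheses, so the effective number
#' of tests is taken as the number of LD bins: genome size divided by the
#' average distance at which LD decays to background. The effective count is
#' kept real-valued. With a 730 Mb genome and 150 kb average LD extent the
#' cutoff lands near 1e-5.
#'
#' @param alpha experiment-wide type-I error rate.
#' @param genome_size_bp reference genome size in bp.
#' @param ld_extent_bp average LD extent in bp (see [ldDecayExtent()]).
#' @return per-test threshold alpha / (genome_size_bp / ld_extent_bp).
#' @examples
#' ldAdjustedThreshold(0.05, 730e6, 150e3)
#' @export
ldAdjustedThreshold <- function(alpha, genome_size_bp, ld_extent_bp) {
  stopifnot(alpha > 0, alpha < 1)
  if (ld_extent_bp <= 0) stop("ld_extent_bp must be positive")
  if (genome_size_bp < ld_extent_bp)
    stop("genome size must be at least the LD extent")
  bonferroni(alpha, genome_size_bp / ld_extent_bp)
}

#' Nearest power of ten of a positive number
#'
#' Convenience for reporting a threshold's order of magnitude.
#'
#' @param x positive number.
#' @return 10^round(log10(x)).
#' @export
nearestPowerOfTen <- function(x) {
  stopifnot(x > 0)
  10^round(log10(x))
}
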