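#' Average seed colors in RGB space
#'
#' Channel-wise arithmetic mean over seeds, rounded half-up to integers.
#' Averaging is done in RGB before any color-space conversion, matching the
#' phenotyping procedure of imaging several seeds per genotype and
#' converting the mean color.
#'
#' @param colors numeric matrix (seeds x 3, columns R, G, B) or data.frame
#'   with columns R, G, B; values in [0, 255].
#' @return integer vector c(R, G, B).
#' @export
averageSeedColor <- function(colors) {
  m <- as.matrix(as.data.frame(colors)[, c("R", "G", "B")])
  if (!nrow(m)) stop("at least one seed color is required")
  if (any(m < 0 | m > 255)) stop("RGB channels must be in [0, 255]")
  mu <- colMeans(m)
  as.integer(floor(mu + 0.5))  # round half-up
}

#' Convert sRGB to CIE-L*a*b* (D65, 2 degree observer)
#'
#' Standard chain: 8-bit sRGB -> gamma expansion -> linear RGB -> XYZ
#' (D65) -> L*a*b* with the piecewise cube-root transfer function and the
#' (6/29)^3 threshold.
#'
#' @param rgb numeric vector c(R, G, B) in [0, 255], or a matrix with one
#'   color per row.
#' @return numeric vector c(L, a, b) (or matrix, one row per input color):
#'   L in [0, 100], a and b signed.
#' @examples
#' rgbToLab(c(255, 255, 255))  # white: L = 100, a = b = 0
#' rgbToLab(c(255, 0, 0))      # sRGB red: about (53.24, 80.09, 67.20)
#' @export
rgbToLab <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, nrow = 1L)
  if (ncol(m) != 3L || any(m < 0 | m > 255))
    stop("expected RGB channels in [0, 255]")
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3L, byrow = TRUE)
  xyz <- lin %*% t(M)
  # D65 reference white as implied by the same matrix, so that
  # (255,255,255) maps to exactly L = 100, a = b = 0
  white <- as.numeric(M %*% c(1, 1, 1))
  names(white) <- c("X", "Y", "Z")
  t3 <- (6 / 29)^3
  f <- function(t) ifelse(t > t3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1L] / white["X"])
  fy <- f(xyz[, 2L] / white["Y"])
  fz <- f(xyz[, 3L] / white["Z"])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.matrix(rgb)) out else drop(out)
}

#' Phenotype a seed-color table
#'
#' Reads (or accepts) a per-seed color table, averages the seeds of each
#' genotype in RGB, and appends the CIE-L*a*b* conversion of the mean
#' color.
#'
#' @param seeds data.frame with columns \code{genotype_id},
#'   \code{seed_index}, \code{R}, \code{G}, \code{B}, or a path to such a
#'   TSV.
#' @return data.frame with one row per genotype: \code{genotype_id},
#'   \code{R}, \code{G}, \code{B}, \code{L}, \code{a}, \code{b}.
#' @export
colorPhenotypeTable <- function(seeds) {
  if (is.character(seeds))
    seeds <- utils::read.table(seeds, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  out <- lapply(split(seeds, seeds$genotype_id), function(g) {
    rgb <- averageSeedColor(g)
    lab <- rgbToLab(rgb)
    data.frame(genotype_id = g$genotype_id[1L], R = rgb[1L], G = rgb[2L],
               B = rgb[3L], L = lab[["L"]], a = lab[["a"]], b = lab[["b"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$genotype_id), , drop = FALSE]
}
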