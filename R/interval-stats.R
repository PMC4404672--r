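#' Tile a genetic map with fixed-width cM bins
#'
#' Each chromosome is tiled from its first marker's cM to its last with bins
#' of \code{width_cM}; the last bin per chromosome is truncated at the
#' chromosome's maximal cM. The default 30 cM approximates the width of a
#' biparental QTL likelihood interval, making the bin a natural unit for
#' asking whether selection signals and QTLs co-occupy the genome.
#'
#' @param map a [GeneticMap-class].
#' @param width_cM bin width in cM (default 30).
#' @return a [BinSet-class].
#' @export
makeBins <- function(map, width_cM = 30) {
  stopifnot(width_cM > 0)
  m <- mapMarkers(map)
  rows <- list()
  for (ch in unique(m$chrom)) {
    cm <- m$cM[m$chrom == ch]
    lo <- min(cm); hi <- max(cm)
    if (hi - lo < width_cM)
      warning("chromosome ", ch, " spans less than one bin width")
    starts <- seq(lo, hi, by = width_cM)
    if (starts[length(starts)] >= hi && length(starts) > 1L)
      starts <- starts[-length(starts)]
    rows[[ch]] <- data.frame(chrom = ch, start_cM = starts,
                             end_cM = pmin(starts + width_cM, hi),
                             stringsAsFactors = FALSE)
  }
  new("BinSet", bins = do.call(rbind, c(rows, make.row.names = FALSE)),
      width_cM = width_cM)
}

.mapped_markers <- function(map, chrom) {
  m <- mapMarkers(map)
  mc <- m[m$chrom == chrom & !is.na(m$bp), , drop = FALSE]
  if (nrow(mc) < 2L)
    stop("chromosome ", chrom, " has fewer than 2 physically mapped markers")
  mc
}

#' Interpolate between genetic and physical coordinates
#'
#' Piecewise-linear interpolation between the flanking aligned markers of a
#' genetic map; exact at markers. Queries outside the mapped range raise an
#' error (no silent extrapolation).
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name.
#' @param cM genetic position(s) to convert.
#' @return physical position(s) in bp.
#' @export
geneticToPhysical <- function(map, chrom, cM) {
  mc <- .mapped_markers(map, chrom)
  if (any(cM < min(mc$cM) | cM > max(mc$cM)))
    stop("cM query outside the mapped range of ", chrom,
         ": refusing to extrapolate")
  stats::approx(mc$cM, mc$bp, xout = cM, ties = "ordered")$y
}

#' @rdname geneticToPhysical
#' @param bp physical position(s) to convert.
#' @export
physicalToGenetic <- function(map, chrom, bp) {
  mc <- .mapped_markers(map, chrom)
  if (any(bp < min(mc$bp) | bp > max(mc$bp)))
    stop("bp query outside the mapped range of ", chrom,
         ": refusing to extrapolate")
  stats::approx(mc$bp, mc$cM, xout = bp, ties = "ordered")$y
}

#' Anchor a genetic interval to physical coordinates via flanking markers
#'
#' A QTL region is delineated by the two aligned flanking markers nearest
#' the likelihood peak: the left anchor is the aligned marker closest to
#' the peak with cM <= interval start (or, if none lies outside, the first
#' aligned marker inside the interval); the right anchor symmetrically.
#' Markers without physical alignment are skipped.
#'
#' @param map a [GeneticMap-class].
#' @param interval an [IntervalSet-class] in cM (single interval).
#' @param peak_cM position of the likelihood peak, inside the interval.
#' @return an [IntervalSet-class] in bp (single interval; trait preserved).
#' @export
anchorInterval <- function(map, interval, peak_cM) {
  iv <- intervals(interval)
  stopifnot(intervalUnit(interval) == "cM", nrow(iv) == 1L)
  if (peak_cM < iv$start || peak_cM > iv$end)
    stop("peak must lie inside the interval")
  mc <- .mapped_markers(map, iv$chrom)
  left_out <- mc[mc$cM <= iv$start, , drop = FALSE]
  left <- if (nrow(left_out)) {
    left_out[which.min(abs(left_out$cM - peak_cM)), ]
  } else {
    inside <- mc[mc$cM >= iv$start & mc$cM <= iv$end, , drop = FALSE]
    if (!nrow(inside)) stop("no aligned marker at or inside interval start")
    inside[1L, ]
  }
  right_out <- mc[mc$cM >= iv$end, , drop = FALSE]
  right <- if (nrow(right_out)) {
    right_out[which.min(abs(right_out$cM - peak_cM)), ]
  } else {
    inside <- mc[mc$cM >= iv$start & mc$cM <= iv$end, , drop = FALSE]
    if (!nrow(inside)) stop("no aligned marker at or inside interval end")
    inside[nrow(inside), ]
  }
  IntervalSet(data.frame(chrom = iv$chrom, start = left$bp, end = right$bp,
                         trait = iv$trait, source = "anchored"),
              unit = "bp")
}

.to_cM <- function(ivset, map) {
  iv <- intervals(ivset)
  if (intervalUnit(ivset) == "cM") return(iv)
  iv$start <- mapply(function(ch, x) physicalToGenetic(map, ch, x),
                     iv$chrom, iv$start)
  iv$end <- mapply(function(ch, x) physicalToGenetic(map, ch, x),
                   iv$chrom, iv$end)
  iv
}

#' Count bin occupancy by selection signals and QTL intervals
#'
#' A bin "has" a feature iff some feature interval overlaps it by a
#' positive cM length. Physical-coordinate interval sets are converted to
#' cM through the map first.
#'
#' @param bins a [BinSet-class].
#' @param selection an [IntervalSet-class] of selection-signature regions.
#' @param qtl an [IntervalSet-class] of QTL likelihood intervals.
#' @param map the [GeneticMap-class] used for bp -> cM conversion (needed
#'   when either set is in bp).
#' @return an [OverlapCounts-class].
#' @export
countOverlap <- function(bins, selection, qtl, map = NULL) {
  bn <- bins(bins)
  hit <- function(ivset) {
    iv <- if (intervalUnit(ivset) == "cM") intervals(ivset)
          else .to_cM(ivset, map)
    vapply(seq_len(nrow(bn)), function(k) {
      any(iv$chrom == bn$chrom[k] &
            pmin(iv$end, bn$end_cM[k]) - pmax(iv$start, bn$start_cM[k]) > 0)
    }, logical(1))
  }
  hl <- hit(selection); hs <- hit(qtl)
  OverlapCounts(n = nrow(bn), l = sum(hl), s = sum(hs), m = sum(hl & hs))
}

.log_hyper_pmf <- function(k, n, l, s) {
  lchoose(l, k) + lchoose(n - l, s - k) - lchoose(n, s)
}

#' Exact hypergeometric probability of the observed bin overlap
#'
#' Upper-tail probability that at least \code{m} of the \code{s} QTL bins
#' fall among the \code{l} selection bins when \code{s} bins are drawn
#' without replacement from \code{n}:
#' \deqn{P(X \ge m) = \sum_{k=m}^{\min(l,s)}
#'   \frac{\binom{l}{k}\binom{n-l}{s-k}}{\binom{n}{s}}}
#' Summation is done in log space for numerical stability.
#'
#' @param counts an [OverlapCounts-class].
#' @return upper-tail p-value in (0, 1].
#' @examples
#' hypergeomOverlapP(OverlapCounts(10, 5, 5, 5))  # 1/choose(10,5)
#' @export
hypergeomOverlapP <- function(counts) {
  stopifnot(is(counts, "OverlapCounts"))
  methods::validObject(counts)
  n <- counts@n; l <- counts@l; s <- counts@s; m <- counts@m
  if (m == 0L) return(1)
  ks <- m:min(l, s)
  lp <- .log_hyper_pmf(ks, n, l, s)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' @rdname hypergeomOverlapP
#' @param k overlap count at which to evaluate the point mass.
#' @return \code{hypergeomOverlapPmf}: P(X = k).
#' @export
hypergeomOverlapPmf <- function(counts, k = counts@m) {
  n <- counts@n; l <- counts@l; s <- counts@s
  if (k < max(0L, s - (n - l)) || k > min(l, s)) return(0)
  exp(.log_hyper_pmf(k, n, l, s))
}
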