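#' @describeIn GenotypeMatrix-class sites x samples integer dosage matrix.
#' @param x,object a \code{GenotypeMatrix}.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @export
setMethod("dosage", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypeMatrix-class named character vector of per-sample
#'   population labels.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @export
setMethod("populations", "GenotypeMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$population), rownames(cd))
})

#' @describeIn GenotypeMatrix-class number of SNP sites (rows).
#' @export
nSites <- function(x) nrow(x)

#' @describeIn GenotypeMatrix-class number of samples (columns).
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GenotypeMatrix-class data.frame of per-site chrom, pos, ref,
#'   alt.
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @export
setMethod("siteInfo", "GenotypeMatrix", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "GenotypeMatrix", function(object) {
  pops <- table(populations(object))
  cat("GenotypeMatrix:", nSites(object), "sites x", nSamples(object),
      "samples\n")
  cat("populations:",
      paste(sprintf("%s(%d)", names(pops), pops), collapse = ", "), "\n")
  d <- dosage(object)
  cat(sprintf("missing: %.1f%%\n", 100 * mean(is.na(d))))
})

#' @describeIn GeneticMap-class the marker table (marker, chrom, cM, bp).
#' @param x,object a \code{GeneticMap}.
#' @export
setGeneric("mapMarkers", function(x) standardGeneric("mapMarkers"))

#' @export
setMethod("mapMarkers", "GeneticMap", function(x) x@markers)

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat("GeneticMap:", nrow(m), "markers on", length(unique(m$chrom)),
      "chromosome(s);", sum(is.na(m$bp)), "without physical alignment\n")
})

#' @describeIn IntervalSet-class the interval table.
#' @param x,object an \code{IntervalSet}.
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @export
setMethod("intervals", "IntervalSet", function(x) x@intervals)

#' @describeIn IntervalSet-class coordinate unit ("bp" or "cM").
#' @export
setGeneric("intervalUnit", function(x) standardGeneric("intervalUnit"))

#' @export
setMethod("intervalUnit", "IntervalSet", function(x) x@unit)

setMethod("length", "IntervalSet", function(x) nrow(x@intervals))

setMethod("show", "IntervalSet", function(object) {
  cat("IntervalSet:", nrow(object@intervals), "interval(s) in",
      object@unit, "\n")
  if (nrow(object@intervals)) print(utils::head(object@intervals, 5L))
})

#' @describeIn WindowScan-class the per-window table.
#' @param x,object a \code{WindowScan}.
#' @export
setGeneric("scanWindows", function(x) standardGeneric("scanWindows"))

#' @export
setMethod("scanWindows", "WindowScan", function(x) x@windows)

#' @describeIn WindowScan-class percentile cutoff (NA until
#'   [topPercentileRegions()] is applied).
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))

#' @export
setMethod("cutoffValue", "WindowScan", function(x) x@cutoff)

setMethod("show", "WindowScan", function(object) {
  w <- object@windows
  cat("WindowScan:", nrow(w), "windows of", object@window_sites,
      "SNPs on", length(unique(w$chrom)), "chromosome(s)\n")
  if (nrow(w)) {
    fin <- w$ratio[!w$infinite]
    cat(sprintf("Hw/Hc ratio: median %.3f, max %s; %d infinite-flag\n",
                stats::median(fin),
                if (length(fin)) sprintf("%.3f", max(fin)) else "-",
                sum(w$infinite)))
  }
  if (!is.na(object@cutoff))
    cat(sprintf("cutoff: %.4f\n", object@cutoff))
})

#' @describeIn BinSet-class the bin table (chrom, start_cM, end_cM).
#' @param x,object a \code{BinSet}.
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @export
setMethod("bins", "BinSet", function(x) x@bins)

setMethod("length", "BinSet", function(x) nrow(x@bins))

setMethod("show", "BinSet", function(object) {
  cat("BinSet:", nrow(object@bins), "bins of", object@width_cM, "cM on",
      length(unique(object@bins$chrom)), "chromosome(s)\n")
})

setMethod("show", "OverlapCounts", function(object) {
  cat(sprintf("OverlapCounts: n=%d bins, l=%d selection, s=%d QTL, m=%d both\n",
              object@n, object@l, object@s, object@m))
})

setMethod("show", "HaplotypeProfile", function(object) {
  cat("HaplotypeProfile:", object@population, "-", length(object@sites),
      "sites,", length(object@pair_haplotypes), "consecutive pairs\n")
})

setMethod("show", "SharingResult", function(object) {
  cat(sprintf("SharingResult %s-%s: shared %d / union %d = %.3f\n",
              object@pop_pair[1], object@pop_pair[2], object@shared,
              object@union_count, object@ratio))
})

#' @describeIn SharingResult-class the shared/union ratio.
#' @param x,object a \code{SharingResult}.
#' @export
setGeneric("sharingRatio", function(x) standardGeneric("sharingRatio"))

#' @export
setMethod("sharingRatio", "SharingResult", function(x) x@ratio)
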