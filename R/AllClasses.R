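#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData assay
NULL

MISSING_DOSAGE <- NA_integer_

#' Genotype matrix with population labels and site coordinates
#'
#' A \code{GenotypeMatrix} holds biallelic SNP genotypes as alt-allele dosages
#' (0, 1, 2 or \code{NA} for missing) in a
#' \linkS4class{RangedSummarizedExperiment}: sites are rows (a
#' \code{GRanges} with \code{ref}/\code{alt} metadata columns), samples are
#' columns, and each sample carries exactly one population label in
#' \code{colData()$population}. Within each chromosome site positions are
#' strictly increasing.
#'
#' @slot .  inherits all slots from \code{RangedSummarizedExperiment}; the
#'   single assay is named \code{"dosage"}.
#' @seealso [GenotypeMatrix()] for construction, [dosage()], [populations()],
#'   [filterSites()]
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  else if (anyNA(SummarizedExperiment::colData(object)$population))
    msg <- c(msg, "every sample needs a population label")
  rr <- SummarizedExperiment::rowRanges(object)
  if (!all(c("ref", "alt") %in% colnames(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' metadata columns")
  pos <- GenomicRanges::start(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix, sites x samples, values in \{0, 1, 2, NA\}.
#' @param chrom character vector of per-site chromosome names.
#' @param pos integer vector of per-site physical positions (bp, 1-based).
#' @param ref,alt character vectors of reference/alternate alleles.
#' @param sample_ids character vector naming the columns of \code{dosage}.
#' @param populations named character vector (or unnamed, parallel to
#'   \code{sample_ids}) assigning each sample to a population.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 2L, 1L, 0L), 2),
#'                      chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                      ref = c("A", "C"), alt = c("G", "T"),
#'                      sample_ids = c("s1", "s2"),
#'                      populations = c(s1 = "wild", s2 = "durra"))
#' nSites(gm)
#' @export
GenotypeMatrix <- function(dosage, chrom, pos, ref, alt, sample_ids,
                           populations) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(names(populations))) {
    stopifnot(length(populations) == length(sample_ids))
    names(populations) <- sample_ids
  }
  missing_lab <- setdiff(sample_ids, names(populations))
  if (length(missing_lab))
    stop("samples without population label: ",
         paste(missing_lab, collapse = ", "))
  extra <- setdiff(names(populations), sample_ids)
  if (length(extra))
    stop("unknown sample in population labels: ",
         paste(extra, collapse = ", "))
  rr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L),
                ref = as.character(ref), alt = as.character(alt))
  names(rr) <- paste0("S", chrom, "_", pos)
  colnames(dosage) <- sample_ids
  rownames(dosage) <- names(rr)
  se <- SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = rr,
    colData = DataFrame(population = unname(populations[sample_ids]),
                        row.names = sample_ids))
  new("GenotypeMatrix", se)
}

#' Genetic map: markers with paired genetic and physical positions
#'
#' Markers with a genetic position (cM) and, for aligned markers, a physical
#' position (bp; \code{NA} when the marker lacks genome alignment). Within
#' each chromosome cM is non-decreasing and bp (over aligned markers) is
#' strictly increasing; at least two markers per chromosome.
#'
#' @slot markers data.frame with columns \code{marker}, \code{chrom},
#'   \code{cM}, \code{bp}.
#' @seealso [GeneticMap()], [geneticToPhysical()], [makeBins()],
#'   [anchorInterval()]
#' @export
setClass("GeneticMap", representation(markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  m <- object@markers
  need <- c("marker", "chrom", "cM", "bp")
  if (!all(need %in% names(m)))
    return(paste("markers needs columns:", paste(need, collapse = ", ")))
  msg <- character()
  for (ch in unique(m$chrom)) {
    mc <- m[m$chrom == ch, ]
    if (nrow(mc) < 2L)
      msg <- c(msg, sprintf("chromosome %s has fewer than 2 markers", ch))
    if (is.unsorted(mc$cM))
      msg <- c(msg, sprintf("cM not non-decreasing on %s", ch))
    bp <- mc$bp[!is.na(mc$bp)]
    if (length(bp) > 1L && any(diff(bp) <= 0)) {
      i <- which(diff(bp) <= 0)[1L]
      off <- mc$marker[!is.na(mc$bp)][i + 1L]
      msg <- c(msg, sprintf("bp not strictly increasing on %s at marker %s",
                            ch, off))
    }
  }
  if (any(m$cM < 0, na.rm = TRUE)) msg <- c(msg, "cM must be >= 0")
  if (any(m$bp < 1, na.rm = TRUE)) msg <- c(msg, "bp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param markers data.frame with columns \code{marker}, \code{chrom},
#'   \code{cM}, \code{bp} (bp may be NA for unaligned markers).
#' @rdname GeneticMap-class
#' @export
GeneticMap <- function(markers) {
  markers <- as.data.frame(markers)
  markers$marker <- as.character(markers$marker)
  markers$chrom <- as.character(markers$chrom)
  markers$cM <- as.numeric(markers$cM)
  markers$bp <- as.numeric(markers$bp)
  ord <- order(markers$chrom, markers$cM,
               ifelse(is.na(markers$bp), Inf, markers$bp))
  new("GeneticMap", markers = markers[ord, , drop = FALSE])
}

#' Trait-labelled genomic or genetic intervals
#'
#' A collection of intervals on one coordinate system: physical (\code{bp},
#' 1-based closed internally, BED I/O is 0-based half-open) or genetic
#' (\code{cM}). Each interval carries a \code{trait} and a \code{source}
#' label.
#'
#' @slot intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{trait}, \code{source}.
#' @slot unit \code{"bp"} or \code{"cM"}.
#' @seealso [IntervalSet()], [readIntervals()], [writeBed()], [countOverlap()]
#' @export
setClass("IntervalSet",
         representation(intervals = "data.frame", unit = "character"))

setValidity("IntervalSet", function(object) {
  iv <- object@intervals
  need <- c("chrom", "start", "end", "trait", "source")
  if (!all(need %in% names(iv)))
    return(paste("intervals needs columns:", paste(need, collapse = ", ")))
  if (!object@unit %in% c("bp", "cM"))
    return("unit must be 'bp' or 'cM'")
  if (any(iv$start > iv$end))
    return("interval start must be <= end")
  TRUE
})

#' @param intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end} and optionally \code{trait}, \code{source}.
#' @param unit coordinate unit, \code{"bp"} or \code{"cM"}.
#' @rdname IntervalSet-class
#' @export
IntervalSet <- function(intervals, unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  iv <- as.data.frame(intervals)
  if (is.null(iv$trait)) iv$trait <- "."
  if (is.null(iv$source)) iv$source <- "."
  iv$chrom <- as.character(iv$chrom)
  iv$start <- as.numeric(iv$start)
  iv$end <- as.numeric(iv$end)
  new("IntervalSet",
      intervals = iv[, c("chrom", "start", "end", "trait", "source")],
      unit = unit)
}

#' Windowed wild/cultivated heterozygosity-ratio scan
#'
#' Result of [hetRatioScan()]: per window of a fixed number of consecutive
#' SNPs, the mean expected heterozygosity in the wild group (\code{Hw}), in
#' the cultivated group (\code{Hc}), and their ratio \code{Hw/Hc}. Windows
#' where \code{Hc} is exactly 0 are flagged infinite and rank above all
#' finite ratios. \code{cutoff} is filled by [topPercentileRegions()].
#'
#' @slot windows data.frame with columns \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{first_site}, \code{n_sites}, \code{Hw}, \code{Hc},
#'   \code{ratio}, \code{infinite}.
#' @slot window_sites integer window size (consecutive SNPs).
#' @slot cutoff numeric percentile cutoff, \code{NA} until set.
#' @export
setClass("WindowScan",
         representation(windows = "data.frame", window_sites = "integer",
                        cutoff = "numeric"))

setValidity("WindowScan", function(object) {
  w <- object@windows
  need <- c("chrom", "start_bp", "end_bp", "first_site", "n_sites",
            "Hw", "Hc", "ratio", "infinite")
  if (!all(need %in% names(w)))
    return(paste("windows needs columns:", paste(need, collapse = ", ")))
  if (nrow(w) && !all(w$n_sites == object@window_sites))
    return("every window must contain exactly window_sites sites")
  TRUE
})

#' Fixed-width genetic bins tiling a map
#'
#' Bins of \code{width_cM} centimorgans tiling each chromosome of a genetic
#' map from its first to its last marker; the last bin per chromosome may be
#' truncated. Operand of the hypergeometric overlap test.
#'
#' @slot bins data.frame with columns \code{chrom}, \code{start_cM},
#'   \code{end_cM}.
#' @slot width_cM nominal bin width in cM.
#' @export
setClass("BinSet",
         representation(bins = "data.frame", width_cM = "numeric"))

#' Bin occupancy counts for the overlap test
#'
#' \code{n} total genetic bins, \code{l} bins holding a selection signal,
#' \code{s} bins holding a QTL interval, \code{m} bins holding both.
#'
#' @slot n,l,s,m integer counts with \code{0 <= m <= min(l, s)} and
#'   \code{l, s <= n}.
#' @seealso [countOverlap()], [hypergeomOverlapP()]
#' @export
setClass("OverlapCounts",
         representation(n = "integer", l = "integer", s = "integer",
                        m = "integer"))

setValidity("OverlapCounts", function(object) {
  n <- object@n; l <- object@l; s <- object@s; m <- object@m
  if (any(c(n, l, s, m) < 0L)) return("counts must be non-negative")
  if (l > n || s > n) return("l and s cannot exceed n")
  if (m > min(l, s)) return("m cannot exceed min(l, s)")
  TRUE
})

#' @param n,l,s,m total bins, bins with selection signal, bins with QTL,
#'   bins with both.
#' @rdname OverlapCounts-class
#' @export
OverlapCounts <- function(n, l, s, m) {
  new("OverlapCounts", n = as.integer(n), l = as.integer(l),
      s = as.integer(s), m = as.integer(m))
}

#' Two-locus haplotype profile of one population
#'
#' For an ordered SNP set, the multiset of two-locus haplotypes observed at
#' each consecutive site pair. Only individuals homozygous and non-missing
#' at both sites of a pair contribute (phasing-free; appropriate for highly
#' inbreeding species), each contributing the ordered pair of its homozygous
#' alleles, coded \code{"R"} (ref) / \code{"A"} (alt).
#'
#' @slot population population label.
#' @slot sites integer site indices (into the source GenotypeMatrix), in
#'   position order.
#' @slot pair_haplotypes list, one named integer count vector per consecutive
#'   pair; names are haplotype codes like \code{"R-A"}.
#' @seealso [buildProfile()], [commonHaplotypeRatio()]
#' @export
setClass("HaplotypeProfile",
         representation(population = "character", sites = "integer",
                        pair_haplotypes = "list"))

setValidity("HaplotypeProfile", function(object) {
  if (length(object@pair_haplotypes) != max(0L, length(object@sites) - 1L))
    return("need one haplotype multiset per consecutive site pair")
  counts <- unlist(object@pair_haplotypes)
  if (length(counts) && any(counts < 1L))
    return("recorded haplotype counts must be >= 1")
  TRUE
})

#' Haplotype-sharing ratio between two populations
#'
#' Pooled over consecutive site pairs: \code{shared} distinct two-locus
#' haplotype types observed in both populations, \code{union} types observed
#' in either; \code{ratio = shared / union}. Symmetric in population order.
#'
#' @slot pop_pair the two population labels.
#' @slot shared,union_count integer type counts summed over pairs.
#' @slot ratio sharing ratio in [0, 1].
#' @export
setClass("SharingResult",
         representation(pop_pair = "character", shared = "integer",
                        union_count = "integer", ratio = "numeric"))

setValidity("SharingResult", function(object) {
  if (object@union_count < 1L) return("union count must be >= 1")
  if (abs(object@ratio - object@shared / object@union_count) > 1e-12)
    return("ratio must equal shared / union")
  TRUE
})
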