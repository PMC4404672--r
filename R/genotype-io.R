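#' Read sample-to-population labels
#'
#' Two-column TSV (\code{sample_id}, \code{population}) with header.
#'
#' @param path file path.
#' @return named character vector, names = sample ids.
#' @export
readPopulationLabels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  stats::setNames(tab$population, tab$sample_id)
}

#' @rdname readPopulationLabels
#' @param labels named character vector.
#' @export
writePopulationLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), population = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.gt_to_dosage <- function(gt) {
  # GT field only; any half-call or missing allele -> NA
  gt <- sub(":.*", "", gt)
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (length(a) != 2L || any(a == ".") || any(!a %in% c("0", "1")))
      return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF genotypes (GT field) are converted to alt-allele dosage; half-calls
#' and \code{./.} become missing. The dosage TSV dialect has columns
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt} followed by one column
#' per sample (NA = missing).
#'
#' @param path genotype file.
#' @param format \code{"vcf"} or \code{"dosage"}.
#' @param pop_labels path to a population-labels TSV (see
#'   [readPopulationLabels()]) or a named character vector. Must cover every
#'   genotyped sample.
#' @param multiallelic \code{"reject"} (default; error on any site with more
#'   than one ALT allele) or \code{"drop"} (remove such sites with a
#'   warning). Splitting is not offered: it would duplicate physical
#'   positions and break the strictly-increasing-position invariant.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage"), pop_labels,
                          multiallelic = c("reject", "drop")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (is.character(pop_labels) && length(pop_labels) == 1L &&
      file.exists(pop_labels))
    pop_labels <- readPopulationLabels(pop_labels)

  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    chrom <- fix[, "CHROM"]
    pos <- as.integer(fix[, "POS"])
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (any(multi)) {
      if (multiallelic == "reject")
        stop(sum(multi), " multiallelic site(s); use multiallelic='drop'")
      warning("dropping ", sum(multi), " multiallelic site(s)")
      keep <- !multi
      chrom <- chrom[keep]; pos <- pos[keep]
      ref <- ref[keep]; alt <- alt[keep]
      gt <- gt[keep, , drop = FALSE]
    }
    d <- apply(gt, 2L, .gt_to_dosage)
    if (is.null(dim(d))) d <- matrix(d, nrow = 1L,
                                     dimnames = list(NULL, colnames(gt)))
    sample_ids <- colnames(gt)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    meta <- c("chrom", "pos", "ref", "alt")
    stopifnot(all(meta %in% names(tab)))
    sample_ids <- setdiff(names(tab), meta)
    chrom <- as.character(tab$chrom)
    pos <- as.integer(tab$pos)
    ref <- tab$ref; alt <- tab$alt
    d <- as.matrix(tab[, sample_ids, drop = FALSE])
    storage.mode(d) <- "integer"
  }

  unlabeled <- setdiff(sample_ids, names(pop_labels))
  if (length(unlabeled))
    stop("samples missing from population labels: ",
         paste(unlabeled, collapse = ", "))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("format error: positions not strictly increasing on ", ch)
  }
  GenotypeMatrix(d, chrom, pos, ref, alt, sample_ids,
                 pop_labels[sample_ids])
}

#' Write a genotype matrix to VCF or dosage TSV
#'
#' The VCF writer emits a minimal VCF 4.2 body with a GT-only FORMAT;
#' dosages 0/1/2 become \code{0/0}, \code{0/1}, \code{1/1} and missing
#' becomes \code{./.}.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file.
#' @param format \code{"vcf"} or \code{"dosage"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(gm, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  si <- siteInfo(gm)
  d <- dosage(gm)
  if (format == "vcf") {
    gt <- matrix("./.", nrow(d), ncol(d))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
    header <- c("##fileformat=VCFv4.2",
                "##source=domescan",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(d)),
                      collapse = "\t"))
    body <- paste(si$chrom, si$pos, rownames(d), si$ref, si$alt, ".", ".",
                  ".", "GT", apply(gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(header, body), path)
  } else {
    tab <- cbind(si, as.data.frame(d, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Per-site alternate-allele frequency and call counts
#'
#' Frequencies use non-missing calls only (complete case per site).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param samples optional character vector restricting to a sample subset.
#' @return data.frame with columns \code{p_alt} (NA when no calls) and
#'   \code{n_called}.
#' @export
siteFrequencies <- function(gm, samples = NULL) {
  d <- dosage(gm)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  n_called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  data.frame(p_alt = p, n_called = n_called, row.names = NULL)
}

#' Filter sites on missingness and minor-allele frequency
#'
#' Retains sites whose missing-call fraction is at most
#' \code{max_missing_rate} and whose minor-allele frequency, computed over
#' non-missing calls, is at least \code{min_maf}. Site order and the sample
#' set are unchanged. Idempotent.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param max_missing_rate maximum tolerated missing fraction per site.
#' @param min_maf minimum minor-allele frequency (default 0.02 retains
#'   informative SNPs).
#' @return the filtered [GenotypeMatrix-class] (possibly 0 sites, with a
#'   warning).
#' @export
filterSites <- function(gm, max_missing_rate = 0.5, min_maf = 0.02) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  d <- dosage(gm)
  miss <- rowMeans(is.na(d))
  sf <- siteFrequencies(gm)
  maf <- pmin(sf$p_alt, 1 - sf$p_alt)
  keep <- miss <= max_missing_rate & !is.na(maf) & maf >= min_maf
  if (!any(keep)) warning("no sites pass the filters")
  gm[keep, ]
}

#' Read / write a genetic map
#'
#' TSV with header columns \code{marker}, \code{chrom}, \code{cM},
#' \code{bp}; \code{bp} may be NA for markers lacking physical alignment.
#'
#' @param path file path.
#' @return a [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  GeneticMap(tab)
}

#' @rdname readGeneticMap
#' @param map a [GeneticMap-class].
#' @export
writeGeneticMap <- function(map, path) {
  utils::write.table(mapMarkers(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read trait intervals (BED for bp, TSV for cM)
#'
#' Physical intervals use BED (0-based half-open on disk; converted to the
#' 1-based closed internal convention): columns chrom, start, end, and
#' optionally name (trait) and source. Genetic intervals use a header-less
#' TSV with the same column order, coordinates in cM taken as-is.
#'
#' @param path file path.
#' @param unit \code{"bp"} or \code{"cM"}.
#' @return an [IntervalSet-class].
#' @export
readIntervals <- function(path, unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  tab$trait <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else "."
  tab$source <- if (ncol(tab) >= 5L) as.character(tab[[5L]]) else "."
  if (unit == "bp") tab$start <- tab$start + 1L  # BED 0-based half-open
  IntervalSet(tab[, c("chrom", "start", "end", "trait", "source")], unit)
}

#' Write intervals as BED (bp) or TSV (cM)
#'
#' @param iv an [IntervalSet-class].
#' @param path output file.
#' @param score optional numeric vector written as a 5th column
#'   (chrom, start, end, trait, score).
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(iv, path, score = NULL) {
  tab <- intervals(iv)
  start <- if (intervalUnit(iv) == "bp") tab$start - 1L else tab$start
  out <- data.frame(chrom = tab$chrom, start = start, end = tab$end,
                    trait = tab$trait)
  out$score <- if (is.null(score)) tab$source else score
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
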