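#' Select the peak-linked SNP set for haplotype analysis
#'
#' Returns the association peak plus every site in the region whose
#' composite LD with the peak satisfies \code{r2 >= r2_min}, ordered by
#' physical position. This mirrors the peak + linked-SNP construction used
#' to probe haplotype structure around a GWAS hotspot.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param peak_site site index of the association peak.
#' @param region an [IntervalSet-class] in bp (single interval) containing
#'   the peak.
#' @param r2_min linkage threshold (default 0.6).
#' @return ordered integer vector of site indices (peak always included).
#' @export
selectLinkedSnps <- function(gm, peak_site, region, r2_min = 0.6) {
  iv <- intervals(region)
  stopifnot(intervalUnit(region) == "bp", nrow(iv) == 1L)
  si <- siteInfo(gm)
  if (si$chrom[peak_site] != iv$chrom ||
      si$pos[peak_site] < iv$start || si$pos[peak_site] > iv$end)
    stop("peak site must lie inside the region")
  cand <- which(si$chrom == iv$chrom & si$pos >= iv$start &
                  si$pos <= iv$end)
  peak_d <- dosage(gm)[peak_site, ]
  sdv <- stats::sd(peak_d, na.rm = TRUE)
  if (is.na(sdv) || sdv == 0)
    stop("peak site is monomorphic: cannot select linked SNPs")
  linked <- vapply(cand, function(j) {
    if (j == peak_site) return(TRUE)
    r2 <- tryCatch(ldR2(gm, peak_site, j), error = function(e) NA_real_)
    !is.na(r2) && r2 >= r2_min
  }, logical(1))
  sel <- cand[linked]
  sel[order(si$pos[sel])]
}

#' Select the first n sites of a region
#'
#' Companion selector for the fixed-count mode (e.g. the first 100 SNPs of
#' a 200 kb region next to a candidate gene).
#'
#' @inheritParams selectLinkedSnps
#' @param n number of sites to take, in position order.
#' @return ordered integer vector of site indices.
#' @export
selectRegionSnps <- function(gm, region, n) {
  iv <- intervals(region)
  stopifnot(intervalUnit(region) == "bp", nrow(iv) == 1L)
  si <- siteInfo(gm)
  cand <- which(si$chrom == iv$chrom & si$pos >= iv$start &
                  si$pos <= iv$end)
  cand <- cand[order(si$pos[cand])]
  utils::head(cand, n)
}

#' Build a population's two-locus haplotype profile
#'
#' For each consecutive pair of the ordered site list, every individual of
#' the population that is homozygous and non-missing at both sites
#' contributes one two-locus haplotype: the ordered pair of its homozygous
#' alleles, coded "R" (ref, dosage 0) or "A" (alt, dosage 2). Individuals
#' heterozygous or missing at either site are skipped for that pair only —
#' a phasing-free rule suited to largely inbreeding species.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param sites ordered integer site indices (>= 2).
#' @param population population label.
#' @return a [HaplotypeProfile-class].
#' @export
buildProfile <- function(gm, sites, population) {
  sites <- as.integer(sites)
  stopifnot(length(sites) >= 2L)
  smp <- .pop_samples(gm, population)
  d <- dosage(gm)[sites, smp, drop = FALSE]
  code <- matrix(NA_character_, nrow(d), ncol(d))
  code[!is.na(d) & d == 0L] <- "R"
  code[!is.na(d) & d == 2L] <- "A"
  pairs <- vector("list", length(sites) - 1L)
  for (k in seq_len(length(sites) - 1L)) {
    a <- code[k, ]; b <- code[k + 1L, ]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) {
      warning("no homozygous individual at site pair ", k,
              " in population ", population)
      pairs[[k]] <- integer(0)
    } else {
      tab <- table(paste(a[ok], b[ok], sep = "-"))
      pairs[[k]] <- stats::setNames(as.integer(tab), names(tab))
    }
  }
  new("HaplotypeProfile", population = as.character(population)[1L],
      sites = sites, pair_haplotypes = pairs)
}

#' Common-haplotype sharing ratio between two populations
#'
#' Pooled over consecutive site pairs: the count of distinct two-locus
#' haplotype types present in both populations (shared) over the count
#' present in either (union). Pairs empty in both populations contribute
#' nothing. A type-based, frequency-free statistic: ratio 1 iff the
#' per-pair type sets coincide, 0 iff they are disjoint everywhere.
#'
#' @param a,b [HaplotypeProfile-class] objects over the same site list.
#' @return a [SharingResult-class].
#' @export
commonHaplotypeRatio <- function(a, b) {
  if (!identical(a@sites, b@sites))
    stop("profiles must be built on the same site list")
  shared <- 0L; uni <- 0L
  for (k in seq_along(a@pair_haplotypes)) {
    ta <- names(a@pair_haplotypes[[k]])
    tb <- names(b@pair_haplotypes[[k]])
    shared <- shared + length(intersect(ta, tb))
    uni <- uni + length(union(ta, tb))
  }
  if (uni == 0L) stop("no haplotype observed in either population")
  new("SharingResult", pop_pair = c(a@population, b@population),
      shared = shared, union_count = uni, ratio = shared / uni)
}

#' Sharing ratios for every population pair
#'
#' @param gm a [GenotypeMatrix-class].
#' @param sites ordered site indices (see [selectLinkedSnps()] /
#'   [selectRegionSnps()]).
#' @param pops character vector of >= 2 population labels.
#' @return data.frame with one row per unordered pair: \code{popA},
#'   \code{popB}, \code{shared}, \code{union}, \code{ratio}.
#' @export
sharingMatrix <- function(gm, sites, pops) {
  stopifnot(length(pops) >= 2L)
  profs <- lapply(pops, function(p) buildProfile(gm, sites, p))
  names(profs) <- pops
  rows <- list()
  for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
    sr <- commonHaplotypeRatio(profs[[i]], profs[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      popA = pops[i], popB = pops[j], shared = sr@shared,
      union = sr@union_count, ratio = sr@ratio, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
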