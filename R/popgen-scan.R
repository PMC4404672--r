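#' Expected heterozygosity of a biallelic site
#'
#' H = 2p(1 - p), the probability that two alleles drawn at random differ.
#' Maximal (0.5) at p = 0.5 and symmetric under p <-> 1 - p.
#'
#' @param p_alt alternate-allele frequency (vectorised).
#' @param n_called number of non-missing calls backing each frequency; a
#'   site with no calls has no defined frequency and raises an error.
#' @return numeric vector of H in [0, 0.5].
#' @examples
#' expectedHet(0.5)   # 0.5
#' expectedHet(0.1)   # 0.18
#' @export
expectedHet <- function(p_alt, n_called = NULL) {
  if (!is.null(n_called) && any(n_called == 0L))
    stop("expected heterozygosity undefined at sites with no calls")
  if (any(p_alt < 0 | p_alt > 1, na.rm = TRUE))
    stop("allele frequency outside [0, 1]")
  2 * p_alt * (1 - p_alt)
}

.pop_samples <- function(gm, pops) {
  labs <- populations(gm)
  smp <- names(labs)[labs %in% pops]
  if (!length(smp))
    stop("no samples in population(s): ", paste(pops, collapse = ", "))
  smp
}

#' Windowed wild/cultivated heterozygosity-ratio scan
#'
#' Tiles each chromosome with consecutive non-overlapping windows of exactly
#' \code{window_sites} SNPs (the trailing remainder is dropped) and computes,
#' per window, the mean per-site expected heterozygosity in the wild group
#' (\code{Hw}), in the pooled cultivated group (\code{Hc}), and the ratio
#' \code{Hw/Hc}. Sites with no calls in a group are excluded from that
#' group's mean. Windows with \code{Hc = 0} are flagged infinite; they rank
#' above every finite ratio in percentile calling, total loss of cultivated
#' diversity being the strongest sweep signal.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param wild_pop population label of the wild group.
#' @param cultivated_pops character vector of cultivated population labels
#'   (pooled).
#' @param window_sites SNPs per window (default 500).
#' @return a [WindowScan-class].
#' @export
hetRatioScan <- function(gm, wild_pop, cultivated_pops, window_sites = 500L) {
  window_sites <- as.integer(window_sites)
  stopifnot(window_sites >= 1L)
  wild <- .pop_samples(gm, wild_pop)
  cult <- .pop_samples(gm, cultivated_pops)
  si <- siteInfo(gm)
  hw <- expectedHet(siteFrequencies(gm, wild)$p_alt)
  hc <- expectedHet(siteFrequencies(gm, cult)$p_alt)

  rows <- list()
  for (ch in unique(si$chrom)) {
    idx <- which(si$chrom == ch)
    nw <- length(idx) %/% window_sites
    if (nw == 0L) next
    for (k in seq_len(nw)) {
      wi <- idx[((k - 1L) * window_sites + 1L):(k * window_sites)]
      Hw <- mean(hw[wi], na.rm = TRUE)
      Hc <- mean(hc[wi], na.rm = TRUE)
      inf <- is.finite(Hw) && Hw > 0 && Hc == 0
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = si$pos[wi[1L]],
        end_bp = si$pos[wi[length(wi)]], first_site = wi[1L],
        n_sites = window_sites, Hw = Hw, Hc = Hc,
        ratio = if (Hc > 0) Hw / Hc else if (inf) Inf else NaN,
        infinite = inf, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no chromosome holds ", window_sites, " sites: empty scan")
  new("WindowScan", windows = do.call(rbind, rows),
      window_sites = window_sites, cutoff = NA_real_)
}

#' Call top-percentile selection-signature regions from a scan
#'
#' The cutoff is the \code{1 - top_fraction} empirical quantile of the
#' window ratios (infinite-flag windows count as larger than every finite
#' ratio). Windows with ratio >= cutoff qualify (ties kept); adjacent
#' qualifying windows on a chromosome are merged into one physical interval.
#'
#' @param scan a [WindowScan-class].
#' @param top_fraction e.g. 0.05 (top 5\%) or 0.01 (top 1\%).
#' @return list with \code{cutoff} (numeric), \code{regions} (an
#'   [IntervalSet-class] in bp, one per merged run, with the run's maximal
#'   ratio in \code{source}), and \code{scan} (the input scan with its
#'   cutoff slot filled).
#' @export
topPercentileRegions <- function(scan, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  w <- scanWindows(scan)
  if (!nrow(w)) stop("empty scan")
  r <- w$ratio
  r[w$infinite] <- Inf
  ok <- !is.nan(r)
  cutoff <- stats::quantile(r[ok], 1 - top_fraction, names = FALSE, type = 7)
  if (is.nan(cutoff)) cutoff <- Inf  # interpolation hit an infinite ratio
  qual <- ok & r >= cutoff

  regs <- list()
  for (ch in unique(w$chrom)) {
    i <- which(w$chrom == ch & qual)
    if (!length(i)) next
    runs <- split(i, cumsum(c(1L, diff(i) != 1L)))
    for (rn in runs) {
      regs[[length(regs) + 1L]] <- data.frame(
        chrom = ch, start = w$start_bp[rn[1L]],
        end = w$end_bp[rn[length(rn)]], trait = "selection",
        source = format(max(r[rn]), digits = 6), stringsAsFactors = FALSE)
    }
  }
  scan@cutoff <- cutoff
  list(cutoff = cutoff,
       regions = IntervalSet(do.call(rbind, regs), "bp"),
       scan = scan)
}

.hudson_site <- function(p1, p2, m1, m2) {
  # m1, m2: sampled allele counts; per-site numerator/denominator
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  cbind(num, den)
}

.wc_site <- function(d1, d2) {
  # Weir & Cockerham (1984) theta components for one biallelic site,
  # two populations, diploid, using observed heterozygosity
  r <- 2
  n1 <- sum(!is.na(d1)); n2 <- sum(!is.na(d2))
  p1 <- mean(d1, na.rm = TRUE) / 2; p2 <- mean(d2, na.rm = TRUE) / 2
  h1 <- mean(d1 == 1L, na.rm = TRUE); h2 <- mean(d2 == 1L, na.rm = TRUE)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, d = a + b + cc)
}

#' Fixation index between two populations
#'
#' Default is Hudson's estimator as a ratio of averages across sites:
#' \deqn{\hat F_{ST} = \frac{\sum_i N_i}{\sum_i D_i}, \quad
#'   N_i = (p_{1i}-p_{2i})^2 - \frac{p_{1i}(1-p_{1i})}{m_{1i}-1}
#'        - \frac{p_{2i}(1-p_{2i})}{m_{2i}-1}, \quad
#'   D_i = p_{1i}(1-p_{2i}) + p_{2i}(1-p_{1i})}
#' with \eqn{p} the sample allele frequencies and \eqn{m} the sampled allele
#' counts. Robust to unequal sample sizes; negative estimates are reported
#' as computed. \code{estimator = "wc"} gives the Weir-Cockerham theta
#' (ratio of summed variance components) as a secondary option.
#'
#' Sites where either population has no calls (or fewer than 2 sampled
#' alleles) are excluded.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param popA,popB population labels (each may name several labels, pooled).
#' @param estimator \code{"hudson"} (default) or \code{"wc"}.
#' @return the F_ST estimate (scalar).
#' @export
fst <- function(gm, popA, popB, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  sa <- .pop_samples(gm, popA)
  sb <- .pop_samples(gm, popB)
  d <- dosage(gm)
  da <- d[, sa, drop = FALSE]
  db <- d[, sb, drop = FALSE]
  na <- rowSums(!is.na(da)); nb <- rowSums(!is.na(db))
  use <- na >= 1L & nb >= 1L & (2 * na) >= 2L & (2 * nb) >= 2L
  if (!any(use)) stop("no site usable in both populations")

  if (estimator == "hudson") {
    use <- na >= 1L & nb >= 1L & (2 * na) > 1L & (2 * nb) > 1L
    p1 <- rowSums(da, na.rm = TRUE) / (2 * na)
    p2 <- rowSums(db, na.rm = TRUE) / (2 * nb)
    nd <- .hudson_site(p1[use], p2[use], 2 * na[use], 2 * nb[use])
    den <- sum(nd[, 2L])
    if (den == 0) stop("no polymorphic site usable in both populations")
    sum(nd[, 1L]) / den
  } else {
    comp <- vapply(which(use), function(i) .wc_site(da[i, ], db[i, ]),
                   numeric(2))
    den <- sum(comp[2L, ], na.rm = TRUE)
    if (den == 0) stop("no polymorphic site usable in both populations")
    sum(comp[1L, ], na.rm = TRUE) / den
  }
}

#' Pairwise F_ST matrix over populations
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels (default: all).
#' @inheritParams fst
#' @return symmetric numeric matrix of pairwise estimates (diagonal 0).
#' @export
fstMatrix <- function(gm, pops = NULL, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  if (is.null(pops)) pops <- sort(unique(populations(gm)))
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k >= 2L)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      out[i, j] <- out[j, i] <- fst(gm, pops[i], pops[j], estimator)
  out
}

#' Composite linkage disequilibrium r-squared between two sites
#'
#' Squared Pearson correlation of the dosage vectors over samples called at
#' both sites (composite LD; no phasing needed). Invariant to ref/alt
#' relabeling (dosage flip 2 - d). Undefined (NA) when either site is
#' monomorphic over the complete pairs.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param site_i,site_j site indices (rows of \code{gm}).
#' @return r^2 in [0, 1], or NA when undefined.
#' @export
ldR2 <- function(gm, site_i, site_j) {
  d <- dosage(gm)
  x <- d[site_i, ]; y <- d[site_j, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 complete sample pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Pairwise r-squared over a site set
#'
#' @param gm a [GenotypeMatrix-class].
#' @param sites site indices.
#' @return data.frame with columns \code{site_i}, \code{site_j},
#'   \code{distance_bp}, \code{r2} for all unordered pairs (same-chromosome
#'   distance; NA distance across chromosomes).
#' @export
ldMatrix <- function(gm, sites) {
  sites <- as.integer(sites)
  d <- t(dosage(gm)[sites, , drop = FALSE])  # samples x sites
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  si <- siteInfo(gm)
  pr <- which(upper.tri(r2), arr.ind = TRUE)
  i <- sites[pr[, 1L]]; j <- sites[pr[, 2L]]
  same <- si$chrom[i] == si$chrom[j]
  data.frame(site_i = i, site_j = j,
             distance_bp = ifelse(same, abs(si$pos[j] - si$pos[i]), NA),
             r2 = r2[pr], row.names = NULL)
}

#' Distance at which LD decays to background
#'
#' Computes pairwise r^2 within a per-chromosome distance horizon, averages
#' it in distance bins of \code{bin_bp}, and returns the left edge of the
#' first bin whose mean r^2 drops below \code{background_r2}. If no bin
#' does, the horizon is returned with \code{reached_background = FALSE}.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param background_r2 background LD level (default 0.1).
#' @param bin_bp distance-bin width in bp (default 10 kb).
#' @param horizon_bp maximum pair distance considered (default 1 Mb).
#' @return list with \code{extent_bp}, \code{reached_background}, and the
#'   per-bin table \code{bins} (left edge, mean r2, n pairs).
#' @export
ldDecayExtent <- function(gm, background_r2 = 0.1, bin_bp = 10000L,
                          horizon_bp = 1000000L) {
  si <- siteInfo(gm)
  edges <- seq(0L, horizon_bp, by = bin_bp)
  nbin <- length(edges) - 1L
  sums <- numeric(nbin); ns <- integer(nbin)
  for (ch in unique(si$chrom)) {
    idx <- which(si$chrom == ch)
    if (length(idx) < 2L) next
    d <- t(dosage(gm)[idx, , drop = FALSE])
    keep <- apply(d, 2L, function(v) stats::sd(v, na.rm = TRUE) > 0)
    keep[is.na(keep)] <- FALSE
    if (sum(keep) < 2L) next
    d <- d[, keep, drop = FALSE]
    pos <- si$pos[idx][keep]
    r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(r2), arr.ind = TRUE)
    dist <- abs(pos[pr[, 2L]] - pos[pr[, 1L]])
    v <- r2[pr]
    ok <- dist < horizon_bp & !is.na(v)
    b <- pmin(dist[ok] %/% bin_bp + 1L, nbin)
    agg <- tapply(v[ok], b, sum)
    sums[as.integer(names(agg))] <- sums[as.integer(names(agg))] + agg
    tab <- table(b)
    ns[as.integer(names(tab))] <- ns[as.integer(names(tab))] +
      as.integer(tab)
  }
  if (!sum(ns)) stop("no polymorphic site pair within the horizon")
  meanr2 <- ifelse(ns > 0L, sums / ns, NA_real_)
  below <- which(!is.na(meanr2) & meanr2 < background_r2)
  reached <- length(below) > 0L
  extent <- if (reached) edges[below[1L]] else horizon_bp
  list(extent_bp = extent, reached_background = reached,
       bins = data.frame(left_bp = edges[seq_len(nbin)], mean_r2 = meanr2,
                         n_pairs = ns))
}

#' Write a window scan as TSV and its signature regions as BED
#'
#' @param scan a [WindowScan-class].
#' @param path output TSV (chrom, start, end, n_sites, Hw, Hc, ratio, flag).
#' @return \code{path}, invisibly.
#' @export
writeScanTsv <- function(scan, path) {
  w <- scanWindows(scan)
  out <- data.frame(chrom = w$chrom, start = w$start_bp, end = w$end_bp,
                    n_sites = w$n_sites,
                    Hw = sprintf("%.6g", w$Hw), Hc = sprintf("%.6g", w$Hc),
                    ratio = sprintf("%.6g", w$ratio),
                    flag = ifelse(w$infinite, "inf", "."))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
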