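# Small deterministic fixtures built in code.

# Genotype matrix from a sites x samples dosage matrix on one chromosome.
gm_fixture <- function(dos, pops, chrom = "chr01",
                       pos = seq_len(nrow(dos)) * 1000L) {
  dos <- as.matrix(dos)
  ids <- sprintf("s%02d", seq_len(ncol(dos)))
  if (is.null(names(pops))) names(pops) <- ids
  GenotypeMatrix(dos, chrom = rep(chrom, nrow(dos)), pos = pos,
                 ref = rep("A", nrow(dos)), alt = rep("G", nrow(dos)),
                 sample_ids = ids, populations = pops)
}

# Random dosage matrix with controlled missingness (seeded by caller).
random_dosage <- function(n_sites, n_samples, p = NULL, miss = 0) {
  if (is.null(p)) p <- runif(n_sites, 0.05, 0.95)
  d <- matrix(rbinom(n_sites * n_samples, 2L, rep(p, n_samples)),
              nrow = n_sites)
  if (miss > 0) d[runif(length(d)) < miss] <- NA_integer_
  d
}

# Uniform two-chromosome genetic map fixture.
map_fixture <- function(chroms = c("chr01", "chr02"), span_cM = 90,
                        span_bp = 9e6, n_markers = 10L) {
  GeneticMap(do.call(rbind, lapply(chroms, function(ch) data.frame(
    marker = sprintf("%s_m%d", ch, seq_len(n_markers)), chrom = ch,
    cM = seq(0, span_cM, length.out = n_markers),
    bp = round(seq(1, span_bp, length.out = n_markers))))))
}

# Independent brute-force oracle for the two-locus sharing ratio:
# plain loops over individuals and consecutive pairs.
oracle_sharing <- function(dosA, dosB) {
  types_of <- function(d) {
    lapply(seq_len(nrow(d) - 1L), function(k) {
      out <- character(0)
      for (i in seq_len(ncol(d))) {
        a <- d[k, i]; b <- d[k + 1L, i]
        if (!is.na(a) && !is.na(b) && a %in% c(0L, 2L) && b %in% c(0L, 2L))
          out <- c(out, paste(ifelse(a == 0L, "R", "A"),
                              ifelse(b == 0L, "R", "A"), sep = "-"))
      }
      unique(out)
    })
  }
  ta <- types_of(dosA); tb <- types_of(dosB)
  sh <- 0L; un <- 0L
  for (k in seq_along(ta)) {
    sh <- sh + length(intersect(ta[[k]], tb[[k]]))
    un <- un + length(union(ta[[k]], tb[[k]]))
  }
  list(shared = sh, union = un, ratio = sh / un)
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail,
# straight from binomial coefficients.
oracle_hyper_tail <- function(n, l, s, m) {
  ks <- m:min(l, s)
  sum(choose(l, ks) * choose(n - l, s - ks)) / choose(n, s)
}
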