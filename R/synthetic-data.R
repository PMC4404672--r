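#' Simulation configuration for synthetic domestication cohorts
#'
#' Declares a multi-population genotype simulation with founder-block LD,
#' Balding-Nichols population differentiation, high selfing, and planted
#' selective sweeps. The defaults emulate a domestication panel: one
#' higher-diversity wild population of 31 accessions plus five cultivated
#' races totalling 471, largely inbreeding (selfing 0.95), with
#' divergence levels spanning the weakly differentiated (wild-bicolor)
#' through strongly differentiated (kafir) range and ~150 kb LD blocks.
#'
#' @param n_chromosomes number of chromosomes.
#' @param sites_per_chromosome SNP sites per chromosome.
#' @param chrom_length_bp physical chromosome length (bp).
#' @param chrom_length_cM genetic chromosome length (cM).
#' @param populations data.frame with columns \code{label},
#'   \code{n_samples}, \code{F_divergence} (Balding-Nichols F in (0, 1)),
#'   \code{selfing_rate} in [0, 1].
#' @param block_length_bp LD block scale: founder haplotypes are drawn per
#'   block of this length and individuals copy whole-block founders, so
#'   LD is strong within a block and absent between blocks.
#' @param n_founders founder haplotypes per block per population.
#'   Few founders give strong within-block LD; \code{Inf} draws each
#'   haplotype directly from the population allele frequencies (the plain
#'   Balding-Nichols limit, no LD).
#' @param sweep_specs list of sweeps, each a list with elements
#'   \code{pops} (labels swept), \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{diversity_retention} in [0, 1] (0 = complete
#'   fixation), \code{haplotype_id} (sweeps sharing an id fix the same
#'   haplotype; distinct ids model independent domestication events).
#' @param missing_rate per-call missing probability.
#' @param markers_per_chromosome evenly spaced genetic-map markers.
#' @param seed integer seed governing all randomness.
#' @return validated config list of class \code{"simConfig"}.
#' @export
simConfig <- function(n_chromosomes = 10L,
                      sites_per_chromosome = 2000L,
                      chrom_length_bp = 70e6,
                      chrom_length_cM = 140,
                      populations = data.frame(
                        label = c("wild", "bicolor", "guinea", "caudatum",
                                  "durra", "kafir"),
                        n_samples = c(31L, 100L, 95L, 90L, 95L, 91L),
                        F_divergence = c(0.02, 0.05, 0.12, 0.18, 0.28, 0.4),
                        selfing_rate = 0.95),
                      block_length_bp = 150e3,
                      n_founders = 6L,
                      sweep_specs = list(),
                      missing_rate = 0,
                      markers_per_chromosome = 21L,
                      seed = 1L) {
  pops <- as.data.frame(populations)
  stopifnot(n_chromosomes >= 1L, sites_per_chromosome >= 1L,
            chrom_length_bp > 0, chrom_length_cM > 0,
            all(c("label", "n_samples", "F_divergence", "selfing_rate")
                %in% names(pops)),
            all(pops$F_divergence > 0), all(pops$F_divergence < 1),
            all(pops$selfing_rate >= 0), all(pops$selfing_rate <= 1),
            block_length_bp > 0, missing_rate >= 0, missing_rate < 1,
            markers_per_chromosome >= 2L)
  for (sw in sweep_specs) {
    stopifnot(all(c("pops", "chrom", "start_bp", "end_bp",
                    "diversity_retention", "haplotype_id") %in% names(sw)),
              sw$diversity_retention >= 0, sw$diversity_retention <= 1,
              sw$start_bp >= 1, sw$end_bp <= chrom_length_bp,
              all(sw$pops %in% pops$label))
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 sites_per_chromosome = as.integer(sites_per_chromosome),
                 chrom_length_bp = chrom_length_bp,
                 chrom_length_cM = chrom_length_cM,
                 populations = pops, block_length_bp = block_length_bp,
                 n_founders = n_founders, sweep_specs = sweep_specs,
                 missing_rate = missing_rate,
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 seed = as.integer(seed)),
            class = "simConfig")
}

.rbeta_trunc <- function(n, a, b, lo = 0.05, hi = 0.95) {
  x <- stats::rbeta(n, a, b)
  while (any(out <- x < lo | x > hi))
    x[out] <- stats::rbeta(sum(out), a, b)
  x
}

#' Simulate a genotype cohort with planted truth
#'
#' Generates a [GenotypeMatrix-class], a matching uniform [GeneticMap-class]
#' and a truth record. Ancestral allele frequencies are Beta(0.8, 0.8)
#' truncated to [0.05, 0.95]; population frequencies follow the
#' Balding-Nichols model Beta(p(1-F)/F, (1-p)(1-F)/F). Within each LD
#' block of \code{block_length_bp}, \code{n_founders} founder haplotypes
#' are drawn per population and each individual's two block haplotypes copy
#' founders (identical with probability \code{selfing_rate}). Sweeps
#' replace a haplotype copy's alleles inside the sweep interval by the
#' sweep haplotype (drawn once per \code{haplotype_id} from the ancestral
#' frequencies, hence shareable across populations) with probability
#' \code{1 - diversity_retention}. Calls are masked at
#' \code{missing_rate}. All randomness derives from \code{config$seed}.
#'
#' @param config a [simConfig()] list.
#' @return list with elements \code{genotypes} ([GenotypeMatrix-class]),
#'   \code{map} ([GeneticMap-class]) and \code{truth} (list: per-population
#'   frequency matrices, sweep site-index ranges, founders, seed).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  pops <- config$populations
  n_tot <- sum(pops$n_samples)
  sample_ids <- unlist(lapply(seq_len(nrow(pops)), function(i)
    sprintf("%s_%03d", pops$label[i], seq_len(pops$n_samples[i]))))
  pop_of <- rep(pops$label, pops$n_samples)
  names(pop_of) <- sample_ids

  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  site_chrom <- character(0); site_pos <- integer(0)
  for (ch in chroms) {
    pos <- sort(sample.int(config$chrom_length_bp,
                           config$sites_per_chromosome))
    site_chrom <- c(site_chrom, rep(ch, length(pos)))
    site_pos <- c(site_pos, pos)
  }
  n_sites <- length(site_pos)

  p_anc <- .rbeta_trunc(n_sites, 0.8, 0.8)
  pop_freq <- matrix(NA_real_, n_sites, nrow(pops),
                     dimnames = list(NULL, pops$label))
  for (i in seq_len(nrow(pops))) {
    f <- pops$F_divergence[i]
    pop_freq[, i] <- stats::rbeta(n_sites, p_anc * (1 - f) / f,
                                  (1 - p_anc) * (1 - f) / f)
  }

  # sweep haplotypes: one allele vector per haplotype_id, shared across
  # populations, drawn from the ancestral frequencies
  hap_ids <- unique(vapply(config$sweep_specs, `[[`, "", "haplotype_id"))
  sweep_haps <- lapply(hap_ids, function(id)
    stats::rbinom(n_sites, 1L, p_anc))
  names(sweep_haps) <- hap_ids

  block_id <- paste0(site_chrom, "_b",
                     (site_pos - 1L) %/% config$block_length_bp)
  blocks <- split(seq_len(n_sites), factor(block_id, unique(block_id)))

  dos <- matrix(0L, n_sites, n_tot, dimnames = list(NULL, sample_ids))
  sweep_truth <- lapply(config$sweep_specs, function(sw) {
    idx <- which(site_chrom == sw$chrom & site_pos >= sw$start_bp &
                   site_pos <= sw$end_bp)
    c(sw, list(site_index = idx))
  })

  for (i in seq_len(nrow(pops))) {
    lab <- pops$label[i]
    cols <- which(pop_of == lab)
    n_ind <- length(cols)
    selfing <- pops$selfing_rate[i]
    sweeps_i <- Filter(function(sw) lab %in% sw$pops, sweep_truth)
    for (bl in blocks) {
      pf <- pop_freq[bl, i]
      nb <- length(bl)
      if (is.finite(config$n_founders)) {
        K <- as.integer(config$n_founders)
        founders <- matrix(stats::rbinom(K * nb, 1L, rep(pf, each = K)),
                           nrow = K)
        i1 <- sample.int(K, n_ind, replace = TRUE)
        i2 <- ifelse(stats::runif(n_ind) < selfing, i1,
                     sample.int(K, n_ind, replace = TRUE))
        h1 <- t(founders[i1, , drop = FALSE])
        h2 <- t(founders[i2, , drop = FALSE])
      } else {
        h1 <- matrix(stats::rbinom(nb * n_ind, 1L, pf), nrow = nb)
        h2 <- matrix(stats::rbinom(nb * n_ind, 1L, pf), nrow = nb)
        selfed <- stats::runif(n_ind) < selfing
        h2[, selfed] <- h1[, selfed]
      }
      for (sw in sweeps_i) {
        in_sw <- bl %in% sw$site_index
        if (!any(in_sw)) next
        hap <- sweep_haps[[sw$haplotype_id]][bl[in_sw]]
        p_fix <- 1 - sw$diversity_retention
        r1 <- stats::runif(n_ind) < p_fix
        r2 <- stats::runif(n_ind) < p_fix
        # individuals carrying identical copies stay homozygous under the
        # sweep as well
        ident <- if (is.finite(config$n_founders)) i1 == i2 else selfed
        r2[ident] <- r1[ident]
        h1[in_sw, r1] <- hap
        h2[in_sw, r2] <- hap
      }
      dos[bl, cols] <- h1 + h2
    }
  }

  if (config$missing_rate > 0) {
    mask <- stats::runif(length(dos)) < config$missing_rate
    dos[mask] <- NA_integer_
  }

  gm <- GenotypeMatrix(dos, site_chrom, site_pos,
                       ref = rep("A", n_sites), alt = rep("T", n_sites),
                       sample_ids = sample_ids, populations = pop_of)
  nm <- config$markers_per_chromosome
  mk <- do.call(rbind, lapply(chroms, function(ch) data.frame(
    marker = sprintf("%s_m%02d", ch, seq_len(nm)), chrom = ch,
    cM = seq(0, config$chrom_length_cM, length.out = nm),
    bp = round(seq(1, config$chrom_length_bp, length.out = nm)))))
  truth <- list(pop_freq = pop_freq, p_anc = p_anc, sweeps = sweep_truth,
                sweep_haplotypes = sweep_haps, site_chrom = site_chrom,
                site_pos = site_pos, config = config, seed = config$seed)
  list(genotypes = gm, map = GeneticMap(mk), truth = truth)
}

#' Simulate QTL likelihood intervals relative to planted sweeps
#'
#' Places \code{n_qtl} physical intervals: a fraction centred inside
#' randomly chosen planted sweep regions, the remainder uniform on the
#' genome. Which intervals overlap a sweep is recorded in the
#' \code{source} column (\code{"sweep"} / \code{"random"}).
#'
#' @param truth the \code{truth} element of [simulateCohort()].
#' @param n_qtl number of intervals.
#' @param fraction_overlapping_sweeps fraction placed onto sweeps.
#' @param width_bp interval width (default 5 Mb, a QTL-likelihood-interval
#'   scale).
#' @param seed integer seed.
#' @return an [IntervalSet-class] in bp.
#' @export
simulateIntervals <- function(truth, n_qtl, fraction_overlapping_sweeps,
                              width_bp = 5e6, seed = 1L) {
  stopifnot(fraction_overlapping_sweeps >= 0,
            fraction_overlapping_sweeps <= 1, n_qtl >= 0)
  if (n_qtl == 0L)
    return(IntervalSet(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), trait = character(0),
                                  source = character(0)), "bp"))
  set.seed(seed)
  cfg <- truth$config
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  n_sw <- round(n_qtl * fraction_overlapping_sweeps)
  if (n_sw > 0L && !length(truth$sweeps))
    stop("no planted sweeps to overlap")
  rows <- list()
  for (k in seq_len(n_qtl)) {
    if (k <= n_sw) {
      sw <- truth$sweeps[[sample.int(length(truth$sweeps), 1L)]]
      centre <- stats::runif(1, sw$start_bp, sw$end_bp)
      ch <- sw$chrom; src <- "sweep"
    } else {
      ch <- sample(chroms, 1L)
      centre <- stats::runif(1, 1, cfg$chrom_length_bp)
      src <- "random"
    }
    start <- max(1, centre - width_bp / 2)
    end <- min(cfg$chrom_length_bp, centre + width_bp / 2)
    rows[[k]] <- data.frame(chrom = ch, start = round(start),
                            end = round(end), trait = sprintf("qtl%02d", k),
                            source = src, stringsAsFactors = FALSE)
  }
  IntervalSet(do.call(rbind, rows), "bp")
}

#' Simulate per-seed RGB color tables
#'
#' Each genotype receives a palette color; each of its
#' \code{seeds_per_genotype} seeds is that color plus independent
#' Normal(0, noise_sd) channel noise, clipped to [0, 255] and rounded.
#'
#' @param n_genotypes number of genotypes.
#' @param palette numeric matrix (colors x 3) of RGB rows; genotypes cycle
#'   through it. Default: a pericarp-like white/yellow/red/brown range.
#' @param noise_sd channel noise standard deviation.
#' @param seeds_per_genotype seeds imaged per genotype (default 5).
#' @param seed integer seed.
#' @return list with \code{seeds} (data.frame genotype_id, seed_index, R,
#'   G, B) and \code{truth} (data.frame of each genotype's palette color).
#' @export
simulateSeedColors <- function(n_genotypes, palette = NULL, noise_sd = 5,
                               seeds_per_genotype = 5L, seed = 1L) {
  if (is.null(palette))
    palette <- matrix(c(240, 235, 220,   # white pericarp
                        215, 180,  90,   # yellow
                        150,  60,  40,   # red
                         90,  55,  35),  # brown
                      ncol = 3L, byrow = TRUE)
  set.seed(seed)
  stopifnot(n_genotypes >= 1L, noise_sd >= 0)
  assign_idx <- rep_len(seq_len(nrow(palette)), n_genotypes)
  ids <- sprintf("G%04d", seq_len(n_genotypes))
  rows <- list()
  for (g in seq_len(n_genotypes)) {
    base <- palette[assign_idx[g], ]
    for (s in seq_len(seeds_per_genotype)) {
      col <- round(pmin(255, pmax(0, base + stats::rnorm(3, 0, noise_sd))))
      rows[[length(rows) + 1L]] <- data.frame(
        genotype_id = ids[g], seed_index = s, R = col[1L], G = col[2L],
        B = col[3L], stringsAsFactors = FALSE)
    }
  }
  list(seeds = do.call(rbind, rows),
       truth = data.frame(genotype_id = ids, R = palette[assign_idx, 1L],
                          G = palette[assign_idx, 2L],
                          B = palette[assign_idx, 3L]))
}
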