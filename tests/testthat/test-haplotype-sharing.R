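region_fixture <- function(chrom = "chr01", start = 1, end = 1e6)
  IntervalSet(data.frame(chrom = chrom, start = start, end = end,
                         trait = "hap"), "bp")

test_that("peak-linked SNP selection applies the r2 threshold", {
  set.seed(31)
  peak <- rbinom(30L, 2L, 0.5)
  dos <- rbind(peak,
               peak,                        # exact copy -> r2 = 1
               2L - peak,                   # flipped copy -> r2 = 1
               rbinom(30L, 2L, 0.5),
               peak,                        # exact copy
               rbinom(30L, 2L, 0.5))
  gm <- gm_fixture(dos, rep("p", 30L))
  sel <- selectLinkedSnps(gm, 1L, region_fixture(), r2_min = 0.99)
  expect_true(1L %in% sel)
  expect_true(all(c(2L, 3L, 5L) %in% sel))
  expect_equal(sel, sort(sel))
  # singleton region containing only the peak
  gm1 <- gm_fixture(rbind(peak), rep("p", 30L))
  expect_equal(selectLinkedSnps(gm1, 1L, region_fixture(end = 1500)), 1L)
  # monomorphic peak is a selection error
  mono <- gm_fixture(rbind(rep(0L, 30L), peak), rep("p", 30L))
  expect_error(selectLinkedSnps(mono, 1L, region_fixture()), "monomorphic")
  # brute-force r2 filter agreement on block-structured data
  cfg <- simConfig(n_chromosomes = 1L, sites_per_chromosome = 300L,
                   chrom_length_bp = 2e6, chrom_length_cM = 50,
                   populations = data.frame(label = "p", n_samples = 40L,
                                            F_divergence = 0.1,
                                            selfing_rate = 0.9),
                   block_length_bp = 400e3, n_founders = 3L, seed = 9L)
  g <- simulateCohort(cfg)$genotypes
  pk <- 150L
  sel2 <- selectLinkedSnps(g, pk, region_fixture(end = 2e6), 0.6)
  d <- dosage(g)
  brute <- which(vapply(seq_len(nSites(g)), function(j) {
    r <- suppressWarnings(cor(d[pk, ], d[j, ]))
    !is.na(r) && r^2 >= 0.6
  }, logical(1)))
  expect_equal(sel2, sort(union(pk, brute)))
})

test_that("profiles take homozygotes only and skip hets per pair", {
  # one individual homozygous ref at 3 sites
  solo <- gm_fixture(matrix(0L, 3L, 1L), "p")
  pr <- buildProfile(solo, 1:3, "p")
  expect_equal(pr@pair_haplotypes, list(c("R-R" = 1L), c("R-R" = 1L)))
  # heterozygous middle site contributes to neither adjacent pair
  het <- gm_fixture(matrix(c(0L, 1L, 2L,
                             0L, 0L, 2L), 3L), c("p", "p"))
  suppressWarnings(pr2 <- buildProfile(het, 1:3, "p"))
  expect_equal(pr2@pair_haplotypes[[1L]], c("R-R" = 1L))
  expect_equal(pr2@pair_haplotypes[[2L]], c("R-A" = 1L))
  # empty pair warns
  allhet <- gm_fixture(matrix(1L, 2L, 2L), c("p", "p"))
  expect_warning(buildProfile(allhet, 1:2, "p"), "no homozygous")
  # 20-individual fixture equals brute-force enumeration
  set.seed(32)
  dos <- random_dosage(8L, 20L, miss = 0.15)
  gm <- gm_fixture(dos, rep("p", 20L))
  pr3 <- buildProfile(gm, 1:8, "p")
  for (k in 1:7) {
    cnt <- integer(0)
    for (i in 1:20) {
      a <- dos[k, i]; b <- dos[k + 1L, i]
      if (!is.na(a) && !is.na(b) && a %in% c(0L, 2L) && b %in% c(0L, 2L)) {
        key <- paste(ifelse(a == 0L, "R", "A"),
                     ifelse(b == 0L, "R", "A"), sep = "-")
        cnt[key] <- if (key %in% names(cnt)) cnt[[key]] + 1L else 1L
      }
    }
    expect_equal(pr3@pair_haplotypes[[k]], cnt[sort(names(cnt))],
                 ignore_attr = FALSE)
  }
})

test_that("sharing ratio matches hand and brute-force enumeration", {
  # worked 3-site example: pair1 A={RR,AA} B={RR}; pair2 A={RA} B={RA,AA}
  dosA <- matrix(c(0L, 0L, 2L,
                   2L, 2L, NA), nrow = 3L)
  dosB <- matrix(c(0L, 0L, 2L,
                   NA, 2L, 2L), nrow = 3L)
  gm <- gm_fixture(cbind(dosA, dosB), rep(c("A", "B"), each = 2L))
  pa <- buildProfile(gm, 1:3, "A")
  pb <- buildProfile(gm, 1:3, "B")
  sr <- commonHaplotypeRatio(pa, pb)
  expect_equal(sr@shared, 2L)
  expect_equal(sr@union_count, 4L)
  expect_equal(sharingRatio(sr), 0.5)
  # symmetric
  expect_equal(sharingRatio(commonHaplotypeRatio(pb, pa)), 0.5)
  # identical populations share everything
  same <- gm_fixture(cbind(dosA, dosA), rep(c("A", "B"), each = 2L))
  expect_equal(sharingRatio(commonHaplotypeRatio(
    buildProfile(same, 1:3, "A"), buildProfile(same, 1:3, "B"))), 1)
  # opposite fixed haplotypes are disjoint
  opp <- gm_fixture(cbind(matrix(0L, 3L, 2L), matrix(2L, 3L, 2L)),
                    rep(c("A", "B"), each = 2L))
  expect_equal(sharingRatio(commonHaplotypeRatio(
    buildProfile(opp, 1:3, "A"), buildProfile(opp, 1:3, "B"))), 0)
  # random 20-individual fixtures equal the loop oracle exactly
  for (s in 1:5) {
    set.seed(100 + s)
    dA <- random_dosage(10L, 20L, miss = 0.1)
    dB <- random_dosage(10L, 20L, miss = 0.1)
    g <- gm_fixture(cbind(dA, dB), rep(c("A", "B"), each = 20L))
    suppressWarnings({
      got <- commonHaplotypeRatio(buildProfile(g, 1:10, "A"),
                                  buildProfile(g, 1:10, "B"))
    })
    orc <- oracle_sharing(dA, dB)
    expect_equal(got@shared, orc$shared)
    expect_equal(got@union_count, orc$union)
  }
  # adding an individual whose haplotypes are already present in both
  # populations leaves the type-based ratio unchanged
  ext <- gm_fixture(cbind(dosA, dosA[, 1L], dosB),
                    c("A", "A", "A", "B", "B"))
  expect_equal(sharingRatio(commonHaplotypeRatio(
    buildProfile(ext, 1:3, "A"), buildProfile(ext, 1:3, "B"))), 0.5)
})

test_that("sharing matrix covers all pairs and separates shared from
           independent sweeps", {
  set.seed(33)
  dos <- random_dosage(6L, 30L)
  gm <- gm_fixture(dos, rep(c("a", "b", "c"), each = 10L))
  suppressWarnings(sm <- sharingMatrix(gm, 1:6, c("a", "b", "c")))
  expect_equal(nrow(sm), 3L)  # k(k-1)/2
  expect_true(all(sm$ratio >= 0 & sm$ratio <= 1))
  # two populations sweep the same haplotype, the third independently
  cfg <- simConfig(n_chromosomes = 1L, sites_per_chromosome = 400L,
                   chrom_length_bp = 4e6, chrom_length_cM = 50,
                   populations = data.frame(label = c("g", "d", "k"),
                                            n_samples = 25L,
                                            F_divergence = 0.15,
                                            selfing_rate = 0.95),
                   block_length_bp = 200e3, n_founders = 4L,
                   sweep_specs = list(
                     list(pops = c("g", "d"), chrom = "chr01",
                          start_bp = 1e6, end_bp = 3e6,
                          diversity_retention = 0.05,
                          haplotype_id = "shared"),
                     list(pops = "k", chrom = "chr01",
                          start_bp = 1e6, end_bp = 3e6,
                          diversity_retention = 0.05,
                          haplotype_id = "own")),
                   seed = 17L)
  sim <- simulateCohort(cfg)
  sites <- which(siteInfo(sim$genotypes)$pos >= 1e6 &
                   siteInfo(sim$genotypes)$pos <= 3e6)
  suppressWarnings(
    sm2 <- sharingMatrix(sim$genotypes, sites, c("g", "d", "k")))
  shared_pair <- sm2$ratio[sm2$popA == "g" & sm2$popB == "d"]
  indep <- sm2$ratio[sm2$popB == "k"]
  expect_true(all(shared_pair > indep))
})
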