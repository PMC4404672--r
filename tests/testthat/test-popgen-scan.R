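test_that("expected heterozygosity follows 2p(1-p)", {
  expect_equal(expectedHet(0.5), 0.5)
  expect_equal(expectedHet(0), 0)
  expect_equal(expectedHet(0.1), 0.18)
  p <- runif(50)
  expect_equal(expectedHet(p), expectedHet(1 - p))  # symmetry
  expect_true(all(expectedHet(p) <= expectedHet(0.5)))
  expect_error(expectedHet(0.5, n_called = 0L), "no calls")
  expect_error(expectedHet(1.2), "outside")
})

test_that("window scan tiles chromosomes and matches brute force", {
  set.seed(21)
  dos <- random_dosage(1500L, 24L)
  gm <- gm_fixture(dos, rep(c("wild", "durra", "kafir"), each = 8L))
  sc <- hetRatioScan(gm, "wild", c("durra", "kafir"), 500L)
  w <- scanWindows(sc)
  expect_equal(nrow(w), 3L)
  expect_equal(w$first_site, c(1L, 501L, 1001L))
  # brute-force per-window recomputation
  wild <- paste0("s", sprintf("%02d", 1:8))
  cult <- paste0("s", sprintf("%02d", 9:24))
  for (k in 1:3) {
    idx <- ((k - 1) * 500 + 1):(k * 500)
    hw <- hc <- numeric(0)
    for (i in idx) {
      dw <- dos[i, 1:8]; dc <- dos[i, 9:24]
      pw <- sum(dw, na.rm = TRUE) / (2 * sum(!is.na(dw)))
      pc <- sum(dc, na.rm = TRUE) / (2 * sum(!is.na(dc)))
      if (!is.nan(pw)) hw <- c(hw, 2 * pw * (1 - pw))
      if (!is.nan(pc)) hc <- c(hc, 2 * pc * (1 - pc))
    }
    expect_equal(w$Hw[k], mean(hw))
    expect_equal(w$Hc[k], mean(hc))
    expect_equal(w$ratio[k], mean(hw) / mean(hc))
  }
  # identical wild and cultivated groups give ratio 1 everywhere
  dup <- gm_fixture(cbind(dos[, 1:8], dos[, 1:8]),
                    rep(c("wild", "cult"), each = 8L))
  rw <- scanWindows(hetRatioScan(dup, "wild", "cult", 500L))
  expect_equal(rw$ratio, rep(1, 3))
  # remainder dropped, chromosomes not spanned
  expect_error(hetRatioScan(gm, "wild", "durra", 2000L), "empty scan")
})

test_that("top-percentile calling keeps ties and merges adjacent windows", {
  mk_scan <- function(ratios, inf = rep(FALSE, length(ratios))) {
    n <- length(ratios)
    new("WindowScan", windows = data.frame(
      chrom = "chr01", start_bp = seq_len(n) * 1000L,
      end_bp = seq_len(n) * 1000L + 500L, first_site = seq_len(n),
      n_sites = 1L, Hw = 1, Hc = 1, ratio = ratios, infinite = inf),
      window_sites = 1L, cutoff = NA_real_)
  }
  res <- topPercentileRegions(mk_scan(as.numeric(1:100)), 0.05)
  qual <- which(scanWindows(res$scan)$ratio >= res$cutoff)
  expect_equal(qual, 96:100)
  expect_equal(nrow(intervals(res$regions)), 1L)  # 96..100 adjacent, merged
  # degenerate: all ratios tie at the cutoff, all windows returned
  res2 <- topPercentileRegions(mk_scan(rep(2, 40)), 0.05)
  expect_equal(res2$cutoff, 2)
  expect_equal(intervals(res2$regions)$start, 1000)
  expect_equal(intervals(res2$regions)$end, 40 * 1000 + 500)
  # infinite-flag windows rank above all finite ratios
  r <- c(as.numeric(1:99), 5)
  res3 <- topPercentileRegions(mk_scan(r, c(rep(FALSE, 99), TRUE)), 0.01)
  w3 <- scanWindows(res3$scan)
  expect_true(intervals(res3$regions)$start == 100 * 1000)
  # quantile bracketing property
  for (f in c(0.01, 0.05, 0.25)) {
    rr <- runif(200)
    resf <- topPercentileRegions(mk_scan(rr), f)
    expect_lte(sum(rr > resf$cutoff), f * 200)
    expect_gte(sum(rr >= resf$cutoff), f * 200)
  }
})

test_that("F_ST estimator behaves at the boundaries and is symmetric", {
  # complete differentiation: fixed for alternative alleles
  dos <- cbind(matrix(0L, 20L, 10L), matrix(2L, 20L, 10L))
  gm <- gm_fixture(dos, rep(c("p1", "p2"), each = 10L))
  expect_equal(fst(gm, "p1", "p2"), 1)
  expect_equal(fst(gm, "p1", "p2", "wc"), 1)
  # duplicated population: no differentiation (small negative allowed)
  set.seed(5)
  d <- random_dosage(400L, 50L)
  same <- gm_fixture(cbind(d, d), rep(c("a", "b"), each = 50L))
  expect_lt(abs(fst(same, "a", "b")), 0.025)
  # symmetry under population swap
  set.seed(6)
  mixed <- gm_fixture(random_dosage(300L, 40L, miss = 0.1),
                      rep(c("a", "b"), each = 20L))
  expect_equal(fst(mixed, "a", "b"), fst(mixed, "b", "a"))
  expect_equal(fst(mixed, "a", "b", "wc"), fst(mixed, "b", "a", "wc"))
  expect_error(fst(gm_fixture(rbind(c(NA, NA, 0L, 0L)),
                              c("a", "a", "b", "b")), "a", "b"),
               "no site usable|no polymorphic")
})

test_that("composite r2 equals squared Pearson correlation of dosages", {
  gm <- gm_fixture(rbind(c(0L, 0L, 2L, 2L, 1L, 1L),
                         c(2L, 2L, 0L, 0L, 1L, 1L),
                         c(0L, 0L, 2L, 2L, 1L, 1L),
                         c(0L, 1L, 2L, 0L, 2L, 1L),
                         c(0L, 0L, 0L, 0L, 0L, 0L)),
                   rep("p", 6L))
  expect_equal(ldR2(gm, 1L, 3L), 1)            # identical vectors
  expect_equal(ldR2(gm, 1L, 2L), 1)            # perfect negative, squared
  d <- dosage(gm)
  expect_equal(ldR2(gm, 1L, 4L), cor(d[1L, ], d[4L, ])^2)
  expect_true(is.na(ldR2(gm, 1L, 5L)))         # monomorphic partner
  # invariant to ref/alt relabeling at one site
  flipped <- gm_fixture(rbind(d[1L, ], 2L - d[4L, ]), rep("p", 6L))
  expect_equal(ldR2(flipped, 1L, 2L), ldR2(gm, 1L, 4L))
  lm <- ldMatrix(gm, 1:4)
  expect_equal(nrow(lm), 6L)
  expect_equal(lm$r2[lm$site_i == 1L & lm$site_j == 4L], ldR2(gm, 1L, 4L))
  expect_equal(lm$distance_bp[1L], 1000L)
})

test_that("LD decay extent recovers the block length and flags no-decay", {
  # single haplotype repeated: r2 = 1 everywhere, horizon flagged
  hap <- rbinom(40L, 1L, 0.5)
  dos <- matrix(rep(2L * hap, 10L), ncol = 10L)
  dos <- cbind(dos, 2L - 2L * hap)  # one divergent sample keeps sites polymorphic
  gm <- gm_fixture(dos, rep("p", 11L), pos = seq_len(40L) * 5000L)
  res <- ldDecayExtent(gm, bin_bp = 50000L, horizon_bp = 200000L)
  expect_false(res$reached_background)
  expect_equal(res$extent_bp, 200000L)
  # founder blocks of length L: extent within one bin of L
  cfg <- simConfig(n_chromosomes = 1L, sites_per_chromosome = 2000L,
                   chrom_length_bp = 12e6, chrom_length_cM = 100,
                   populations = data.frame(label = "p", n_samples = 60L,
                                            F_divergence = 0.1,
                                            selfing_rate = 0.95),
                   block_length_bp = 150e3, n_founders = 2L, seed = 13L)
  g <- simulateCohort(cfg)$genotypes
  res2 <- ldDecayExtent(g, bin_bp = 75000L, horizon_bp = 600000L)
  expect_true(res2$reached_background)
  expect_lte(abs(res2$extent_bp - 150e3), 75000L)
  # independent sites: already below background in the first bin
  set.seed(8)
  ind <- gm_fixture(random_dosage(500L, 80L), rep("p", 80L),
                    pos = sort(sample.int(5e6, 500L)))
  res3 <- ldDecayExtent(ind, bin_bp = 100000L, horizon_bp = 1000000L)
  expect_equal(res3$extent_bp, 0L)
})
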