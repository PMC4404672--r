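test_that("genetic bins tile each chromosome with truncation", {
  m90 <- GeneticMap(data.frame(marker = c("a", "b"), chrom = "chr01",
                               cM = c(0, 90), bp = c(1, 9e6)))
  b90 <- makeBins(m90, 30)
  expect_equal(nrow(bins(b90)), 3L)
  expect_equal(bins(b90)$end_cM, c(30, 60, 90))
  m100 <- GeneticMap(data.frame(marker = c("a", "b"), chrom = "chr01",
                                cM = c(0, 100), bp = c(1, 1e7)))
  b100 <- makeBins(m100, 30)
  expect_equal(nrow(bins(b100)), 4L)
  expect_equal(bins(b100)$end_cM[4L] - bins(b100)$start_cM[4L], 10)
  # multi-chromosome count equals sum of per-chromosome ceil(span/width)
  set.seed(41)
  spans <- round(runif(10, 40, 160))
  mk <- GeneticMap(do.call(rbind, lapply(1:10, function(i) data.frame(
    marker = sprintf("c%d_%d", i, 1:2), chrom = sprintf("chr%02d", i),
    cM = c(0, spans[i]), bp = c(1, spans[i] * 1e5)))))
  expect_equal(nrow(bins(makeBins(mk, 30))), sum(ceiling(spans / 30)))
})

test_that("genetic-physical interpolation is exact at markers and
           invertible", {
  map <- GeneticMap(data.frame(marker = c("m1", "m2", "m3"),
                               chrom = "chr01", cM = c(0, 10, 20),
                               bp = c(5e5, 1e6, 3e6)))
  expect_equal(geneticToPhysical(map, "chr01", c(0, 10, 20)),
               c(5e5, 1e6, 3e6))
  expect_equal(geneticToPhysical(map, "chr01", 15), 2e6)  # midpoint
  expect_equal(physicalToGenetic(map, "chr01", 2e6), 15)
  set.seed(42)
  x <- runif(100, 0, 20)
  expect_equal(physicalToGenetic(map, "chr01",
                                 geneticToPhysical(map, "chr01", x)), x)
  expect_error(geneticToPhysical(map, "chr01", 25), "extrapolate")
  expect_error(physicalToGenetic(map, "chr01", 4e6), "extrapolate")
})

test_that("interval anchoring picks flanking aligned markers", {
  map <- GeneticMap(data.frame(
    marker = paste0("m", 1:6), chrom = "chr01",
    cM = c(0, 10, 20, 30, 40, 50),
    bp = c(1e5, 1e6, 2e6, NA, 4e6, 5e6)))  # m4 genetically mapped only
  iv <- IntervalSet(data.frame(chrom = "chr01", start = 12, end = 28,
                               trait = "PH"), "cM")
  got <- intervals(anchorInterval(map, iv, peak_cM = 20))
  expect_equal(got$start, 1e6)   # m2, nearest peak with cM <= 12
  expect_equal(got$end, 4e6)     # m5: m4 at 30 cM lacks alignment, skipped
  # endpoints exactly at aligned markers anchor to those markers
  iv2 <- IntervalSet(data.frame(chrom = "chr01", start = 10, end = 20,
                                trait = "PH"), "cM")
  got2 <- intervals(anchorInterval(map, iv2, peak_cM = 15))
  expect_equal(c(got2$start, got2$end), c(1e6, 2e6))
  # anchored interval contains the interpolated endpoint positions
  expect_lte(got$start, geneticToPhysical(map, "chr01", 12))
  expect_gte(got$end, geneticToPhysical(map, "chr01", 28))
  expect_error(anchorInterval(map, iv, peak_cM = 40), "inside")
})

test_that("bin occupancy counts match a brute-force scan", {
  map <- map_fixture(span_cM = 90, span_bp = 9e6)
  bn <- makeBins(map, 30)
  none <- IntervalSet(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), trait = character(0),
                                 source = character(0)), "cM")
  one <- IntervalSet(data.frame(chrom = "chr01", start = 5, end = 10,
                                trait = "sel"), "cM")
  qtl1 <- IntervalSet(data.frame(chrom = "chr01", start = 20, end = 25,
                                 trait = "PH"), "cM")
  c0 <- countOverlap(bn, none, qtl1)
  expect_equal(c(c0@l, c0@m), c(0L, 0L))
  c1 <- countOverlap(bn, one, qtl1)    # same first bin on chr01
  expect_equal(c(c1@n, c1@l, c1@s, c1@m), c(6L, 1L, 1L, 1L))
  # swapping roles swaps l and s, keeps m
  cs <- countOverlap(bn, qtl1, one)
  expect_equal(c(cs@l, cs@s, cs@m), c(c1@s, c1@l, c1@m))
  # 40 random intervals, mixed units, vs independent bin-by-bin scan
  set.seed(43)
  rnd_iv <- function(n, unit) {
    ch <- sample(c("chr01", "chr02"), n, replace = TRUE)
    lo <- if (unit == "cM") runif(n, 0, 80) else runif(n, 1, 8e6)
    w <- if (unit == "cM") runif(n, 1, 15) else runif(n, 1e5, 1.5e6)
    IntervalSet(data.frame(chrom = ch, start = lo, end = lo + w,
                           trait = "t"), unit)
  }
  sel <- rnd_iv(20L, "bp"); qtl <- rnd_iv(20L, "cM")
  got <- countOverlap(bn, sel, qtl, map)
  hit_oracle <- function(ivtab) {
    b <- bins(bn)
    vapply(seq_len(nrow(b)), function(k) {
      any(vapply(seq_len(nrow(ivtab)), function(i) {
        ivtab$chrom[i] == b$chrom[k] &&
          min(ivtab$end[i], b$end_cM[k]) -
            max(ivtab$start[i], b$start_cM[k]) > 0
      }, logical(1)))
    }, logical(1))
  }
  sel_tab <- intervals(sel)
  for (i in seq_len(nrow(sel_tab))) {
    sel_tab$start[i] <- physicalToGenetic(map, sel_tab$chrom[i],
                                          sel_tab$start[i])
    sel_tab$end[i] <- physicalToGenetic(map, sel_tab$chrom[i],
                                        sel_tab$end[i])
  }
  hl <- hit_oracle(sel_tab); hs <- hit_oracle(intervals(qtl))
  expect_equal(got@l, sum(hl))
  expect_equal(got@s, sum(hs))
  expect_equal(got@m, sum(hl & hs))
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  expect_equal(hypergeomOverlapP(OverlapCounts(50, 10, 8, 0)), 1)
  expect_equal(hypergeomOverlapP(OverlapCounts(10, 5, 5, 5)),
               1 / choose(10, 5))
  # full-support PMF sums to 1
  for (n in c(7L, 19L)) for (l in c(2L, n %/% 2L)) for (s in c(3L, n - 2L)) {
    ks <- max(0L, s - (n - l)):min(l, s)
    tot <- sum(vapply(ks, function(k)
      hypergeomOverlapPmf(OverlapCounts(n, l, s, max(0L, s - (n - l))), k),
      numeric(1)))
    expect_lt(abs(tot - 1), 1e-12)
  }
  # grid agreement with the choose()-based oracle and with phyper
  set.seed(44)
  for (rep in 1:200) {
    n <- sample(5:25, 1L)
    l <- sample(0:n, 1L)
    s <- sample(0:n, 1L)
    lo <- max(0L, s - (n - l))
    m <- sample(lo:min(l, s), 1L)
    cnt <- OverlapCounts(n, l, s, m)
    p <- hypergeomOverlapP(cnt)
    expect_lt(abs(p - oracle_hyper_tail(n, l, s, m)), 1e-10)
    expect_lt(abs(p - phyper(m - 1, l, n - l, s, lower.tail = FALSE)),
              1e-10)
  }
  # monotone non-increasing in m
  ps <- vapply(0:6, function(m)
    hypergeomOverlapP(OverlapCounts(40, 10, 6, m)), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(OverlapCounts(10, 5, 4, 5), "m cannot exceed")
})
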