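write_bed <- function(rows) {
  tmp <- tempfile(fileext = ".bed")
  writeLines(rows, tmp)
  tmp
}

test_that("BED parsing validates intervals and keeps strand", {
  gr <- read_bed(write_bed("chr1\t100\t200"))
  expect_identical(GenomicRanges::start(gr), 101L)   # 0-based to 1-based
  expect_identical(GenomicRanges::end(gr), 200L)
  expect_identical(as.character(GenomicRanges::strand(gr)), "*")
  gr6 <- read_bed(write_bed("chr1\t0\t50\tpeak1\t0\t-"))
  expect_identical(as.character(GenomicRanges::strand(gr6)), "-")
  expect_error(read_bed(write_bed("chr1\t300\t200")),
               "line 1.*start must be < end")
  expect_error(read_bed(write_bed(c("chr1\t1\t2", "chr1\t5"))),
               "line 2")
})

test_that("constant coverage gives flat unnormalised profiles", {
  cov <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000),
                                score = 2.0)
  anchors <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(20001, 50001),
                                                     width = 1))
  pm <- compute_matrix(cov, anchors, flank = 2000, bin_size = 100,
                       normalize = FALSE)
  expect_identical(dim(pm$values), c(2L, 40L))
  expect_true(all(abs(pm$values - 2.0) < 1e-12))
  expect_error(compute_matrix(cov, anchors, flank = 2000, bin_size = 300),
               "divide")
})

test_that("unnormalised totals conserve the windowed track signal", {
  anchors <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(10001, width = 1))
  cov <- simulate_coverage(GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(9001,
                                                                   11000)),
                           enrichment = 3, width = 100, seed = 12,
                           contig_length = 20000)
  pm <- compute_matrix(cov, anchors, flank = 1000, bin_size = 100,
                       normalize = FALSE)
  # bins align with the track's own 100-bp grid: totals must agree exactly
  window <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, 11000))
  inside <- IRanges::overlapsAny(cov, window)
  expect_equal(sum(pm$values) * pm$bin_size, sum(cov$score[inside]) * 100,
               tolerance = 1e-9)
})

test_that("profiles are invariant to anchor order and strand-flip involutes", {
  cov <- simulate_coverage(GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(5001,
                                                                   6000)),
                           enrichment = 4, seed = 3, contig_length = 30000)
  anchors <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(5501, 15001, 20001),
                                                     width = 1),
                                    strand = c("+", "-", "+"))
  pm <- compute_matrix(cov, anchors, flank = 1000, bin_size = 100)
  pm_rev <- compute_matrix(cov, rev(anchors), flank = 1000, bin_size = 100)
  expect_equal(unname(pm$values), unname(pm_rev$values[3:1, ]))
  flip <- function(gr) {
    s <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(s == "+", "-",
                                        ifelse(s == "-", "+", s))
    gr
  }
  pm_flip2 <- compute_matrix(cov, flip(flip(anchors)), flank = 1000,
                             bin_size = 100)
  expect_equal(pm$values, pm_flip2$values)
  # minus-strand profile equals the reversed plus-strand profile
  plus <- anchors[2]; GenomicRanges::strand(plus) <- "+"
  pm_plus <- compute_matrix(cov, plus, flank = 1000, bin_size = 100)
  expect_equal(unname(pm$values[2, ]), rev(unname(pm_plus$values[1, ])))
})

test_that("planted enrichment shows up at the anchor centre", {
  anchor <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 11000))
  ratios <- sapply(1:20, function(s) {
    cov <- simulate_coverage(anchor, enrichment = 5, width = 100, seed = s,
                             contig_length = 40000)
    pm <- compute_matrix(cov, GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(10500, 10501)), flank = 2000, bin_size = 100)
    centre <- pm$values[1, 20:21]
    flank <- pm$values[1, c(1:5, 36:40)]
    mean(centre) / mean(flank)
  })
  expect_equal(mean(ratios), 5, tolerance = 0.15)
})

test_that("average_profile bands contain the mean", {
  cov <- simulate_coverage(GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(5001,
                                                                   5100)),
                           seed = 2, contig_length = 20000)
  anchors <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(4001, 5001, 9001),
                                                     width = 1))
  pm <- compute_matrix(cov, anchors, flank = 1000, bin_size = 100)
  prof <- average_profile(pm, n_boot = 200, seed = 4)
  expect_true(all(prof$lower <= prof$mean + 1e-9))
  expect_true(all(prof$upper >= prof$mean - 1e-9))
  single <- compute_matrix(cov, anchors[1], flank = 1000, bin_size = 100)
  prof1 <- average_profile(single, n_boot = 10, seed = 1)
  expect_equal(prof1$mean, unname(single$values[1, ]))
})

test_that("group comparison separates enriched from flat tracks", {
  anchor_set <- GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(seq(5001, 32001,
                                                            by = 3000),
                                                        width = 500))
  mk <- function(enr, s) {
    cov <- simulate_coverage(anchor_set, enrichment = enr, width = 100,
                             seed = s, contig_length = 40000)
    compute_matrix(cov, anchor_set, flank = 1000, bin_size = 100,
                   normalize = FALSE)
  }
  ps <- sapply(1:20, function(s)
    compare_groups(list(mk(5, s), mk(5, s + 100)),
                   list(mk(1, s + 200), mk(1, s + 300)))$p)
  expect_lt(max(ps), 0.01)
  # identical tracks in both groups: fully tied, p = 1
  same <- mk(1, 7)
  expect_identical(compare_groups(list(same), list(same))$p, 1)
  # two-sided symmetry under label swap
  a <- list(mk(3, 1)); b <- list(mk(1, 2))
  expect_equal(compare_groups(a, b)$p, compare_groups(b, a)$p,
               tolerance = 1e-12)
  expect_error(compare_groups(list(), list(same)), ">= 1 track")
})
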