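demo_pfm <- function() {
  new_pfm(matrix(c(8, 1, 1, 1,
                   1, 8, 1, 1,
                   1, 1, 8, 1,
                   1, 1, 1, 8), 4, 4), motif_id = "M0001", name = "demo")
}

test_that("JASPAR parsing round-trips and rejects incomplete motifs", {
  tmp <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TestMotif",
               "A  [ 10  2  0 ]",
               "C  [  1  5  2 ]",
               "G  [  0  1  8 ]",
               "T  [  2  5  3 ]"), tmp)
  pfms <- read_jaspar(tmp)
  expect_length(pfms, 1)
  expect_identical(pfms[[1]]$motif_id, "MA0001.1")
  expect_identical(dim(pfms[[1]]$counts), c(4L, 3L))
  expect_equal(pfms[[1]]$counts["A", ], c(10, 2, 0))
  out <- withr::local_tempfile()
  write_jaspar(pfms, out)
  again <- read_jaspar(out)
  expect_equal(again[[1]]$counts, pfms[[1]]$counts)
  writeLines(c(">MA0002.1 Broken",
               "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), tmp)
  expect_error(read_jaspar(tmp), "MA0002.1.*base T")
})

test_that("pfm_to_pwm follows the pseudocount arithmetic", {
  p <- new_pfm(matrix(c(3, 1, 0, 0), 4, 1))
  pwm <- pfm_to_pwm(p, pseudocount = 1)
  expect_equal(unname(pwm$scores["A", 1]), log2(0.65 / 0.25),
               tolerance = 1e-12)
  # counts proportional to the background give all-zero scores
  flat <- new_pfm(matrix(c(2, 2, 2, 2), 4, 2))
  expect_equal(unname(pfm_to_pwm(flat)$scores),
               matrix(0, 4, 2), tolerance = 1e-12)
  expect_error(pfm_to_pwm(p, background = c(0.5, 0.5, 0, 0)), "background")
  expect_error(pfm_to_pwm(p, pseudocount = 0), "pseudocount")
})

test_that("score distribution sums to one and thresholds match enumeration", {
  pwm <- pfm_to_pwm(demo_pfm())
  dist <- cardiosex:::.pwm_score_distribution(pwm)
  expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
  # width-2 motif against the 16-dinucleotide enumeration
  two <- pfm_to_pwm(new_pfm(matrix(c(5, 1, 1, 1, 1, 1, 5, 1), 4, 2)))
  for (pc in c(0.5, 0.1, 0.02))
    expect_equal(score_threshold(two, pc)$threshold,
                 threshold_oracle(two, pc))
  # p_cutoff = 1 returns the minimum attainable score
  dist2 <- cardiosex:::.pwm_score_distribution(two)
  expect_equal(score_threshold(two, 1)$threshold,
               min(dist2$grid) * dist2$grain)
})

test_that("DP threshold equals exhaustive enumeration for random motifs", {
  set.seed(12)
  for (i in 1:50) {
    w <- sample(2:8, 1)
    counts <- matrix(rpois(4 * w, 4) + ifelse(runif(4 * w) < 0.2, 10, 0),
                     4, w)
    counts[, colSums(counts) == 0] <- 1
    pwm <- pfm_to_pwm(new_pfm(counts))
    pc <- 10^runif(1, -4, -0.5)
    expect_equal(score_threshold(pwm, pc)$threshold,
                 threshold_oracle(pwm, pc))
  }
})

test_that("an unattainable cutoff returns the maximum score, flagged", {
  pwm <- pfm_to_pwm(demo_pfm())
  res <- score_threshold(pwm, 1e-9)
  expect_false(res$attainable)
  dist <- cardiosex:::.pwm_score_distribution(pwm)
  expect_equal(res$threshold, max(dist$grid) * dist$grain)
})

test_that("scanning finds every planted site of an informative motif", {
  # width 9: the consensus word's own probability 4^-9 sits below 1e-5,
  # so the cutoff is attainable
  pfm <- new_pfm(matrix(c(20, 0, 0, 0,
                          0, 20, 0, 0,
                          0, 0, 20, 0,
                          20, 0, 0, 0,
                          0, 0, 0, 20,
                          0, 20, 0, 0,
                          0, 0, 20, 0,
                          0, 0, 0, 20,
                          20, 0, 0, 0), 4, 9), "strong")
  sim <- simulate_promoters(30, 120, pfm, placement_prob = 1, seed = 31)
  pwm <- pfm_to_pwm(pfm)
  thr <- score_threshold(pwm, 1e-5)
  expect_true(thr$attainable)
  hits <- scan_pwm(sim$sequences, pwm, thr$threshold)
  planted <- sim$truth$placements
  found <- merge(planted, hits, by = c("sequence_id", "offset"))
  expect_identical(nrow(found), nrow(planted))
  expect_true(all(hits$p <= 1e-5))
})

test_that("all-N sequences yield no hits and empty input no error", {
  pwm <- pfm_to_pwm(demo_pfm())
  seqs <- c(n1 = paste(rep("N", 50), collapse = ""))
  expect_identical(nrow(scan_pwm(seqs, pwm, -10)), 0L)
  expect_identical(nrow(scan_pwm(character(0), pwm, 0)), 0L)
})

test_that("reverse-complementing the input mirrors hits across strands", {
  pfm <- new_pfm(matrix(c(9, 1, 0, 0,
                          0, 8, 1, 1,
                          1, 0, 9, 0,
                          0, 1, 0, 9), 4, 4), "asym")
  pwm <- pfm_to_pwm(pfm)
  sim <- simulate_promoters(10, 80, pfm, placement_prob = 1, seed = 77)
  seqs <- as.character(sim$sequences)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  names(rc) <- names(seqs)
  h_fwd <- scan_pwm(seqs, pwm, 2)
  h_rc <- scan_pwm(rc, pwm, 2)
  expect_identical(nrow(h_fwd), nrow(h_rc))
  w <- 4; len <- 80
  remapped <- data.frame(sequence_id = h_rc$sequence_id,
                         offset = len - w - h_rc$offset,
                         strand = ifelse(h_rc$strand == "+", "-", "+"),
                         score = h_rc$score)
  o1 <- h_fwd[order(h_fwd$sequence_id, h_fwd$offset, h_fwd$strand),
              c("sequence_id", "offset", "strand", "score")]
  o2 <- remapped[order(remapped$sequence_id, remapped$offset,
                       remapped$strand), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("background scan hit counts match the closed-form expectation", {
  pfm <- new_pfm(matrix(rep(c(12, 0, 0, 0), 6), 4), "a6")
  pwm <- pfm_to_pwm(pfm)
  thr <- score_threshold(pwm, 1e-3)
  n_seqs <- 60; len <- 200; w <- ncol(pfm$counts)
  sim <- simulate_promoters(n_seqs, len, pfm, placement_prob = 0, seed = 55)
  hits <- scan_pwm(sim$sequences, pwm, thr$threshold)
  expected <- 2 * (len - w + 1) * n_seqs * thr$tail_p
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected) + 1)
})

test_that("promoter extraction follows the strand-aware half-open window", {
  set.seed(8)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")))
  genes <- data.frame(gene_id = c("plus", "minus", "edge"),
                      chromosome = "chr1",
                      tss = c(10000L, 10000L, 100L),
                      strand = c("+", "-", "+"))
  prom <- extract_promoters(genes, genome)
  expect_identical(unname(Biostrings::width(prom$sequences)[1]), 6000L)
  expect_identical(prom$windows$start[1], 5000L)
  expect_identical(prom$windows$end[1], 11000L)
  # minus strand: reverse complement of [tss - 1000 + 1, tss + 5000 + 1)
  raw <- Biostrings::subseq(genome[["chr1"]], start = 9002, end = 15001)
  expect_identical(as.character(prom$sequences[["minus"]]),
                   as.character(Biostrings::reverseComplement(raw)))
  expect_true(prom$windows$truncated[3])
  expect_false(any(prom$windows$truncated[1:2]))
  bad <- data.frame(gene_id = "x", chromosome = "chrZ", tss = 5L,
                    strand = "+")
  expect_error(extract_promoters(bad, genome), "missing contig: chrZ")
})

test_that("hypergeometric enrichment matches the combinatorial identity", {
  target <- setNames(rep(TRUE, 5), paste0("t", 1:5))
  bg <- setNames(c(rep(TRUE, 5), rep(FALSE, 5)),
                 c(paste0("t", 1:5), paste0("u", 1:5)))
  res <- motif_enrichment(target, bg)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  none <- setNames(rep(FALSE, 5), paste0("t", 1:5))
  expect_equal(motif_enrichment(none, bg)$p, 1)
  expect_equal(motif_enrichment(bg, bg)$p, 1)   # target = universe
  inconsistent <- setNames(rep(TRUE, 6), c(paste0("t", 1:5), "u1"))
  expect_error(motif_enrichment(inconsistent, bg), "inconsistent")
})
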