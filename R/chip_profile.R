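# Average coverage metaprofiles around TSS/enhancer anchors, for comparing
# chromatin-mark enrichment between groups of tracks (e.g. XX vs XY ES
# lines). Input is a coverage track (bedGraph), not alignments; upstream
# read processing is out of scope.

#' Read anchor intervals from a BED file
#'
#' BED3 or better; 0-based half-open coordinates; a strand column (field 6)
#' is honoured when present.
#'
#' @param path BED path.
#' @param kind anchor kind label: "TSS", "enhancer" or "custom".
#' @return a [GenomicRanges::GRanges] (1-based internally, as is the
#'   Bioconductor convention) with a `kind` metadata column.
#' @export
read_bed <- function(path, kind = "custom") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("empty BED file")
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED line ", which(nf < 3)[1L], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 >= end0 | start0 < 0)
  if (length(bad) > 0)
    stop(sprintf("BED line %d: invalid interval (start must be < end)",
                 bad[1L]))
  strand <- rep(".", length(lines))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[[`, character(1), 6L)
  if (any(!strand %in% c("+", "-", ".")))
    stop("BED line ", which(!strand %in% c("+", "-", "."))[1L],
         ": invalid strand")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0),
                               strand = sub("^\\.$", "*", strand))
  S4Vectors::mcols(gr)$kind <- kind
  gr
}

#' Read a bedGraph coverage track
#' @param path bedGraph path.
#' @return a [GenomicRanges::GRanges] with a `score` column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Coverage matrix around anchors
#'
#' Per anchor, the mean coverage in `2 * flank / bin_size` bins across
#' `[ref - flank, ref + flank)` where the reference point is the anchor
#' start or midpoint; minus-strand anchors have their bin order reversed so
#' the profile always reads 5' to 3'. Values are scaled to reads per
#' million of the track total (`sum(score * width) / 1e6`). Bins that fall
#' entirely outside the track's covered span are NA-flagged.
#'
#' @param coverage a `GRanges` with `score` (from [read_bedgraph()] or
#'   [simulate_coverage()]), or a bedGraph path.
#' @param anchors a `GRanges` of anchors (from [read_bed()]).
#' @param flank half-window in bases, default 2000.
#' @param bin_size bin width, must divide `2 * flank`, default 100.
#' @param reference "start" or "midpoint", default depends on the anchors'
#'   `kind`: "start" for TSS, "midpoint" otherwise.
#' @param normalize scale to reads-per-million, default TRUE.
#' @return a `profile_matrix`: list with `values` (anchors x bins),
#'   `bin_centers` (offsets relative to the reference), `flank`,
#'   `bin_size`.
#' @export
compute_matrix <- function(coverage, anchors, flank = 2000, bin_size = 100,
                           reference = NULL, normalize = TRUE) {
  if (is.character(coverage)) coverage <- read_bedgraph(coverage)
  if ((2 * flank) %% bin_size != 0)
    stop("bin_size must divide 2 * flank")
  if (is.null(reference)) {
    kinds <- unique(S4Vectors::mcols(anchors)$kind)
    reference <- if (length(kinds) == 1 && identical(kinds, "TSS"))
      "start" else "midpoint"
  }
  n_bins <- as.integer(2 * flank / bin_size)
  cov_chr <- as.character(GenomicRanges::seqnames(coverage))
  cov_start <- GenomicRanges::start(coverage)   # 1-based
  cov_end <- GenomicRanges::end(coverage)
  score <- S4Vectors::mcols(coverage)$score
  total <- sum(score * (cov_end - cov_start + 1))
  scale_f <- if (normalize && total > 0) 1e6 / total else 1
  span <- tapply(seq_along(cov_chr), cov_chr,
                 function(i) c(min(cov_start[i]), max(cov_end[i])))
  vals <- matrix(NA_real_, length(anchors), n_bins)
  a_chr <- as.character(GenomicRanges::seqnames(anchors))
  a_strand <- as.character(GenomicRanges::strand(anchors))
  ref <- ifelse(rep(reference, length(anchors)) == "start",
                GenomicRanges::start(anchors),
                floor((GenomicRanges::start(anchors) +
                       GenomicRanges::end(anchors)) / 2))
  for (i in seq_along(anchors)) {
    chr <- a_chr[i]
    bin_starts <- ref[i] - flank + (seq_len(n_bins) - 1L) * bin_size
    bin_ends <- bin_starts + bin_size - 1L
    row <- numeric(n_bins)
    on_chr <- which(cov_chr == chr)
    if (length(on_chr) > 0) {
      for (b in seq_len(n_bins)) {
        ov <- pmin(cov_end[on_chr], bin_ends[b]) -
              pmax(cov_start[on_chr], bin_starts[b]) + 1
        pos <- ov > 0
        row[b] <- sum(score[on_chr][pos] * ov[pos]) / bin_size
      }
      sp <- span[[chr]]
      outside <- bin_ends < sp[1L] | bin_starts > sp[2L]
      row[outside] <- NA_real_
    } else row[] <- NA_real_
    if (a_strand[i] == "-") row <- rev(row)
    vals[i, ] <- row * scale_f
  }
  rownames(vals) <- if (!is.null(names(anchors))) names(anchors) else
    sprintf("anchor%04d", seq_along(anchors))
  centers <- -flank + (seq_len(n_bins) - 0.5) * bin_size
  structure(list(values = vals, bin_centers = centers, flank = flank,
                 bin_size = bin_size, normalized = normalize),
            class = "profile_matrix")
}

#' Average profile with a bootstrap band
#'
#' Column means over anchors plus a 95% band from an anchor-level
#' bootstrap.
#'
#' @param pm a `profile_matrix`.
#' @param n_boot bootstrap resamples, default 1000.
#' @param seed integer seed.
#' @return data.frame with `bin_center`, `mean`, `lower`, `upper`.
#' @export
average_profile <- function(pm, n_boot = 1000, seed = 1) {
  stopifnot(inherits(pm, "profile_matrix"))
  X <- pm$values
  if (nrow(X) < 1) stop("profile needs >= 1 anchor")
  mu <- colMeans(X, na.rm = TRUE)
  band <- with_seed(seed, {
    boots <- replicate(n_boot, {
      idx <- sample.int(nrow(X), replace = TRUE)
      colMeans(X[idx, , drop = FALSE], na.rm = TRUE)
    })
    apply(boots, 1L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  })
  data.frame(bin_center = pm$bin_centers, mean = mu,
             lower = band[1L, ], upper = band[2L, ])
}

#' Compare two groups of coverage tracks at shared anchors
#'
#' For every track the per-anchor area under the profile (sum of bin values
#' times bin width) is computed; the two groups' pooled per-anchor areas
#' are compared with a two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#' The test is a pragmatic stand-in: no specific statistic is canonical for
#' metaprofile group differences.
#'
#' @param pms_a,pms_b lists of `profile_matrix` objects (one per track),
#'   computed on the same anchors.
#' @return list with `p`, `statistic`, `areas_a`, `areas_b`.
#' @export
compare_groups <- function(pms_a, pms_b) {
  if (inherits(pms_a, "profile_matrix")) pms_a <- list(pms_a)
  if (inherits(pms_b, "profile_matrix")) pms_b <- list(pms_b)
  if (length(pms_a) == 0 || length(pms_b) == 0)
    stop("both groups need >= 1 track")
  area <- function(pm) rowSums(pm$values, na.rm = TRUE) * pm$bin_size
  a <- unlist(lapply(pms_a, area)); b <- unlist(lapply(pms_b, area))
  if (stats::sd(c(a, b)) == 0)      # fully tied: no evidence either way
    return(list(p = 1, statistic = length(a) * length(b) / 2,
                areas_a = a, areas_b = b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       areas_a = a, areas_b = b)
}

#' Write a profile matrix as TSV
#' @param pm a `profile_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_profile_tsv <- function(pm, path) {
  tab <- data.frame(anchor = rownames(pm$values), pm$values,
                    check.names = FALSE)
  names(tab)[-1L] <- as.character(pm$bin_centers)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
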