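# Known-motif scanning of promoter windows with exact p-value thresholds.
#
# Position frequency matrices (JASPAR text format) are converted to
# log2-odds position weight matrices with a background-proportional
# pseudocount. The null score distribution under the i.i.d. background is
# computed exactly by dynamic programming over columns, with scores
# discretised to a fixed grain (default 1e-3 bits); the score threshold for
# a p-value cutoff is the smallest discretised score whose upper tail
# probability does not exceed the cutoff. Both strands are scanned; windows
# containing N are skipped.

.dna_bases <- c("A", "C", "G", "T")

#' Construct a position frequency matrix
#' @param counts 4 x w nonnegative matrix, rows A, C, G, T.
#' @param motif_id,name identifiers.
#' @return an object of class `pfm`.
#' @export
new_pfm <- function(counts, motif_id = "motif", name = motif_id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PFM needs 4 rows (A, C, G, T)")
  if (ncol(counts) < 1) stop("PFM needs width >= 1")
  if (any(counts < 0) || any(colSums(counts) <= 0))
    stop("PFM counts must be nonnegative with positive column sums")
  rownames(counts) <- .dna_bases
  structure(list(motif_id = motif_id, name = name, counts = counts),
            class = "pfm")
}

#' Read motifs in JASPAR text format
#'
#' Parses the ">ID NAME" header plus four bracketed count rows (A, C, G, T)
#' per motif; order is preserved.
#'
#' @param path path to a JASPAR-format file.
#' @return list of `pfm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no motif headers ('>') found")
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1L]]
    motif_id <- parts[1L]
    name <- if (length(parts) > 1) paste(parts[-1L], collapse = " ") else motif_id
    block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(.dna_bases, function(b) {
      ln <- grep(sprintf("^\\s*%s\\s*[\\[|]?", b), block, value = TRUE)
      ln <- ln[grepl(sprintf("^\\s*%s([^A-Za-z]|$)", b), ln)]
      if (length(ln) == 0)
        stop(sprintf("motif %s: missing count row for base %s", motif_id, b))
      nums <- regmatches(ln[1L], gregexpr("[0-9.]+", ln[1L]))[[1L]]
      as.numeric(nums)
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1)
      stop(sprintf("motif %s: unequal row lengths", motif_id))
    out[[i]] <- new_pfm(do.call(rbind, rows), motif_id = motif_id, name = name)
  }
  out
}

#' Write motifs in JASPAR text format
#' @param pfms a `pfm` or list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_jaspar <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  con <- file(path, "wt"); on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$name), con)
    for (b in .dna_bases)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Convert a PFM to a log2-odds PWM
#'
#' Per column, `prob_b = (count_b + pseudocount * background_b) /
#' (total + pseudocount)` and `score_b = log2(prob_b / background_b)`.
#'
#' @param pfm a `pfm`.
#' @param background base composition summing to 1, all positive; default
#'   uniform.
#' @param pseudocount total pseudocount mass per column, default 1.
#' @return an object of class `pwm` with fields `scores` (4 x w),
#'   `background`, `pseudocount`.
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 1.0) {
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 positive values summing to 1")
  .check_number(pseudocount, "pseudocount", lower = .Machine$double.eps)
  cs <- colSums(pfm$counts)
  prob <- sweep(pfm$counts + pseudocount * background, 2L, cs + pseudocount, "/")
  scores <- log2(prob / background)
  rownames(scores) <- .dna_bases
  structure(list(motif_id = pfm$motif_id, name = pfm$name, scores = scores,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

# exact null score distribution on a discretised grid. Returns a list with
# `grid` (integer scores, ascending) and `prob`. grain is in bits.
.pwm_score_distribution <- function(pwm, grain = 1e-3) {
  S <- round(pwm$scores / grain)
  # convolve column score distributions; start from the empty prefix
  cur_lo <- 0L
  cur <- 1
  for (j in seq_len(ncol(S))) {
    col <- S[, j]
    new_lo <- cur_lo + min(col)
    new <- numeric(length(cur) + max(col) - min(col))
    for (b in 1:4) {
      off <- col[b] - min(col)
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * pwm$background[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  grid <- cur_lo + seq_along(cur) - 1L
  keep <- cur > 0                      # achievable scores only
  list(grid = grid[keep], prob = cur[keep], grain = grain)
}

#' Score threshold for an exact p-value cutoff
#'
#' @param pwm a `pwm`.
#' @param p_cutoff upper-tail probability cutoff, default 1e-5.
#' @param grain score discretisation grain in bits, default 1e-3.
#' @return list with `threshold` (score in bits), `attainable` (FALSE when
#'   the cutoff undercuts the minimum attainable tail, in which case the
#'   maximum score is returned), and `tail_p` (the exact tail at the
#'   threshold).
#' @export
score_threshold <- function(pwm, p_cutoff = 1e-5, grain = 1e-3) {
  .check_number(p_cutoff, "p_cutoff", lower = 1e-300, upper = 1)
  dist <- .pwm_score_distribution(pwm, grain)
  tail <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail <= p_cutoff)
  if (length(ok) == 0)
    return(list(threshold = max(dist$grid) * grain, attainable = FALSE,
                tail_p = tail[length(tail)]))
  i <- ok[1L]
  list(threshold = dist$grid[i] * grain, attainable = TRUE, tail_p = tail[i])
}

#' Exact upper-tail p of a score
#' @param pwm a `pwm`.
#' @param score score(s) in bits.
#' @param grain discretisation grain, default 1e-3.
#' @return tail probabilities `P(null score >= score)` on the discretised
#'   grid.
#' @export
pwm_tail_p <- function(pwm, score, grain = 1e-3) {
  dist <- .pwm_score_distribution(pwm, grain)
  tail <- rev(cumsum(rev(dist$prob)))
  idx <- findInterval(round(score / grain), dist$grid)
  # tail at the smallest grid point >= score
  vapply(round(score / grain), function(s) {
    i <- which(dist$grid >= s)
    if (length(i) == 0) 0 else tail[i[1L]]
  }, numeric(1))
}

.revcomp_pwm <- function(pwm) {
  sc <- pwm$scores[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$scores))),
                   drop = FALSE]
  rownames(sc) <- .dna_bases
  pwm$scores <- sc
  pwm
}

# score every window of an integer-encoded sequence (1..4, NA for N)
.window_scores <- function(enc, S) {
  w <- ncol(S); n <- length(enc)
  if (n < w) return(numeric(0))
  out <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    v <- S[, j][enc[j:(n - w + j)]]
    out <- out + v           # NA propagates for windows containing N
  }
  out
}

#' Scan sequences with a PWM on both strands
#'
#' Windows with score at least `threshold` are reported with 0-based
#' forward-strand offsets; the reverse strand is scanned via the
#' reverse-complement matrix so minus-strand hits also carry forward
#' coordinates. Windows containing N are skipped. Scoring happens on the
#' same discretisation grid as the threshold's exact null distribution, so
#' a reported hit's p value is exactly its tail probability under the
#' background model.
#'
#' @param sequences a [Biostrings::DNAStringSet], a named character vector,
#'   or a FASTA path.
#' @param pwm a `pwm`.
#' @param threshold score threshold in bits (from [score_threshold()]).
#' @param grain grain used for the reported exact p values.
#' @return data.frame with `sequence_id`, `offset` (0-based), `strand`,
#'   `score`, `p`.
#' @export
scan_pwm <- function(sequences, pwm, threshold, grain = 1e-3) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (inherits(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (length(sequences) == 0)
    return(data.frame(sequence_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0)))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  Sf <- round(pwm$scores / grain)               # integer grid, as in the DP
  Sr <- round(.revcomp_pwm(pwm)$scores / grain)
  thr_int <- round(threshold / grain)
  hits <- list()
  for (id in names(sequences)) {
    enc <- match(strsplit(toupper(sequences[[id]]), "")[[1L]], .dna_bases)
    for (strand in c("+", "-")) {
      sc <- .window_scores(enc, if (strand == "+") Sf else Sr)
      keep <- which(!is.na(sc) & sc >= thr_int)
      if (length(keep) > 0)
        hits[[length(hits) + 1L]] <-
          data.frame(sequence_id = id, offset = keep - 1L, strand = strand,
                     score = sc[keep] * grain, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(sequence_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0)))
  out <- do.call(rbind, hits)
  out$p <- pwm_tail_p(pwm, out$score, grain)
  out[order(out$sequence_id, out$offset, out$strand), , drop = FALSE]
}

#' Extract promoter windows around annotated TSSs
#'
#' Plus-strand genes get `[tss - upstream, tss + downstream)` and
#' minus-strand genes the mirrored window `[tss - downstream + 1,
#' tss + upstream + 1)` reverse-complemented, in 0-based half-open
#' coordinates. Windows truncated at contig bounds are flagged.
#'
#' @param genes gene annotation data.frame with `gene_id`, `chromosome`,
#'   `tss` (0-based), `strand`.
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome, or a
#'   FASTA path.
#' @param upstream,downstream window extents, defaults 5000 and 1000.
#' @return list with `sequences` (a [Biostrings::DNAStringSet] named by
#'   gene) and `windows` (data.frame gene_id, chromosome, start, end,
#'   strand, truncated).
#' @export
extract_promoters <- function(genes, genome, upstream = 5000,
                              downstream = 1000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  missing <- setdiff(genes$chromosome, names(genome))
  if (length(missing) > 0) stop("gene on missing contig: ", missing[1L])
  n <- nrow(genes)
  seqs <- character(n); trunc <- logical(n)
  start0 <- integer(n); end0 <- integer(n)
  for (i in seq_len(n)) {
    tss <- genes$tss[i]; chr <- genes$chromosome[i]
    len <- Biostrings::width(genome[chr])
    if (genes$strand[i] == "+") {
      s <- tss - upstream; e <- tss + downstream       # [s, e) 0-based
    } else {
      s <- tss - downstream + 1L; e <- tss + upstream + 1L
    }
    cs <- max(s, 0L); ce <- min(e, len)
    trunc[i] <- cs != s || ce != e
    piece <- Biostrings::subseq(genome[[chr]], start = cs + 1L, end = ce)
    if (genes$strand[i] == "-")
      piece <- Biostrings::reverseComplement(piece)
    seqs[i] <- as.character(piece)
    start0[i] <- as.integer(cs); end0[i] <- as.integer(ce)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes$gene_id
  list(sequences = out,
       windows = data.frame(gene_id = genes$gene_id,
                            chromosome = genes$chromosome,
                            start = start0, end = end0,
                            strand = genes$strand, truncated = trunc,
                            stringsAsFactors = FALSE))
}

#' Hypergeometric motif enrichment (zero-or-one occurrence per gene)
#'
#' One-sided upper-tail hypergeometric p for observing `x` target genes
#' with a hit given `K` hit genes in a universe of `N`, drawing `n`
#' targets.
#'
#' @param target_hits named logical vector: has-hit flag per target gene.
#' @param background_hits named logical vector over the universe
#'   (must contain the targets).
#' @return list with `p`, `x`, `K`, `n`, `N`.
#' @export
motif_enrichment <- function(target_hits, background_hits) {
  if (!all(names(target_hits) %in% names(background_hits)))
    stop("target genes must be contained in the background universe")
  N <- length(background_hits)
  K <- sum(background_hits)
  n <- length(target_hits)
  x <- sum(target_hits)
  if (x > min(K, n)) stop("inconsistent inputs: x > min(K, n)")
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, x = x, K = K, n = n, N = N)
}
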