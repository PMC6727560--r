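# Synthetic inputs with the statistical structure the analysis assumes,
# paired with ground-truth sidecars so parameter recovery can be tested
# without external downloads.
#
# Expression noise is lognormal (Normal on the log2 scale) because the
# pipeline consumes FPKM, not counts. Every generator is a pure function of
# its arguments and seed: it draws from a private stream and restores the
# caller's RNG state.

#' Simulate a bulk ES-line panel with planted sex effects and a planted
#' sex-correlated module
#'
#' Mirrors a balanced two-sex bulk design (default six male and six female
#' lines). Per gene, log2 expression is Normal(mu_g, noise_sd); the first
#' `n_biased` genes get their mean shifted by +/- effect/2 per sex (random
#' direction). A disjoint block of `module_size` genes shares a latent
#' per-sample factor constructed to have exactly the requested point-biserial
#' correlation `r_module` with sex in-sample; each member gene adds the
#' factor with its own loading plus Normal noise. Values are exponentiated
#' back to the FPKM scale.
#'
#' @param n_per_sex samples per sex, default 6.
#' @param n_genes total genes, default 2000.
#' @param n_biased planted sex-effect genes, default 50.
#' @param effect total log2 shift between the sexes, default 4.
#' @param module_size planted module size (0 disables the module), default
#'   100.
#' @param r_module target module-sex correlation, default 0.85.
#' @param noise_sd residual SD on the log2 scale, default 0.5.
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (sex_biased_genes, module_genes, r_true, latent, sample_sexes).
#' @export
simulate_bulk_panel <- function(n_per_sex = 6, n_genes = 2000, n_biased = 50,
                                effect = 4, module_size = 100,
                                r_module = 0.85, noise_sd = 0.5, seed = 1) {
  .check_number(n_per_sex, "n_per_sex", lower = 2)
  .check_number(effect, "effect", lower = 0)
  .check_number(r_module, "r_module", lower = -1, upper = 1)
  .check_number(module_size, "module_size", lower = 0)
  if (module_size == 1) stop("module_size must be 0 (no module) or >= 2")
  if (module_size > n_genes) stop("module_size cannot exceed n_genes")
  if (n_biased + module_size > n_genes)
    stop("n_biased + module_size cannot exceed n_genes")
  with_seed(seed, {
    n <- 2L * n_per_sex
    sex <- rep(c("male", "female"), each = n_per_sex)
    female <- as.numeric(sex == "female")
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    biased <- if (n_biased > 0) gene_id[seq_len(n_biased)] else character(0)
    module <- if (module_size > 0)
      gene_id[n_biased + seq_len(module_size)] else character(0)
    direction <- sample(c("XX", "XY"), n_biased, replace = TRUE)

    # latent factor with exact in-sample point-biserial correlation r_module
    s_std <- as.numeric(scale(female))
    e <- stats::rnorm(n)
    e <- e - s_std * sum(e * s_std) / sum(s_std^2)   # orthogonalise
    e <- as.numeric(scale(e))
    latent <- r_module * s_std + sqrt(1 - r_module^2) * e

    mu <- stats::rnorm(n_genes, mean = 3, sd = 1.5)
    logx <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n) + mu
    if (n_biased > 0) {
      shift <- ifelse(direction == "XX", effect / 2, -effect / 2)
      logx[seq_len(n_biased), ] <- logx[seq_len(n_biased), ] +
        outer(shift, female - 0.5) * 2   # +/- effect/2 per sex
    }
    if (module_size > 0) {
      loading <- stats::runif(module_size, 1, 2)
      logx[n_biased + seq_len(module_size), ] <-
        logx[n_biased + seq_len(module_size), ] + outer(loading, latent)
    }
    vals <- 2^logx
    dimnames(vals) <- list(gene_id, sprintf("s%02d", seq_len(n)))
    samples <- data.frame(sample_id = colnames(vals), sex = sex,
                          stage = "ES", batch = "b1", cross = "F1",
                          stringsAsFactors = FALSE)
    truth <- list(
      sex_biased_genes = data.frame(gene_id = biased, direction = direction,
                                    effect_size = rep(effect, n_biased),
                                    stage = rep("ES", n_biased),
                                    stringsAsFactors = FALSE),
      module_genes = module, r_true = r_module, latent = latent,
      sample_sexes = stats::setNames(sex, colnames(vals)))
    list(matrix = expression_matrix(vals, samples = samples), truth = truth)
  })
}

#' Simulate a single-cell panel with Xist/Eif2s3y marker structure
#'
#' Female cells express Xist highly (lognormal around `marker_mean`) and
#' Eif2s3y not at all apart from a small leak; male cells are the mirror
#' image. Each marker value is then independently zeroed with probability
#' `dropout`. A block of background genes with no sex structure is added so
#' the matrix exercises the full pipeline.
#'
#' @param stage stage label, default "E8.5".
#' @param n_cells number of cells.
#' @param female_fraction fraction of truly female cells, default 0.5.
#' @param marker_mean FPKM scale of the expressed marker, default 50.
#' @param dropout per-marker dropout probability in `[0, 1)`, default 0.3.
#' @param leak_prob probability that the silent marker leaks a low value,
#'   default 0.1.
#' @param n_background background genes, default 100.
#' @param seed integer seed.
#' @return list with `matrix` and `truth` (`cell_sexes`).
#' @export
simulate_cells <- function(stage = "E8.5", n_cells = 200,
                           female_fraction = 0.5, marker_mean = 50,
                           dropout = 0.3, leak_prob = 0.1,
                           n_background = 100, seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  .check_number(female_fraction, "female_fraction", lower = 0, upper = 1)
  .check_number(dropout, "dropout", lower = 0, upper = 1 - 1e-12)
  if (!stage %in% stage_levels()) stop("unknown stage: ", stage)
  with_seed(seed, {
    n_f <- round(n_cells * female_fraction)
    sexes <- sample(rep(c("female", "male"), c(n_f, n_cells - n_f)))
    high <- function(n) stats::rlnorm(n, meanlog = log(marker_mean), sdlog = 0.5)
    low <- function(n) ifelse(stats::runif(n) < leak_prob,
                              stats::runif(n, 0, 0.5), 0)
    xist <- ifelse(sexes == "female", high(n_cells), low(n_cells))
    eif <- ifelse(sexes == "male", high(n_cells), low(n_cells))
    xist[stats::runif(n_cells) < dropout] <- 0
    eif[stats::runif(n_cells) < dropout] <- 0
    bg <- matrix(stats::rlnorm(n_background * n_cells, meanlog = 1, sdlog = 1),
                 n_background, n_cells)
    vals <- rbind(Xist = xist, Eif2s3y = eif, bg)
    rownames(vals) <- c("Xist", "Eif2s3y",
                        sprintf("bg%03d", seq_len(n_background)))
    colnames(vals) <- sprintf("c%04d", seq_len(n_cells))
    samples <- data.frame(sample_id = colnames(vals), sex = "unknown",
                          stage = stage, batch = "sc", cross = NA,
                          stringsAsFactors = FALSE)
    list(matrix = expression_matrix(vals, samples = samples),
         truth = list(cell_sexes = stats::setNames(sexes, colnames(vals))))
  })
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Backgrounds are i.i.d. with the given base composition; with probability
#' `placement_prob` each sequence receives one motif instance sampled from
#' the PFM's column frequencies, at a uniform offset and strand.
#'
#' @param n_seqs number of sequences.
#' @param length sequence length (>= motif width).
#' @param pfm a PFM from [read_jaspar()] or [new_pfm()].
#' @param placement_prob per-sequence planting probability.
#' @param background base composition (A, C, G, T), default uniform.
#' @param seed integer seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and `truth`
#'   (`placements`: data.frame sequence_id, offset (0-based), strand).
#' @export
simulate_promoters <- function(n_seqs, length, pfm, placement_prob = 0.5,
                               background = rep(0.25, 4), seed = 1) {
  w <- ncol(pfm$counts)
  if (length < w) stop("sequence length must be >= motif width")
  .check_number(placement_prob, "placement_prob", lower = 0, upper = 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    probs <- sweep(pfm$counts, 2L, colSums(pfm$counts), "/")
    seqs <- character(n_seqs)
    placements <- list()
    for (i in seq_len(n_seqs)) {
      s <- sample(bases, length, replace = TRUE, prob = background)
      if (stats::runif(1) < placement_prob) {
        inst <- vapply(seq_len(w), function(j)
          sample(bases, 1L, prob = probs[, j]), character(1))
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-")
          inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
        off <- sample.int(length - w + 1L, 1L) - 1L   # 0-based
        s[off + seq_len(w)] <- inst
        placements[[base::length(placements) + 1L]] <-
          data.frame(sequence_id = sprintf("seq%04d", i), offset = off,
                     strand = strand, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("seq%04d", seq_len(n_seqs))
    placements <- if (base::length(placements) > 0)
      do.call(rbind, placements)
    else data.frame(sequence_id = character(0), offset = integer(0),
                    strand = character(0))
    list(sequences = out, truth = list(placements = placements))
  })
}

#' Simulate a coverage track with planted enrichment at anchors
#'
#' One contiguous contig is tiled into bins of `width` bases; background
#' counts are Poisson with a rate chosen so the expected total equals
#' `library_size`, and bins overlapping an anchor have their rate multiplied
#' by `enrichment`.
#'
#' @param anchors a [GenomicRanges::GRanges] of anchor intervals (single
#'   contig).
#' @param enrichment fold enrichment at anchors, >= 1.
#' @param width bin width in bases, default 100.
#' @param library_size expected total count, default 1e6.
#' @param contig_length length of the simulated contig; defaults to the
#'   anchor maximum plus 10 kb.
#' @param seed integer seed.
#' @return a [GenomicRanges::GRanges] of bins with a `score` column
#'   (bedGraph-ready via [rtracklayer::export]).
#' @export
simulate_coverage <- function(anchors, enrichment = 5, width = 100,
                              library_size = 1e6, contig_length = NULL,
                              seed = 1) {
  .check_number(enrichment, "enrichment", lower = 1)
  if (any(GenomicRanges::start(anchors) > GenomicRanges::end(anchors)))
    stop("malformed anchor intervals")
  chroms <- unique(as.character(GenomicRanges::seqnames(anchors)))
  if (length(chroms) != 1) stop("anchors must sit on a single contig")
  if (is.null(contig_length))
    contig_length <- max(GenomicRanges::end(anchors)) + 10000L
  with_seed(seed, {
    n_bins <- ceiling(contig_length / width)
    starts <- (seq_len(n_bins) - 1L) * width + 1L
    bins <- GenomicRanges::GRanges(
      chroms, IRanges::IRanges(start = starts,
                               end = pmin(starts + width - 1L, contig_length)))
    hit <- IRanges::overlapsAny(bins, anchors)
    base_rate <- library_size /
      (sum(!hit) + enrichment * sum(hit))
    rate <- ifelse(hit, enrichment * base_rate, base_rate)
    S4Vectors::mcols(bins)$score <- stats::rpois(n_bins, rate)
    bins
  })
}

#' Simulate a planted-partition interaction network
#'
#' Stochastic block model: nodes are split evenly over `n_communities`
#' blocks; within-block pairs are connected with probability `p_in`,
#' between-block pairs with `p_out`. Edge confidence scores are drawn
#' uniformly above the STRING-style 0.7 cut so the planted edges survive
#' score filtering.
#'
#' @param n_nodes,n_communities sizes; `n_communities <= n_nodes`.
#' @param p_in,p_out connection probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return list with `edges` (data.frame node1, node2, combined_score) and
#'   `truth` (`communities`: named membership vector).
#' @export
simulate_interactions <- function(n_nodes = 60, n_communities = 3,
                                  p_in = 0.9, p_out = 0.05, seed = 1) {
  if (n_communities > n_nodes) stop("n_communities cannot exceed n_nodes")
  .check_number(p_in, "p_in", lower = 0, upper = 1)
  .check_number(p_out, "p_out", lower = 0, upper = 1)
  if (p_out >= p_in) stop("need p_out < p_in")
  with_seed(seed, {
    nodes <- sprintf("n%03d", seq_len(n_nodes))
    block <- rep(seq_len(n_communities), length.out = n_nodes)
    pairs <- utils::combn(n_nodes, 2L)
    same <- block[pairs[1L, ]] == block[pairs[2L, ]]
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < p
    edges <- data.frame(node1 = nodes[pairs[1L, keep]],
                        node2 = nodes[pairs[2L, keep]],
                        combined_score = round(stats::runif(sum(keep),
                                                            0.75, 0.999), 3),
                        stringsAsFactors = FALSE)
    list(edges = edges,
         truth = list(communities = stats::setNames(block, nodes)))
  })
}

#' Write a ground-truth sidecar as structured text
#'
#' One JSON document holding whichever planted-feature records the paired
#' generator produced; readable back with [read_truth_sidecar()].
#'
#' @param truth the `truth` element of a generator result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_sidecar
#' @export
read_truth_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
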