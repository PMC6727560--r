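# Weighted gene co-expression network construction and module analysis.
#
# The network is unsigned: similarity S_mn = |cor(m, n)| (Pearson, on
# log2(FPKM + 1)), adjacency a_mn = S_mn^beta with beta chosen as the lowest
# power achieving approximate scale-free topology, pairwise connectivity by
# topological overlap, average-linkage clustering of 1 - TOM, a top-down cut
# into modules of at least `min_size` genes, eigengenes as first principal
# components, and module-trait (sex) correlation.

#' Absolute Pearson correlation matrix
#'
#' @param m an [expression_matrix()] of FPKM values (log2(x+1) is applied
#'   internally) or a plain numeric genes-by-samples matrix used as is.
#' @return symmetric matrix of `|cor|` values with unit diagonal.
#' @export
similarity <- function(m) {
  X <- if (inherits(m, "expression_matrix")) log2(m$values + 1) else m
  if (ncol(X) < 3) stop("similarity needs >= 3 samples")
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene present: ", rownames(X)[sds == 0][1L])
  S <- abs(stats::cor(t(X)))
  diag(S) <- 1
  S
}

# scale-free topology fit on a connectivity vector: bin k into `nbins`
# log-spaced bins, regress log10(frequency) on log10(mean k), and report
# R^2 signed by the slope (scale-free requires a negative slope).
#' Scale-free fit index for a connectivity distribution
#'
#' @param k positive connectivities.
#' @param nbins number of logarithmically spaced bins (default 10).
#' @return list with `r2` (signed by the slope), `slope`, and the bin table.
#' @export
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) stop("degenerate fit: all connectivities identical")
  breaks <- 10^seq(log10(min(k)), log10(max(k)), length.out = nbins + 1)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  km <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  keep <- !is.na(km)
  km <- km[keep]; freq <- freq[keep]
  if (length(km) < 2) stop("degenerate fit: connectivities collapse to one bin")
  fit <- stats::lm(log10(freq) ~ log10(km))
  slope <- unname(stats::coef(fit)[2L])
  # summary.lm warns on an exactly perfect fit; that case is legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(r2 = -sign(slope) * r2, slope = slope,
       bins = data.frame(mean_k = as.numeric(km), freq = as.numeric(freq)))
}

#' Choose the soft-threshold power
#'
#' For each candidate power the similarity matrix is raised elementwise,
#' connectivities are computed, and the scale-free fit index is evaluated
#' with [scale_free_fit()]. The lowest power whose signed R^2 reaches
#' `r2_cut` is returned; if none qualifies, the power maximising R^2 is
#' returned with `reached_cut = FALSE`.
#'
#' @param S similarity matrix from [similarity()].
#' @param powers candidate integer powers, default 1:20.
#' @param r2_cut acceptance cut on the signed R^2, default 0.8.
#' @param nbins bins for the fit.
#' @return list with `beta`, `reached_cut`, and `fit_table` (power, r2,
#'   slope, mean_k).
#' @export
pick_soft_threshold <- function(S, powers = 1:20, r2_cut = 0.8, nbins = 10) {
  if (length(powers) < 2) stop("need >= 2 candidate powers")
  rows <- lapply(powers, function(b) {
    A <- S^b; diag(A) <- 0
    k <- rowSums(A)
    if (length(unique(k)) < 2)
      stop("degenerate fit: all connectivities identical at power ", b)
    f <- scale_free_fit(k, nbins = nbins)
    data.frame(power = b, r2 = f$r2, slope = f$slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r2 >= r2_cut)
  if (length(ok) > 0) {
    list(beta = tab$power[ok[1L]], reached_cut = TRUE, fit_table = tab)
  } else {
    warning("no power reached the scale-free R^2 cut; returning the best fit")
    list(beta = tab$power[which.max(tab$r2)], reached_cut = FALSE,
         fit_table = tab)
  }
}

#' Soft-thresholded adjacency
#'
#' Elementwise power of the similarity matrix; the diagonal is set to zero
#' so that connectivity k_m = sum over u != m of a_mu is a plain row sum.
#'
#' @param S similarity matrix.
#' @param beta integer power >= 1.
#' @return adjacency matrix with zero diagonal.
#' @export
adjacency <- function(S, beta) {
  .check_number(beta, "beta", lower = 1)
  A <- S^beta
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' T_mn = (sum over shared neighbours u of a_mu a_un + a_mn) /
#' (min(k_m, k_n) + 1 - a_mn), with unit diagonal. Because the adjacency
#' diagonal is zero the matrix product A %*% A is exactly the
#' shared-neighbour sum.
#'
#' @param A adjacency matrix from [adjacency()].
#' @return symmetric TOM with values in `[0, 1]` and unit diagonal.
#' @export
tom <- function(A) {
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  T <- (L + A) / denom
  diag(T) <- 1
  dimnames(T) <- dimnames(A)
  T
}

#' Average-linkage clustering of the TOM dissimilarity
#'
#' @param T TOM from [tom()].
#' @return an [stats::hclust] dendrogram on dissimilarity 1 - TOM.
#' @export
cluster_genes <- function(T) {
  if (nrow(T) < 2) stop("clustering needs >= 2 genes")
  stats::hclust(stats::as.dist(1 - T), method = "average")
}

# module label palette, ordered by module size like the field's convention
.module_palette <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq_len(n - length(base))))
}

#' Cut a dendrogram into modules
#'
#' A static top-down cut at the `cut_height_q` quantile of the merge
#' heights; clusters of at least `min_size` genes become modules (labelled
#' by size, largest first), smaller clusters are "unassigned".
#'
#' @param dendrogram an [stats::hclust] object from [cluster_genes()].
#' @param min_size minimum module size, default 50.
#' @param cut_height_q quantile of merge heights for the cut, default 0.99.
#' @return named character vector of module labels per gene.
#' @export
cut_modules <- function(dendrogram, min_size = 50, cut_height_q = 0.99) {
  .check_number(min_size, "min_size", lower = 2)
  .check_number(cut_height_q, "cut_height_q", lower = 0, upper = 1)
  # ties can leave average-linkage heights non-monotone by float noise,
  # which cutree rejects; clamp before cutting
  dendrogram$height <- cummax(dendrogram$height)
  h <- stats::quantile(dendrogram$height, cut_height_q, names = FALSE)
  cl <- stats::cutree(dendrogram, h = h)
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_size]
  if (length(big) == 0)
    warning("no cluster reaches min_size; all genes unassigned")
  labels <- rep("unassigned", length(cl))
  pal <- .module_palette(length(big))
  for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- pal[i]
  names(labels) <- dendrogram$labels
  labels
}

#' Module eigengene
#'
#' First principal component across samples of the per-gene standardised
#' member submatrix, unit-normalised, with the sign fixed so that the mean
#' correlation with the member expression profiles is nonnegative.
#'
#' @param m an [expression_matrix()] (log2(x+1) applied internally) or a
#'   plain genes-by-samples matrix used as is.
#' @param members gene identifiers of the module.
#' @return numeric per-sample vector of unit norm.
#' @export
module_eigengene <- function(m, members) {
  X <- if (inherits(m, "expression_matrix")) log2(m$values + 1) else m
  missing <- setdiff(members, rownames(X))
  if (length(missing) > 0) stop("member gene missing: ", missing[1L])
  if (length(members) < 2) stop("eigengene needs >= 2 member genes")
  if (ncol(X) < 3) stop("eigengene needs >= 3 samples")
  Z <- t(scale(t(X[members, , drop = FALSE])))
  if (any(is.na(Z))) stop("zero-variance member gene; remove constants first")
  sv <- svd(Z, nu = 0, nv = 1)
  e <- sv$v[, 1L]
  mc <- mean(stats::cor(e, t(Z)))
  if (mc < 0) e <- -e
  names(e) <- colnames(X)
  e
}

#' Compute eigengenes for every module
#' @param m expression input as in [module_eigengene()].
#' @param labels module labels from [cut_modules()].
#' @return matrix, one column per module (unassigned genes are skipped).
#' @export
module_eigengenes <- function(m, labels) {
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods) == 0) stop("no modules to compute eigengenes for")
  sapply(mods, function(md) module_eigengene(m, names(labels)[labels == md]))
}

#' Merge modules with close eigengenes
#'
#' Modules whose eigengene correlation exceeds `1 - merge_cut` are merged,
#' closest pair first, recomputing eigengenes after each merge, until no
#' pair qualifies. The merged module keeps the label of the larger member.
#'
#' @param m expression input as in [module_eigengene()].
#' @param labels module labels from [cut_modules()].
#' @param merge_cut dissimilarity threshold in (0, 1), default 0.25.
#' @return updated label vector.
#' @export
merge_close_modules <- function(m, labels, merge_cut = 0.25) {
  .check_number(merge_cut, "merge_cut")
  if (merge_cut <= 0 || merge_cut >= 1) stop("'merge_cut' must be in (0, 1)")
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2) break
    E <- module_eigengenes(m, labels)
    C <- stats::cor(E)
    diag(C) <- -Inf
    best <- which(C == max(C), arr.ind = TRUE)[1L, ]
    if (C[best[1L], best[2L]] <= 1 - merge_cut) break
    a <- colnames(E)[best[1L]]; b <- colnames(E)[best[2L]]
    keep <- if (sum(labels == a) >= sum(labels == b)) a else b
    labels[labels %in% c(a, b)] <- keep
  }
  labels
}

#' Correlate module eigengenes with a binary trait
#'
#' Pearson correlation between each eigengene and the 0/1 indicator
#' (female = 1, male = 0, so positive r means female-associated), with the
#' p value from the t distribution on n - 2 degrees of freedom.
#'
#' @param eigengenes matrix from [module_eigengenes()] (samples x modules).
#' @param trait numeric or logical per-sample indicator.
#' @return data.frame with `module`, `r`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  trait <- as.numeric(trait)
  if (length(trait) != nrow(eigengenes))
    stop("trait must be defined for every sample")
  if (stats::sd(trait) == 0) stop("constant trait")
  n <- length(trait)
  r <- as.numeric(stats::cor(eigengenes, trait))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  data.frame(module = colnames(eigengenes), r = r, p = p,
             stringsAsFactors = FALSE)
}

#' Gene and module significance
#'
#' Gene significance is GS = -log10(p) of the gene's trait association
#' (p = 0 is capped at `cap` and flagged); module significance is the mean
#' GS over module members.
#'
#' @param de_p named vector of per-gene p values.
#' @param labels module labels from [cut_modules()].
#' @param cap GS cap for p = 0, default 300.
#' @return list with `gs` (data.frame gene_id, gs, capped) and `ms`
#'   (data.frame module, ms).
#' @export
significance <- function(de_p, labels, cap = 300) {
  if (any(is.na(de_p) | de_p < 0 | de_p > 1)) stop("p values must be in [0, 1]")
  capped <- de_p == 0
  gs <- ifelse(capped, cap, -log10(de_p))
  gs <- pmin(gs, cap)
  gs_tab <- data.frame(gene_id = names(de_p), gs = unname(gs),
                       capped = unname(capped), stringsAsFactors = FALSE)
  mods <- setdiff(unique(labels), "unassigned")
  ms <- vapply(mods, function(md) {
    members <- intersect(names(labels)[labels == md], names(de_p))
    mean(gs[members])
  }, numeric(1))
  list(gs = gs_tab, ms = data.frame(module = mods, ms = unname(ms),
                                    stringsAsFactors = FALSE))
}

#' Full co-expression module pipeline
#'
#' Similarity, soft-threshold selection, adjacency, TOM, clustering, module
#' cut, merge, eigengenes, and trait correlation in one call.
#'
#' @param m an [expression_matrix()].
#' @param trait per-sample binary trait (female = 1); defaults to the sex
#'   column of the sample annotation.
#' @param powers,r2_cut passed to [pick_soft_threshold()].
#' @param min_size,cut_height_q passed to [cut_modules()].
#' @param merge_cut passed to [merge_close_modules()].
#' @return list with `beta`, `fit_table`, `labels`, `eigengenes`,
#'   `trait_correlation`, `dendrogram`.
#' @export
wgcna_modules <- function(m, trait = NULL, powers = 1:20, r2_cut = 0.8,
                          min_size = 50, cut_height_q = 0.99,
                          merge_cut = 0.25) {
  stopifnot(inherits(m, "expression_matrix"))
  if (is.null(trait)) trait <- as.numeric(m$samples$sex == "female")
  S <- similarity(m)
  pick <- pick_soft_threshold(S, powers = powers, r2_cut = r2_cut)
  A <- adjacency(S, pick$beta)
  TOM <- tom(A)
  dend <- cluster_genes(TOM)
  labels <- cut_modules(dend, min_size = min_size, cut_height_q = cut_height_q)
  if (!all(labels == "unassigned"))
    labels <- merge_close_modules(m, labels, merge_cut = merge_cut)
  res <- list(beta = pick$beta, fit_table = pick$fit_table, labels = labels,
              eigengenes = NULL, trait_correlation = NULL, dendrogram = dend)
  if (!all(labels == "unassigned")) {
    res$eigengenes <- module_eigengenes(m, labels)
    res$trait_correlation <- module_trait_correlation(res$eigengenes, trait)
  }
  res
}
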