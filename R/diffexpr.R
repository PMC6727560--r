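# Per-gene two-sample testing between the sexes with FDR control.
#
# The test is Welch's unequal-variance t statistic on log2(FPKM + 1); the
# multiplicity correction is Benjamini-Hochberg. A gene is called XX
# (female-enriched) when q < alpha with a positive female-minus-male mean
# difference, XY when the difference is negative, and nb otherwise.

#' Welch two-sample t test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p value. Degenerate inputs follow fixed conventions: two
#' zero-variance groups with equal means give t = 0, p = 1; zero pooled
#' variance with unequal means gives t = +/-Inf, p = 0 (flagged degenerate).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t_stat`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("values must be finite")
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / length(a) + vb / length(b)
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    if (d == 0) return(list(t_stat = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t_stat = sign(d) * Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  t_stat <- d / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(t_stat = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       degenerate = FALSE)
}

# row-wise Welch test; X is genes x samples, grp a logical vector selecting
# group a. Returns a data.frame(t_stat, df, p). Vectorised because the null
# calibration runs thousands of genes per seed.
.welch_rows <- function(X, grp) {
  Xa <- X[, grp, drop = FALSE]; Xb <- X[, !grp, drop = FALSE]
  na <- ncol(Xa); nb <- ncol(Xb)
  ma <- rowMeans(Xa); mb <- rowMeans(Xb)
  va <- rowSums((Xa - ma)^2) / (na - 1)
  vb <- rowSums((Xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  d <- ma - mb
  t_stat <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  deg <- se2 == 0
  if (any(deg)) {          # zero variance in both groups
    t_stat[deg] <- ifelse(d[deg] == 0, 0, sign(d[deg]) * Inf)
    p[deg] <- ifelse(d[deg] == 0, 1, 0)
    df[deg] <- NA_real_
  }
  data.frame(mean_female = ma, mean_male = mb, delta = d,
             t_stat = t_stat, df = df, p = p, degenerate = deg)
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up procedure: q_(i) = min over j >= i of min(1, p_(j) * m / j), with
#' the original order restored.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return numeric vector of q values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q <- pmin(1, p_values[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  q[order(o)]
}

#' Assign bias codes from adjusted p values
#'
#' @param de data.frame with columns `q` and `delta` (female minus male).
#' @param alpha FDR threshold, strict: a gene is biased only when `q < alpha`.
#'   The single-cell stages use 0.05; the cardiac-precursor bulk comparison
#'   uses 0.01.
#' @return `de` with a `bias` column in `{"XX","XY","nb"}`.
#' @export
call_bias <- function(de, alpha = 0.05) {
  .check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie strictly in (0, 1)")
  bias <- rep("nb", nrow(de))
  sig <- !is.na(de$q) & de$q < alpha
  bias[sig & de$delta > 0] <- "XX"
  bias[sig & de$delta < 0] <- "XY"
  de$bias <- bias
  de
}

#' Differential sex-bias test for one stage
#'
#' Composes the pipeline filters with the test: restrict to the stage's
#' samples, attach sex labels (from a [sex_cells()] call table for
#' single-cell stages, or from the sample annotation for bulk designs),
#' drop ambiguous/unassigned cells, flag genes failing the FPKM presence
#' rule in both sexes as absent, drop zero-variance genes among the tested
#' set, run the Welch test per gene on log2(FPKM + 1), adjust with
#' Benjamini-Hochberg, and call biases.
#'
#' @param m an [expression_matrix()] of FPKM values.
#' @param stage stage label; `NULL` uses all samples.
#' @param sex_source either a data.frame from [sex_cells()] (matched by
#'   `cell_id`) or `NULL` to use the `sex` column of the sample annotation.
#' @param alpha FDR threshold for [call_bias()].
#' @param presence_threshold FPKM floor for [filter_not_expressed()].
#' @return data.frame with one row per gene: `gene_id`, `mean_female`,
#'   `mean_male`, `delta`, `t_stat`, `df`, `p`, `q`, `bias` (with `"absent"`
#'   for genes failing presence, which carry NA statistics).
#' @export
stage_de <- function(m, stage = NULL, sex_source = NULL, alpha = 0.05,
                     presence_threshold = 1.0) {
  stopifnot(inherits(m, "expression_matrix"))
  samples <- m$samples
  if (!is.null(stage)) {
    if (!stage %in% stage_levels()) stop("unknown stage: ", stage)
    keep <- !is.na(samples$stage) & samples$stage == stage
  } else keep <- rep(TRUE, nrow(samples))
  sex <- samples$sex
  if (!is.null(sex_source)) {
    idx <- match(samples$sample_id, sex_source$cell_id)
    sex <- ifelse(is.na(idx), "unknown", sex_source$call[idx])
  }
  usable <- keep & sex %in% c("male", "female")
  stage_name <- if (is.null(stage)) "all" else stage
  if (sum(usable & sex == "female") < 2 || sum(usable & sex == "male") < 2)
    stop(sprintf("stage %s needs >= 2 usable samples per sex", stage_name))

  vals <- m$values[, usable, drop = FALSE]
  sexu <- sex[usable]
  # presence: mean FPKM >= threshold in at least one sex at this stage
  pres <- rowMeans(vals[, sexu == "female", drop = FALSE]) >= presence_threshold |
          rowMeans(vals[, sexu == "male", drop = FALSE]) >= presence_threshold
  logv <- log2(vals + 1)
  out <- data.frame(gene_id = rownames(vals),
                    mean_female = NA_real_, mean_male = NA_real_,
                    delta = NA_real_, t_stat = NA_real_, df = NA_real_,
                    p = NA_real_, q = NA_real_, bias = "absent",
                    stringsAsFactors = FALSE)
  testable <- pres & apply(logv, 1L, function(r) any(r != r[1L]))
  constant <- pres & !testable        # expressed but flat: nb by convention
  out$bias[constant] <- "nb"
  if (any(testable)) {
    res <- .welch_rows(logv[testable, , drop = FALSE], sexu == "female")
    res$q <- bh_fdr(res$p)
    res <- call_bias(res, alpha)
    out[testable, c("mean_female", "mean_male", "delta", "t_stat",
                    "df", "p", "q", "bias")] <-
      res[, c("mean_female", "mean_male", "delta", "t_stat",
              "df", "p", "q", "bias")]
  }
  out
}
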