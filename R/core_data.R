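# Expression container, TSV I/O, and the expression filters applied before
# every downstream stage.

#' Developmental stages, in order
#'
#' The ordered set of stages the pipeline knows about: embryonic stem cells
#' (ES), derived cardiac precursors (CP), embryonic hearts at 8.5, 9.5 and
#' 10.5 days post coitum, neonatal hearts (P1), and adult hearts.
#'
#' @return character vector of stage labels in developmental order.
#' @export
stage_levels <- function() {
  c("ES", "CP", "E8.5", "E9.5", "E10.5", "P1", "Adult")
}

.default_gene_annotation <- function(gene_id) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id,
             symbol = gene_id,
             chromosome = rep(NA_character_, n),
             tss = rep(NA_integer_, n),
             strand = rep(NA_character_, n),
             reg_class = rep("other", n),
             stringsAsFactors = FALSE)
}

.default_sample_annotation <- function(sample_id) {
  data.frame(sample_id = sample_id,
             sex = "unknown",
             stage = NA_character_,
             batch = NA_character_,
             cross = NA_character_,
             stringsAsFactors = FALSE)
}

#' Construct an expression matrix with gene and sample annotations
#'
#' The central container of the package: a nonnegative gene-by-sample matrix
#' of FPKM values plus one annotation row per gene (`gene_id`, `symbol`,
#' `chromosome`, `tss`, `strand`, `reg_class`) and per sample (`sample_id`,
#' `sex`, `stage`, `batch`, `cross`). Missing annotation columns are filled
#' with defaults (`reg_class = "other"`, `sex = "unknown"`).
#'
#' @param values numeric matrix, genes in rows, samples in columns; row and
#'   column names are used as gene and sample identifiers.
#' @param genes optional data.frame of gene annotations keyed by `gene_id`.
#' @param samples optional data.frame of sample annotations keyed by
#'   `sample_id`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes = NULL, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("'values' must have gene identifiers as row names")
  gene_ids <- if (is.null(rownames(values))) character(0)
              else rownames(values)
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("'values' must have sample identifiers as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene_id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (nrow(values) > 0 && ncol(values) > 0) {
    bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "negative or non-finite expression value for gene '%s', sample '%s'",
        rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  }
  if (is.null(genes)) genes <- .default_gene_annotation(gene_ids)
  if (is.null(samples)) samples <- .default_sample_annotation(colnames(values))
  genes <- .complete_gene_annotation(genes, gene_ids)
  samples <- .complete_sample_annotation(samples, colnames(values))
  structure(list(values = values, genes = genes, samples = samples),
            class = "expression_matrix")
}

.complete_gene_annotation <- function(genes, gene_ids) {
  if (!"gene_id" %in% names(genes)) stop("gene annotation needs a 'gene_id' column")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  missing <- setdiff(gene_ids, genes$gene_id)
  if (length(missing) > 0)
    genes <- rbind(genes[, intersect(names(genes),
                                     names(.default_gene_annotation("x"))),
                         drop = FALSE] |> .pad_gene_cols(),
                   .default_gene_annotation(missing))
  else genes <- .pad_gene_cols(genes)
  genes <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes$reg_class[is.na(genes$reg_class)] <- "other"
  bad <- !genes$reg_class %in% c("TF", "ERE", "other")
  if (any(bad)) stop("unknown reg_class: ", genes$reg_class[bad][1L])
  if (any(!is.na(genes$tss) & genes$tss < 0)) stop("tss must be >= 0")
  if (any(!is.na(genes$strand) & !genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  genes
}

.pad_gene_cols <- function(genes) {
  tmpl <- .default_gene_annotation(genes$gene_id)
  for (nm in names(tmpl)) if (!nm %in% names(genes)) genes[[nm]] <- tmpl[[nm]]
  genes[, names(tmpl), drop = FALSE]
}

.complete_sample_annotation <- function(samples, sample_ids) {
  if (!"sample_id" %in% names(samples))
    stop("sample annotation needs a 'sample_id' column")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in annotation: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  missing <- setdiff(sample_ids, samples$sample_id)
  if (length(missing) > 0)
    stop("sample in matrix missing from annotation: ", missing[1L])
  tmpl <- .default_sample_annotation(samples$sample_id)
  for (nm in names(tmpl)) if (!nm %in% names(samples)) samples[[nm]] <- tmpl[[nm]]
  samples <- samples[match(sample_ids, samples$sample_id), names(tmpl),
                     drop = FALSE]
  rownames(samples) <- NULL
  samples$sex[is.na(samples$sex)] <- "unknown"
  bad <- !samples$sex %in% c("male", "female", "unknown")
  if (any(bad)) stop("unknown sex label: ", samples$sex[bad][1L])
  bad <- !is.na(samples$stage) & !samples$stage %in% stage_levels()
  if (any(bad)) stop("unknown stage label: ", samples$stage[bad][1L])
  samples
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  stages <- table(x$samples$stage, useNA = "no")
  if (length(stages) > 0)
    cat("stages:", paste(sprintf("%s=%d", names(stages), stages),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its annotations from TSV files
#'
#' The matrix dialect is tab-separated UTF-8 with a "." decimal separator and
#' no quoting: first column `gene_id`, header row of sample identifiers, one
#' gene per row. The annotation file is also tab-separated and may contain a
#' gene block (columns `gene_id`, `symbol`, `chromosome`, `tss`, `strand`,
#' `reg_class`) and/or a sample block (`sample_id`, `sex`, `stage`, `batch`,
#' `cross`); `annotation_path` may also be a list with elements `genes` and
#' `samples` pointing at two separate files. Missing values are not
#' permitted in the matrix.
#'
#' @param path path to the expression TSV.
#' @param annotation_path optional annotation TSV path or
#'   `list(genes =, samples =)` of paths.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, annotation_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(tab) < 1) stop("expression table needs a gene_id column")
  gene_id <- as.character(tab[[1L]])
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (nrow(vals) > 0 && ncol(vals) > 0) {
    suppressWarnings(storage.mode(vals) <- "double")
    bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("negative or non-numeric value for gene '%s', sample '%s'",
                   gene_id[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  rownames(vals) <- gene_id
  genes <- samples <- NULL
  if (!is.null(annotation_path)) {
    paths <- if (is.list(annotation_path)) annotation_path
             else list(genes = annotation_path, samples = annotation_path)
    read_ann <- function(p) if (is.null(p)) NULL else
      utils::read.table(p, header = TRUE, sep = "\t", quote = "",
                        check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "")
    ga <- read_ann(paths$genes)
    sa <- read_ann(paths$samples)
    if (!is.null(ga) && "gene_id" %in% names(ga)) genes <- ga
    if (!is.null(sa) && "sample_id" %in% names(sa)) samples <- sa
  }
  expression_matrix(vals, genes = genes, samples = samples)
}

#' Write an expression matrix (and optionally its annotations) to TSV
#'
#' Emits the dialect read back by [read_expression_tsv()]. Values are
#' formatted with enough digits that a write/read round trip reproduces them
#' to at least 6 decimal places.
#'
#' @param m an [expression_matrix()].
#' @param path output path for the matrix TSV.
#' @param annotation_path optional `list(genes =, samples =)` of output paths
#'   for the two annotation tables.
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(m, path, annotation_path = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m$values)), collapse = "\t"), con)
  if (nrow(m$values) > 0) {
    body <- apply(m$values, 1L, function(r)
      paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(rownames(m$values), body,
                     sep = if (ncol(m$values) > 0) "\t" else ""), con)
  }
  if (!is.null(annotation_path)) {
    if (!is.null(annotation_path$genes))
      utils::write.table(m$genes, annotation_path$genes, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(annotation_path$samples))
      utils::write.table(m$samples, annotation_path$samples, sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Flag values and genes below the expression floor
#'
#' A value below `threshold` FPKM is designated not expressed. A gene counts
#' as expressed at a stage when its mean FPKM over that stage's samples
#' reaches the threshold within at least one sex group; samples of unknown
#' sex form their own group so single-sex or unsexed designs still yield a
#' presence call.
#'
#' @param m an [expression_matrix()].
#' @param threshold FPKM floor, default 1.
#' @return list with elements `matrix` (the input), `not_expressed`
#'   (gene-by-sample logical), and `expressed` (gene-by-stage logical for the
#'   stages present in the sample annotation).
#' @export
filter_not_expressed <- function(m, threshold = 1.0) {
  stopifnot(inherits(m, "expression_matrix"))
  .check_number(threshold, "threshold", lower = 0)
  not_expressed <- m$values < threshold
  stages <- unique(m$samples$stage[!is.na(m$samples$stage)])
  expressed <- matrix(NA, nrow(m$values), length(stages),
                      dimnames = list(rownames(m$values), stages))
  for (st in stages) {
    in_stage <- !is.na(m$samples$stage) & m$samples$stage == st
    sexes <- unique(m$samples$sex[in_stage])
    hit <- rep(FALSE, nrow(m$values))
    for (sx in sexes) {
      cols <- in_stage & m$samples$sex == sx
      hit <- hit | rowMeans(m$values[, cols, drop = FALSE]) >= threshold
    }
    expressed[, st] <- hit
  }
  list(matrix = m, not_expressed = not_expressed, expressed = expressed)
}

#' Drop genes with zero variance across all samples
#'
#' Genes whose values are identical in every sample carry no information for
#' testing or correlation and are removed; the order of the remaining genes
#' is preserved. Removing everything is legal but warned about.
#'
#' @param m an [expression_matrix()].
#' @return an [expression_matrix()] without the constant genes.
#' @export
drop_zero_variance <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (nrow(m$values) == 0) return(m)
  keep <- apply(m$values, 1L, function(r) length(r) > 0 && any(r != r[1L]))
  if (!any(keep)) warning("all genes have zero variance; result is empty")
  expression_matrix(m$values[keep, , drop = FALSE],
                    genes = m$genes[keep, , drop = FALSE],
                    samples = m$samples)
}

#' log2(x + 1) transform
#'
#' All downstream statistics (tests, correlations, eigengenes) operate on
#' log2(FPKM + 1); this is the one place the transform is defined.
#'
#' @param m an [expression_matrix()] of nonnegative values.
#' @return an [expression_matrix()] on the log scale.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  expression_matrix(log2(m$values + 1), genes = m$genes, samples = m$samples)
}
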