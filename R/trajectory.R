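# Cross-stage bias trajectories: integrate per-stage bias calls into a
# gene x stage table of codes {XX, XY, nb, absent} and classify each gene's
# trajectory into the developmental groups:
#
#   I   biased in ES cells, not expressed at any later stage
#   II  biased in ES cells with later bias(es), all in the same direction
#   III biased in ES cells with an opposite-direction bias at a later stage
#   IV  not biased in ES cells; first bias after implantation but before
#       gonadogenesis (CP, E8.5, E9.5 or E10.5)
#   V   first bias only after gonadogenesis (P1 or Adult)
#
# plus the residual class "lost" (ES-biased, remains expressed later but
# never biased again) and "never_biased". The gonadogenesis boundary sits
# between E10.5 and P1: gonads differentiate after E10.5, so biases up to
# E10.5 predate sex hormones.

.bias_codes <- c("XX", "XY", "nb", "absent")
.pregonadal_stages <- c("CP", "E8.5", "E9.5", "E10.5")
.postgonadal_stages <- c("P1", "Adult")

#' Build a bias table from per-stage differential results
#'
#' Per gene and stage: `absent` when the gene fails the presence rule at
#' that stage, otherwise the stage's bias call (`XX`, `XY` or `nb`). Stages
#' without results are `absent`.
#'
#' @param stage_results named list mapping stage label to a [stage_de()]
#'   result (whose `bias` column already encodes absent).
#' @param genes optional gene annotation data.frame (`gene_id`,
#'   `chromosome`, ...) attached to the table.
#' @return a `bias_table`: list with `codes` (gene x stage character
#'   matrix over all of [stage_levels()]) and `genes`.
#' @export
build_bias_table <- function(stage_results, genes = NULL) {
  if (is.null(names(stage_results)) ||
      !all(names(stage_results) %in% stage_levels()))
    stop("stage_results must be named by stage labels")
  gene_ids <- unique(unlist(lapply(stage_results, function(d) d$gene_id)))
  codes <- matrix("absent", length(gene_ids), length(stage_levels()),
                  dimnames = list(gene_ids, stage_levels()))
  for (st in names(stage_results)) {
    d <- stage_results[[st]]
    if (anyDuplicated(d$gene_id))
      stop("conflicting duplicate gene entries at stage ", st, ": ",
           d$gene_id[duplicated(d$gene_id)][1L])
    codes[d$gene_id, st] <- d$bias
  }
  if (!all(codes %in% .bias_codes)) stop("invalid bias code in stage results")
  if (is.null(genes)) genes <- .default_gene_annotation(gene_ids)
  structure(list(codes = codes,
                 genes = .complete_gene_annotation(genes, gene_ids)),
            class = "bias_table")
}

#' Read a bias table from TSV
#'
#' Expected columns: `gene`, the seven stage columns `ES`, `CP`, `8.5`,
#' `9.5`, `10.5`, `p1`, `Adult` (or the equivalent [stage_levels()] names),
#' and `Chr`. Empty cells map to `absent`; any other cell must be exactly
#' `XX`, `XY` or `nb` (codes are strict, case-sensitive). Extra columns are
#' ignored.
#'
#' @param path TSV path.
#' @return a `bias_table`.
#' @export
read_bias_table_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", na.strings = NULL,
                           colClasses = "character")
  alias <- c("ES" = "ES", "CP" = "CP", "8.5" = "E8.5", "E8.5" = "E8.5",
             "9.5" = "E9.5", "E9.5" = "E9.5", "10.5" = "E10.5",
             "E10.5" = "E10.5", "p1" = "P1", "P1" = "P1", "Adult" = "Adult")
  stage_cols <- names(tab)[names(tab) %in% names(alias)]
  if (length(unique(alias[stage_cols])) != 7)
    stop("bias table must contain all seven stage columns")
  if (!"gene" %in% names(tab)) stop("bias table needs a 'gene' column")
  if (anyDuplicated(tab$gene))
    stop("duplicate gene: ", tab$gene[duplicated(tab$gene)][1L])
  codes <- matrix("absent", nrow(tab), 7,
                  dimnames = list(tab$gene, stage_levels()))
  for (cl in stage_cols) {
    v <- tab[[cl]]
    v[is.na(v) | v == ""] <- "absent"
    bad <- which(!v %in% .bias_codes)
    if (length(bad) > 0)
      stop(sprintf("unknown bias code '%s' in row %d (gene %s)",
                   tab[[cl]][bad[1L]], bad[1L], tab$gene[bad[1L]]))
    codes[, alias[cl]] <- v
  }
  genes <- .default_gene_annotation(tab$gene)
  if ("Chr" %in% names(tab)) genes$chromosome <- tab$Chr
  if ("reg_class" %in% names(tab)) genes$reg_class <- tab$reg_class
  structure(list(codes = codes, genes = genes, extra = tab),
            class = "bias_table")
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("bias_table: %d genes x %d stages\n",
              nrow(x$codes), ncol(x$codes)))
  print(table(factor(x$codes, levels = .bias_codes)))
  invisible(x)
}

#' Classify one bias trajectory
#'
#' @param row character vector of codes over the ordered stages
#'   (length 7, values in `{"XX","XY","nb","absent"}`).
#' @return list with `group` (one of I, II, III, IV, V, lost,
#'   never_biased), `first_bias_stage` (or NA), and `transitions`
#'   (data.frame from, to, type for consecutive stage pairs where both
#'   codes are not absent).
#' @export
classify <- function(row) {
  stages <- stage_levels()
  if (length(row) != length(stages)) stop("trajectory must cover all stages")
  if (!all(row %in% .bias_codes)) stop("invalid bias code")
  biased <- row %in% c("XX", "XY")
  first <- if (any(biased)) stages[which(biased)[1L]] else NA_character_
  es <- row[1L]; later <- row[-1L]
  if (es %in% c("XX", "XY")) {
    later_biased <- later[later %in% c("XX", "XY")]
    if (all(later == "absent")) group <- "I"
    else if (length(later_biased) == 0) group <- "lost"
    else if (any(later_biased != es)) group <- "III"
    else group <- "II"
  } else if (!any(biased)) {
    group <- "never_biased"
  } else if (first %in% .pregonadal_stages) {
    group <- "IV"
  } else {
    group <- "V"
  }
  # transitions run between consecutive stages at which the gene is
  # expressed, skipping absent stretches (a bias that reappears in the
  # opposite direction after a gap still counts as a reversal)
  present <- which(row != "absent")
  if (length(present) >= 2) {
    a <- present[-length(present)]; b <- present[-1L]
    transitions <- data.frame(from = stages[a], to = stages[b],
                              type = vapply(seq_along(a), function(i)
                                .transition_type(row[a[i]], row[b[i]]),
                                character(1)),
                              stringsAsFactors = FALSE)
  } else {
    transitions <- data.frame(from = character(0), to = character(0),
                              type = character(0))
  }
  list(group = group, first_bias_stage = first, transitions = transitions)
}

.transition_type <- function(a, b) {
  ab <- a %in% c("XX", "XY"); bb <- b %in% c("XX", "XY")
  if (ab && bb) { if (a == b) "maintain" else "reverse" }
  else if (ab) "lose"
  else if (bb) "acquire"
  else "none"
}

#' Classify every gene of a bias table
#'
#' @param table a `bias_table`.
#' @return data.frame with `gene`, `group`, `first_bias_stage`.
#' @export
classify_trajectories <- function(table) {
  stopifnot(inherits(table, "bias_table"))
  res <- apply(table$codes, 1L, classify)
  data.frame(gene = rownames(table$codes),
             group = vapply(res, `[[`, character(1), "group"),
             first_bias_stage = vapply(res, `[[`, character(1),
                                       "first_bias_stage"),
             stringsAsFactors = FALSE)
}

#' Count genes with the same bias at two stages
#'
#' A gene counts as conserved when it carries an identical, non-nb,
#' non-absent code at both stages, optionally restricted to one direction.
#'
#' @param table a `bias_table`.
#' @param stage_a,stage_b stage labels.
#' @param direction `"XX"`, `"XY"`, or `"either"`.
#' @return integer count.
#' @export
conserved_count <- function(table, stage_a, stage_b, direction = "either") {
  stopifnot(inherits(table, "bias_table"))
  for (st in c(stage_a, stage_b))
    if (!st %in% colnames(table$codes)) stop("unknown stage: ", st)
  if (!direction %in% c("XX", "XY", "either"))
    stop("direction must be XX, XY or either")
  a <- table$codes[, stage_a]; b <- table$codes[, stage_b]
  hit <- a == b & a %in% c("XX", "XY")
  if (direction != "either") hit <- hit & a == direction
  sum(hit)
}

#' Genes with the same bias at two stages
#' @inheritParams conserved_count
#' @return character vector of gene identifiers.
#' @export
conserved_genes <- function(table, stage_a, stage_b, direction = "either") {
  stopifnot(inherits(table, "bias_table"))
  a <- table$codes[, stage_a]; b <- table$codes[, stage_b]
  hit <- a == b & a %in% c("XX", "XY")
  if (direction != "either") hit <- hit & a == direction
  rownames(table$codes)[hit]
}

#' Count X-linked genes in a subset
#'
#' @param subset gene identifiers.
#' @param annotation gene annotation data.frame with `gene_id` and
#'   `chromosome` covering the subset.
#' @return integer count of genes with chromosome `"X"`.
#' @export
x_linked_count <- function(subset, annotation) {
  idx <- match(subset, annotation$gene_id)
  if (any(is.na(idx))) stop("unannotated gene: ", subset[is.na(idx)][1L])
  chr <- annotation$chromosome[idx]
  if (any(is.na(chr))) stop("unannotated gene: ", subset[is.na(chr)][1L])
  sum(chr == "X")
}

#' Transition counts between two stages
#'
#' Genes absent at either stage are excluded from all four counts.
#'
#' @param table a `bias_table`.
#' @param stage_a,stage_b stage labels.
#' @return named integer vector: `maintain`, `lose`, `acquire`, `reverse`.
#' @export
transition_summary <- function(table, stage_a, stage_b) {
  stopifnot(inherits(table, "bias_table"))
  for (st in c(stage_a, stage_b))
    if (!st %in% colnames(table$codes)) stop("unknown stage: ", st)
  a <- table$codes[, stage_a]; b <- table$codes[, stage_b]
  present <- a != "absent" & b != "absent"
  ab <- a %in% c("XX", "XY"); bb <- b %in% c("XX", "XY")
  c(maintain = sum(present & ab & bb & a == b),
    lose = sum(present & ab & !bb),
    acquire = sum(present & !ab & bb),
    reverse = sum(present & ab & bb & a != b))
}

#' Genes making a given transition between two stages
#' @inheritParams transition_summary
#' @param type one of `"maintain"`, `"lose"`, `"acquire"`, `"reverse"`.
#' @return character vector of gene identifiers.
#' @export
transition_genes <- function(table, stage_a, stage_b, type) {
  stopifnot(inherits(table, "bias_table"))
  a <- table$codes[, stage_a]; b <- table$codes[, stage_b]
  present <- a != "absent" & b != "absent"
  ab <- a %in% c("XX", "XY"); bb <- b %in% c("XX", "XY")
  hit <- switch(type,
                maintain = present & ab & bb & a == b,
                lose = present & ab & !bb,
                acquire = present & !ab & bb,
                reverse = present & ab & bb & a != b,
                stop("unknown transition type: ", type))
  rownames(table$codes)[hit]
}
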