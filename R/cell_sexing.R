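# Single-cell sex inference from the Xist/Eif2s3y marker ratio.
#
# Xist (X-linked, high in females) and Eif2s3y (Y-linked, male-only) are
# oppositely biased markers; their per-cell FPKM ratio assigns sex. Cells
# with a ratio of at least 1.5 are called female and cells below 1 male.
# The ratio gap [1, 1.5) is not defined by either threshold, so such cells
# are labelled ambiguous; cells with both markers at zero are uninformative
# and labelled unassigned. Ratios are taken on raw FPKM, not a log scale.

#' Xist/Eif2s3y ratio for one or more cells
#'
#' `xist / eif2s3y` when the denominator is positive; `Inf` when only the
#' Y marker is silent (the female signature); `NaN` (undefined) when both
#' markers are zero.
#'
#' @param xist,eif2s3y nonnegative FPKM values, recycled to common length.
#' @return numeric vector of ratios (`Inf` and `NaN` as described).
#' @export
sex_ratio <- function(xist, eif2s3y) {
  if (any(!is.finite(xist) | xist < 0) || any(!is.finite(eif2s3y) | eif2s3y < 0))
    stop("marker FPKM values must be finite and >= 0")
  n <- max(length(xist), length(eif2s3y))
  xist <- rep_len(xist, n); eif2s3y <- rep_len(eif2s3y, n)
  ratio <- xist / eif2s3y            # x/0 -> Inf for x > 0, 0/0 -> NaN
  ratio
}

#' Sex call from a marker ratio
#'
#' Applies the thresholds exactly: ratio >= 1.5 is female, ratio < 1 is
#' male, the gap [1, 1.5) is ambiguous, and an undefined ratio (both
#' markers zero) is unassigned.
#'
#' @param ratio value(s) from [sex_ratio()].
#' @param female_cut,male_cut the two printed thresholds; defaults 1.5 and 1.
#' @return character vector in `{"female","male","ambiguous","unassigned"}`.
#' @export
call_sex <- function(ratio, female_cut = 1.5, male_cut = 1.0) {
  out <- rep("unassigned", length(ratio))
  defined <- !is.nan(ratio)
  out[defined & ratio >= female_cut] <- "female"
  out[defined & ratio < male_cut] <- "male"
  out[defined & ratio >= male_cut & ratio < female_cut] <- "ambiguous"
  out
}

#' Sex every cell of an expression matrix
#'
#' Looks up the two marker genes by row identifier and produces one call per
#' cell. Ambiguous and unassigned cells are flagged for exclusion from
#' downstream differential testing.
#'
#' @param m an [expression_matrix()] of single cells.
#' @param xist_id,eif2s3y_id row identifiers of the two marker genes.
#' @param female_cut,male_cut thresholds passed to [call_sex()].
#' @return data.frame with columns `cell_id`, `xist`, `eif2s3y`, `ratio`,
#'   `call`, `usable` (TRUE for male/female calls).
#' @export
sex_cells <- function(m, xist_id = "Xist", eif2s3y_id = "Eif2s3y",
                      female_cut = 1.5, male_cut = 1.0) {
  stopifnot(inherits(m, "expression_matrix"))
  for (g in c(xist_id, eif2s3y_id))
    if (!g %in% rownames(m$values))
      stop("marker gene absent from matrix: ", g)
  xist <- m$values[xist_id, ]
  eif <- m$values[eif2s3y_id, ]
  ratio <- sex_ratio(xist, eif)
  call <- call_sex(ratio, female_cut = female_cut, male_cut = male_cut)
  data.frame(cell_id = colnames(m$values),
             xist = unname(xist), eif2s3y = unname(eif),
             ratio = unname(ratio), call = call,
             usable = call %in% c("male", "female"),
             stringsAsFactors = FALSE)
}

#' Write a sex-call table as TSV
#' @param calls data.frame from [sex_cells()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sex_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
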