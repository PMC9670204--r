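#' Rank the three most intense unmodified peptides
#'
#' Eligible peptides are unmodified and present (non-missing area) in every
#' sample; they are ranked by mean area across all samples, descending,
#' with ties broken by peptide id (lexicographic).  One global top-3 set is
#' used for every sample, preserving cross-sample comparability.
#'
#' @param table long-format peak-area data.frame with columns `peptide_id`,
#'   `is_phospho`, `sample_id`, `area` (see [generate_peptide_table()] or
#'   [read_peptide_csv()]).
#' @return character vector of the top-3 unmodified peptide ids, in rank
#'   order.
#' @export
rank_unmodified <- function(table) {
  check_peptide_table(table)
  un <- table[!table$is_phospho & !is.na(table$area), , drop = FALSE]
  samples <- unique(table$sample_id)
  present <- vapply(split(un$sample_id, un$peptide_id),
                    function(s) all(samples %in% s), TRUE)
  eligible <- names(present)[present]
  if (length(eligible) < 3L) {
    stop("fewer than 3 unmodified peptides present in all samples")
  }
  un <- un[un$peptide_id %in% eligible, , drop = FALSE]
  means <- vapply(split(un$area, un$peptide_id), mean, 0)
  ord <- order(-means, names(means))
  names(means)[ord][1:3]
}

#' Top-3 unmodified-peptide normalization
#'
#' Each peak area is divided by the summed areas, in the same sample, of
#' the protein's three most intense unmodified peptides ([rank_unmodified()]).
#' The per-sample sum cancels loading/injection variation exactly:
#' multiplying every area of a sample by k > 0 leaves its normalized
#' values unchanged.
#'
#' @param table long-format peak-area data.frame (see [rank_unmodified()]).
#' @param reference_peptides optional explicit reference set (character,
#'   length 3); defaults to [rank_unmodified()] on the table.
#' @return the input data.frame with a `value` column (normalized
#'   abundance) appended; attribute `reference_peptides` records the set.
#' @export
normalize_peptides <- function(table, reference_peptides = NULL) {
  check_peptide_table(table)
  top3 <- reference_peptides %||% rank_unmodified(table)
  stopifnot(length(top3) == 3L)
  ref <- table[table$peptide_id %in% top3, , drop = FALSE]
  sums <- vapply(split(ref$area, ref$sample_id), sum, 0, na.rm = TRUE)
  if (any(sums <= 0) || !all(unique(table$sample_id) %in% names(sums))) {
    stop("per-sample top-3 reference sum must be positive in every sample")
  }
  table$value <- table$area / sums[table$sample_id]
  attr(table, "reference_peptides") <- top3
  table
}

#' Condition fold-changes of normalized phosphopeptide abundances
#'
#' For each phosphopeptide, the fold change of every condition relative to
#' the control is the ratio of mean normalized abundances, and conditions
#' are compared by an all-pairs Tukey-Kramer test on the per-replicate
#' normalized values.
#'
#' @param normalized output of [normalize_peptides()].
#' @param control_condition label of the control condition.
#' @return list with `folds` (data.frame `peptide_id`, `condition`, `fold`,
#'   `flagged`) and `tests` (named list of [tukey_kramer()] results, one
#'   per phosphopeptide; `NULL` where group sizes are too small).
#' @export
condition_ratios <- function(normalized, control_condition) {
  stopifnot(is.data.frame(normalized), "value" %in% names(normalized),
            "condition" %in% names(normalized))
  if (!any(normalized$condition == control_condition)) {
    stop("control condition absent from the table")
  }
  phos <- normalized[normalized$is_phospho, , drop = FALSE]
  out <- list()
  tests <- list()
  for (pep in unique(phos$peptide_id)) {
    d <- phos[phos$peptide_id == pep, , drop = FALSE]
    ctrl <- d$value[d$condition == control_condition]
    if (length(ctrl) < 2L) {
      stop(sprintf("control condition needs >= 2 replicates (peptide %s)", pep))
    }
    m_ctrl <- mean(ctrl)
    conds <- setdiff(unique(d$condition), control_condition)
    fold <- vapply(conds, function(cc) {
      if (m_ctrl == 0) NA_real_ else
        mean(d$value[d$condition == cc]) / m_ctrl
    }, 0)
    out[[pep]] <- data.frame(peptide_id = pep, condition = conds,
                             fold = unname(fold),
                             flagged = m_ctrl == 0)
    groups <- split(d$value, d$condition)
    pooled_var <- sum(vapply(groups, function(v) {
      if (length(v) >= 2L) (length(v) - 1) * stats::var(v) else 0
    }, 0))
    tests[[pep]] <- if (all(lengths(groups) >= 2L) && pooled_var > 0) {
      tukey_kramer(groups)
    }
  }
  list(folds = do.call(rbind, c(out, list(make.row.names = FALSE))),
       tests = tests)
}

#' @noRd
check_peptide_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("peptide_id", "is_phospho", "sample_id", "area")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(table$peptide_id, table$sample_id)
  if (anyDuplicated(key)) {
    stop("duplicate (peptide_id, sample_id) rows in peptide table")
  }
  if (any(table$area < 0, na.rm = TRUE)) stop("negative peak areas")
  invisible(table)
}
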