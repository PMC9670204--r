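#' Parameters for the synthetic peptide peak-area table
#'
#' Emulates the shape of a data-independent-acquisition (SWATH) peak-area
#' export for one protein: a handful of phosphopeptides plus at least six
#' unmodified peptides, measured across conditions with technical
#' replicates.  Defaults mirror the study design: five phosphopeptides
#' (one carrying the functionally important T217 site; the remaining ids
#' are synthetic placeholders), three conditions (control, acrolein,
#' acrolein + Jak3 inhibitor) and three replicates, with a planted 3-fold
#' increase of the T217 phosphopeptide under acrolein that reverts with
#' the inhibitor.
#'
#' @param phosphopeptide_ids character ids of phosphopeptides.
#' @param unmodified_peptide_ids character ids of unmodified peptides
#'   (at least 6).
#' @param conditions condition labels; the first is the control.
#' @param n_replicates technical replicates per condition.
#' @param base_area_meanlog,base_area_sdlog lognormal distribution of
#'   per-peptide base peak areas (arbitrary units).
#' @param planted_fold_changes named list `peptide_id -> named numeric of
#'   per-condition folds`; missing entries default to 1 (a message notes
#'   each defaulted phosphopeptide/condition pair).
#' @param sample_scale_sdlog lognormal sigma of the per-sample loading /
#'   injection scale applied to every peptide of a sample.
#' @param noise_sdlog lognormal sigma of the per-measurement replicate
#'   noise.
#' @param seed integer seed.
#' @return An object of class `peptide_sim_params`.
#' @export
peptide_sim_params <- function(phosphopeptide_ids = c("phos_T217",
                                                      paste0("phos_", 2:5)),
                               unmodified_peptide_ids = paste0("unmod_", 1:6),
                               conditions = c("control", "acrolein",
                                              "acrolein_jak3i"),
                               n_replicates = 3L,
                               base_area_meanlog = log(1e6),
                               base_area_sdlog = 1,
                               planted_fold_changes = list(
                                 phos_T217 = c(acrolein = 3,
                                               acrolein_jak3i = 1)),
                               sample_scale_sdlog = 0.2,
                               noise_sdlog = 0.1,
                               seed = 1L) {
  stopifnot(length(phosphopeptide_ids) >= 1L,
            length(unmodified_peptide_ids) >= 6L,
            length(conditions) >= 2L, is_count(n_replicates),
            is_number(base_area_meanlog), is_number(base_area_sdlog),
            base_area_sdlog >= 0,
            is_number(sample_scale_sdlog), sample_scale_sdlog >= 0,
            is_number(noise_sdlog), noise_sdlog >= 0, is_count(seed, min = 0L))
  if (anyDuplicated(c(phosphopeptide_ids, unmodified_peptide_ids))) {
    stop("peptide ids must be unique")
  }
  folds <- unlist(planted_fold_changes)
  if (length(folds) && any(folds <= 0)) stop("fold changes must be > 0")
  structure(
    list(phosphopeptide_ids = phosphopeptide_ids,
         unmodified_peptide_ids = unmodified_peptide_ids,
         conditions = conditions, n_replicates = as.integer(n_replicates),
         base_area_meanlog = base_area_meanlog,
         base_area_sdlog = base_area_sdlog,
         planted_fold_changes = planted_fold_changes,
         sample_scale_sdlog = sample_scale_sdlog,
         noise_sdlog = noise_sdlog, seed = as.integer(seed)),
    class = "peptide_sim_params"
  )
}

#' Generate a long-format peptide peak-area table with planted folds
#'
#' `area(peptide, sample) = base_area(peptide) * fold(peptide, condition) *
#' sample_scale(sample) * lognormal noise`, with the sample scale applied
#' to every peptide of that sample (so top-3 normalization can cancel it
#' exactly).
#'
#' @param params a [peptide_sim_params()] object.
#' @return list with `table` (data.frame `peptide_id`, `is_phospho`,
#'   `phospho_site`, `sample_id`, `condition`, `area`) and `truth`
#'   (data.frame of planted per-peptide, per-condition folds, and the
#'   per-sample scales).
#' @export
generate_peptide_table <- function(params) {
  stopifnot(inherits(params, "peptide_sim_params"))
  peptides <- c(params$phosphopeptide_ids, params$unmodified_peptide_ids)
  is_phos <- peptides %in% params$phosphopeptide_ids
  samples <- expand.grid(condition = params$conditions,
                         replicate = seq_len(params$n_replicates),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_rep%d", samples$condition,
                               samples$replicate)

  base <- with_seed(derive_seed(params$seed, 0L, stream = 21L),
                    stats::rlnorm(length(peptides),
                                  params$base_area_meanlog,
                                  params$base_area_sdlog))
  names(base) <- peptides

  fold_of <- function(pep, cond) {
    f <- params$planted_fold_changes[[pep]]
    if (is.null(f) || is.na(f[cond] %||% NA)) return(NA_real_)
    unname(f[cond])
  }
  folds <- expand.grid(peptide_id = peptides, condition = params$conditions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  folds$fold <- mapply(fold_of, folds$peptide_id, folds$condition)
  defaulted <- is.na(folds$fold)
  # peptides absent from the map default silently; a *partial* entry
  # (some conditions stated, others not) is logged
  partial <- defaulted &
    folds$peptide_id %in% names(params$planted_fold_changes) &
    folds$condition != params$conditions[1L]
  if (any(partial)) {
    message("generate_peptide_table: missing fold-change entries default to 1 (",
            paste(unique(folds$peptide_id[partial]), collapse = ", "), ")")
  }
  folds$fold[defaulted] <- 1

  rows <- list()
  for (s in seq_len(nrow(samples))) {
    rows[[s]] <- with_seed(derive_seed(params$seed, s, stream = 22L), {
      scale_s <- stats::rlnorm(1L, 0, params$sample_scale_sdlog)
      noise <- stats::rlnorm(length(peptides), 0, params$noise_sdlog)
      f <- folds$fold[match(
        paste(peptides, samples$condition[s]),
        paste(folds$peptide_id, folds$condition))]
      data.frame(
        peptide_id = peptides,
        is_phospho = is_phos,
        phospho_site = ifelse(is_phos, sub("^phos_", "", peptides),
                              NA_character_),
        sample_id = samples$sample_id[s],
        condition = samples$condition[s],
        area = base[peptides] * f * scale_s * noise,
        scale = scale_s
      )
    })
  }
  tab <- do.call(rbind, rows)
  scales <- unique(tab[, c("sample_id", "scale")])
  tab$scale <- NULL
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(folds = folds, base_areas = base,
                    sample_scales = scales))
}
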