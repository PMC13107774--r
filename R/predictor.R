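#' Predict functional class for new genome assemblies
#'
#' Featurizes each genome with the bundle's vocabulary, restricts to the
#' bundle's selected k-mer columns, standardizes with the bundle's training
#' mean/SD, and scores with the frozen classifier. The call is `SFS` when
#' the SFS score reaches the decision threshold. Prediction is a pure
#' function of the bundle and the genome bytes. Genomes with less than
#' 10 kb of total sequence are still predicted but flagged, since the model
#' is meant for complete ~2 Mb assemblies; unparseable files yield an error
#' row rather than aborting the batch.
#'
#' @param object A `model_bundle`.
#' @param fasta Character vector of FASTA paths (possibly empty), or a list
#'   of `genome_record` objects.
#' @param threshold Decision threshold on the SFS score (default 0.5).
#' @param ... Unused.
#' @return Tibble with `strain_id`, `probability_SFS`, `call`,
#'   `bundle_version`, `warnings`.
#' @export
predict.model_bundle <- function(object, fasta, threshold = 0.5, ...) {
  bundle <- object
  if (length(fasta) == 0) {
    return(tibble::tibble(strain_id = character(), probability_SFS = double(),
                          call = character(), bundle_version = character(),
                          warnings = character()))
  }
  vocab <- kmer_vocabulary(bundle$k_values)
  if (!identical(vocab_descriptor(vocab), bundle$vocab_descriptor)) {
    stop("vocabulary descriptor mismatch; refusing to predict")
  }
  genomes <- if (is.character(fasta)) {
    lapply(fasta, function(p) tryCatch(read_genomes(p)[[1]],
                                       error = function(e) e))
  } else {
    fasta
  }
  spec <- classifier_registry(bundle$family)[[1]]
  rows <- lapply(genomes, function(g) {
    if (inherits(g, "error")) {
      return(tibble::tibble(strain_id = NA_character_,
                            probability_SFS = NA_real_, call = NA_character_,
                            bundle_version = bundle$format_version,
                            warnings = paste("skipped:",
                                             conditionMessage(g))))
    }
    warn <- ""
    total_bp <- sum(Biostrings::width(g$contigs))
    if (total_bp < 10000) {
      warn <- paste0("short assembly (", total_bp,
                     " bp): model expects complete genomes")
    }
    km <- build_feature_matrix(list(g), vocab, mode = bundle$matrix_mode)
    z <- design_matrix(km, bundle$selection)
    p <- as.numeric(spec$score(bundle$model, z))
    tibble::tibble(strain_id = g$strain_id, probability_SFS = p,
                   call = ifelse(p >= threshold, "SFS", "SubFS"),
                   bundle_version = bundle$format_version, warnings = warn)
  })
  dplyr::bind_rows(rows)
}

#' Summarize predicted calls per cohort group
#'
#' Counts and percentages of SFS/SubFS calls per group; with exactly two
#' groups, a two-sided Fisher exact test compares the SFS proportions.
#'
#' @param records Prediction tibble from [predict.model_bundle()] (rows with
#'   missing calls are dropped with a warning).
#' @param groups Optional group label per record (e.g. healthy / BV). With
#'   `NULL`, the whole cohort forms one group.
#' @return A `cohort_summary`: tibble with `group`, `n`, `n_sfs`, `pct_sfs`,
#'   `pct_subfs`; the Fisher p-value (two groups only) in attribute
#'   `"fisher_p"`.
#' @export
summarize_cohort <- function(records, groups = NULL) {
  stopifnot(nrow(records) >= 1)
  if (is.null(groups)) groups <- rep("all", nrow(records))
  stopifnot(length(groups) == nrow(records))
  keep <- !is.na(records$call)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " record(s) without a call")
    records <- records[keep, , drop = FALSE]
    groups <- groups[keep]
  }
  groups <- as.factor(groups)
  if (any(is.na(groups))) stop("unknown group label")
  out <- tibble::tibble(group = groups, call = records$call) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     n_sfs = sum(.data$call == "SFS"),
                     .groups = "drop") |>
    dplyr::mutate(pct_sfs = 100 * .data$n_sfs / .data$n,
                  pct_subfs = 100 - .data$pct_sfs)
  if (nlevels(groups) == 2) {
    tab <- rbind(out$n_sfs, out$n - out$n_sfs)
    attr(out, "fisher_p") <- stats::fisher.test(tab)$p.value
  }
  class(out) <- c("cohort_summary", class(out))
  out
}
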