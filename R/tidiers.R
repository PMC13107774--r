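#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a benchmark report into a long family-by-round tibble
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return Tibble with `family`, `round`, `auc`.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) {
  tibble::as_tibble(x$auc_rounds, rownames = "family") |>
    tidyr::pivot_longer(-"family", names_to = "round", values_to = "auc") |>
    dplyr::mutate(round = as.integer(sub("round", "", .data$round)),
                  family = factor(.data$family, levels = rownames(x$auc_rounds)))
}

#' One-row summary of a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return Tibble with `chosen`, `mean_auc`, `test_auc`, `n_families`,
#'   `rounds`.
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble::tibble(chosen = x$chosen,
                 mean_auc = unname(x$mean_auc[x$chosen]),
                 test_auc = x$test_auc,
                 n_families = nrow(x$auc_rounds),
                 rounds = x$rounds)
}

#' Tidy a feature-selection result
#'
#' @param x A `selected_features` object.
#' @param ... Unused.
#' @return Per-feature tibble of the fusion-stage survivors (`index`,
#'   `s_bar`, `cluster`, `selected`, and `kmer` when a vocabulary was
#'   attached).
#' @method tidy selected_features
#' @export
tidy.selected_features <- function(x, ...) {
  x$scores
}

#' One-row summary of a feature-selection result
#'
#' @param x A `selected_features` object.
#' @param ... Unused.
#' @return Tibble of per-stage survivor counts.
#' @method glance selected_features
#' @export
glance.selected_features <- function(x, ...) {
  tibble::as_tibble(as.list(x$stage_counts))
}
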