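#' Trait block configuration for the composite functional score
#'
#' Five phenotype blocks contribute to the composite score with fixed
#' weights summing to 1: growth capacity (max specific growth rate, default
#' 0.1), acidification (culture supernatant pH, 0.2), lactic acid production
#' (0.2), hydrogen peroxide production (0.2) and antagonistic activity
#' against BV-associated pathogens (0.3). All traits are higher-is-better
#' except pH, whose min-max score is inverted so stronger acidification
#' (lower pH) scores higher.
#'
#' @param weights Named numeric vector with entries `growth`,
#'   `acidification`, `lactic`, `h2o2`, `antagonism`; must sum to 1.
#' @param normalization `"minmax"` (default) scales each raw trait to
#'   \[0, 1\] across strains; `"zscore"` standardizes instead (the composite
#'   is then not bounded in \[0, 1\]).
#' @return A `trait_config` object.
#' @export
trait_config <- function(weights = c(growth = 0.1, acidification = 0.2,
                                     lactic = 0.2, h2o2 = 0.2,
                                     antagonism = 0.3),
                         normalization = c("minmax", "zscore")) {
  normalization <- match.arg(normalization)
  blocks <- c("growth", "acidification", "lactic", "h2o2", "antagonism")
  stopifnot(setequal(names(weights), blocks))
  weights <- weights[blocks]
  if (any(weights < 0) || any(weights > 1)) stop("weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("block weights must sum to 1, got ", sum(weights))
  }
  structure(list(weights = weights, normalization = normalization),
            class = "trait_config")
}

# canonical phenotype column layout: five scalar traits + 8 inhibition zones
pheno_trait_cols <- function() {
  c("mu_max", "cfs_ph", "lactic_gL", "h2o2_cfs", "h2o2_pellet",
    "zone_gv_cfs", "zone_se_cfs", "zone_fv_cfs", "zone_pb_cfs",
    "zone_gv_pellet", "zone_se_pellet", "zone_fv_pellet", "zone_pb_pellet")
}

#' Read a per-strain phenotype table
#'
#' Expects a TSV with header `strain_id`, `mu_max` (1/h), `cfs_ph` (pH
#' units), `lactic_gL` (g/L), `h2o2_cfs` (umol/L), `h2o2_pellet` (umol/g)
#' and eight inhibition-zone diameters in mm
#' (`zone_{gv,se,fv,pb}_{cfs,pellet}`; 0 means no inhibition). Missing
#' values are allowed.
#'
#' @param path TSV file path.
#' @return Tibble with one row per strain.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  validate_phenotypes(tbl)
}

#' Validate a phenotype table
#'
#' @param tbl Data frame with the columns documented in [read_phenotypes()].
#' @return The validated tibble.
#' @export
validate_phenotypes <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("strain_id", pheno_trait_cols())
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tbl$strain_id)) stop("duplicate strain_id in phenotype table")
  vals <- as.matrix(tbl[pheno_trait_cols()])
  if (any(vals < 0, na.rm = TRUE)) stop("phenotype values must be >= 0")
  ph <- tbl$cfs_ph
  if (any(ph <= 0 | ph >= 14, na.rm = TRUE)) stop("cfs_ph must lie in (0, 14)")
  tbl
}

#' @noRd
minmax01 <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("trait has no non-missing values")
  if (rng[1] == rng[2]) {
    warning("constant trait mapped to 0.5")
    return(ifelse(is.na(x), NA_real_, 0.5))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Normalize raw phenotype traits across strains
#'
#' Each raw trait is min-max scaled to \[0, 1\] across strains (or z-scored
#' under the `"zscore"` config); the pH score is inverted (`1 - minmax(pH)`)
#' so stronger acidification scores higher. A trait constant across strains
#' maps to 0.5 with a warning.
#'
#' @param tbl Phenotype table (see [read_phenotypes()]).
#' @param config A [trait_config()].
#' @return Tibble of `strain_id` plus normalized trait columns.
#' @export
normalize_traits <- function(tbl, config = trait_config()) {
  tbl <- validate_phenotypes(tbl)
  if (nrow(tbl) < 2) stop("need at least 2 strains")
  cols <- pheno_trait_cols()
  scale_one <- function(x) {
    if (config$normalization == "minmax") minmax01(x)
    else as.numeric(scale(x))
  }
  out <- tibble::tibble(strain_id = tbl$strain_id)
  for (cl in cols) {
    v <- scale_one(tbl[[cl]])
    if (cl == "cfs_ph" && config$normalization == "minmax") v <- 1 - v
    if (cl == "cfs_ph" && config$normalization == "zscore") v <- -v
    out[[cl]] <- v
  }
  out
}

#' Compute the weighted composite functional score
#'
#' Block scores are: growth = normalized mu_max; acidification = inverted
#' normalized pH; lactic = normalized lactic acid; h2o2 = mean of the two
#' normalized hydrogen-peroxide measures (supernatant and pellet);
#' antagonism = mean of the eight normalized inhibition-zone diameters.
#' The composite is the weighted sum of block scores and lies in \[0, 1\]
#' under min-max normalization. A missing sub-measure is excluded from its
#' block mean; a strain with a fully missing block is dropped with a warning.
#'
#' @param normalized Output of [normalize_traits()].
#' @param config A [trait_config()].
#' @return Tibble with `strain_id`, the five block scores and `composite`.
#' @export
composite_score <- function(normalized, config = trait_config()) {
  w <- config$weights
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  block_mean <- function(cols) {
    m <- as.matrix(normalized[cols])
    rowMeans(m, na.rm = TRUE)
  }
  out <- tibble::tibble(
    strain_id = normalized$strain_id,
    growth = block_mean("mu_max"),
    acidification = block_mean("cfs_ph"),
    lactic = block_mean("lactic_gL"),
    h2o2 = block_mean(c("h2o2_cfs", "h2o2_pellet")),
    antagonism = block_mean(grep("^zone_", names(normalized), value = TRUE))
  )
  bad <- !stats::complete.cases(out[c("growth", "acidification", "lactic",
                                      "h2o2", "antagonism")])
  if (any(bad)) {
    warning("excluding strain(s) with a fully missing block: ",
            paste(out$strain_id[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  out$composite <- as.numeric(
    as.matrix(out[c("growth", "acidification", "lactic", "h2o2",
                    "antagonism")]) %*% w
  )
  out
}

#' Assign superior/suboptimal functional labels by median split
#'
#' The median composite score is the cutoff: strains with composite >= median
#' are labelled `SFS` (superior functional strain), the rest `SubFS`. With n
#' distinct scores this puts ceiling(n/2) strains in the SFS class. Ties at
#' the median all go to SFS (documented convention) with a warning.
#'
#' @param scores Output of [composite_score()].
#' @return The input tibble with a `label` factor column (levels
#'   `SubFS`, `SFS`) and the cutoff in attribute `"cutoff"`.
#' @export
assign_labels <- function(scores) {
  stopifnot("composite" %in% names(scores))
  if (nrow(scores) < 2) stop("need at least 2 strains")
  s <- scores$composite
  if (length(unique(s)) == 1) {
    stop("no discriminating phenotype signal: all composite scores identical")
  }
  cutoff <- stats::median(s)
  if (sum(s == cutoff) > 1) {
    warning("composite-score ties at the median cutoff; all assigned SFS")
  }
  scores$label <- factor(ifelse(s >= cutoff, "SFS", "SubFS"),
                         levels = c("SubFS", "SFS"))
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Score phenotypes end to end
#'
#' Convenience wrapper: [normalize_traits()] then [composite_score()] then
#' [assign_labels()].
#'
#' @inheritParams normalize_traits
#' @return Labelled composite-score tibble (see [assign_labels()]).
#' @export
score_phenotypes <- function(tbl, config = trait_config()) {
  assign_labels(composite_score(normalize_traits(tbl, config), config))
}

#' Compare trait distributions between label groups
#'
#' Two-sided Mann-Whitney U tests per raw trait between the SFS and SubFS
#' groups. `stats::wilcox.test` uses the exact null distribution for small
#' untied samples and the normal approximation (with continuity correction)
#' otherwise.
#'
#' @param tbl Phenotype table.
#' @param labels Factor/character of group labels aligned with `tbl` rows,
#'   or a labelled score tibble from [score_phenotypes()].
#' @return Tibble with one row per trait: `trait`, group medians, `p_value`.
#' @export
compare_groups <- function(tbl, labels) {
  tbl <- validate_phenotypes(tbl)
  if (is.data.frame(labels)) {
    labels <- labels$label[match(tbl$strain_id, labels$strain_id)]
  }
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("need exactly 2 non-empty groups")
  g <- droplevels(labels)
  purrr::map_dfr(pheno_trait_cols(), function(cl) {
    x <- tbl[[cl]][g == levels(g)[1]]
    y <- tbl[[cl]][g == levels(g)[2]]
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    tibble::tibble(
      trait = cl,
      median_1 = stats::median(x, na.rm = TRUE),
      median_2 = stats::median(y, na.rm = TRUE),
      p_value = p
    )
  }) |>
    dplyr::rename_with(~ sub("_1$", paste0("_", levels(g)[1]), .x)) |>
    dplyr::rename_with(~ sub("_2$", paste0("_", levels(g)[2]), .x))
}
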