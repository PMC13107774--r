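#' Train the deployable model bundle on all labelled strains
#'
#' Refits the whole stack — feature selection, z-score standardization and
#' the chosen classifier family — on the full labelled cohort and freezes
#' everything prediction needs into one self-contained bundle: the k-mer
#' vocabulary descriptor, the selected feature indices, the per-feature
#' mean/SD, the fitted classifier, and the selection configuration.
#'
#' @param kmat A `kmer_matrix` of all labelled strains.
#' @param labels Class labels (`SFS`/`SubFS`) aligned with the strains.
#' @param family Classifier family id (typically `benchmark_report$chosen`).
#' @param config A [selection_config()].
#' @param seed Seed for the final classifier fit.
#' @return A `model_bundle`.
#' @export
fit_final <- function(kmat, labels, family, config = selection_config(),
                      seed = 1L) {
  stopifnot(inherits(kmat, "kmer_matrix"))
  if (is.data.frame(labels)) {
    labels <- labels$label[match(kmat$strain_ids, labels$strain_id)]
  }
  labels <- droplevels(as.factor(labels))
  stopifnot(length(labels) == length(kmat$strain_ids), !anyNA(labels))
  sel <- run_selection(kmat, labels, config)
  z <- design_matrix(kmat, sel)
  spec <- classifier_registry(family)[[1]]
  model <- spec$fit(z, labels, seed = seed)
  structure(
    list(format_version = "1.0",
         vocab_descriptor = vocab_descriptor(kmat$vocabulary),
         k_values = kmat$vocabulary$k_values,
         matrix_mode = kmat$mode,
         selection = sel,
         family = family,
         model = model,
         config = config,
         seed = as.integer(seed),
         training_fingerprint = paste(sort(kmat$strain_ids), collapse = ",")),
    class = "model_bundle"
  )
}

# compact vocabulary identity: k orders plus total dimension; any mismatch
# means feature indices in the bundle would be meaningless
#' @noRd
vocab_descriptor <- function(vocab) {
  paste0("k=", paste(vocab$k_values, collapse = ","), ";dim=", vocab$size)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle v", x$format_version, "> family=", x$family,
      ", ", length(x$selection$indices), " features, vocab ",
      x$vocab_descriptor, "\n", sep = "")
  invisible(x)
}

#' Save / load a model bundle
#'
#' Bundles are serialized as versioned RDS files; [read_bundle()] refuses
#' files whose format version it does not know.
#'
#' @param bundle A `model_bundle`.
#' @param path File path.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` returns
#'   the bundle.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "model_bundle")) stop("not a model bundle: ", path)
  if (!identical(bundle$format_version, "1.0")) {
    stop("unsupported bundle format version: ", bundle$format_version)
  }
  bundle
}
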