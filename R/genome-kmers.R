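#' Read genome assemblies from FASTA files
#'
#' Reads one genome assembly per FASTA file (plain or gzip) into a list of
#' genome records. The strain identifier is the file stem (file name without
#' directory or `.fa`/`.fasta`/`.fna`/`.gz` extensions) unless a manifest
#' overrides it. Sequences are upper-cased on ingest; IUPAC ambiguity codes
#' are retained and handled downstream by the sliding-window counter.
#'
#' @param paths Character vector of FASTA file paths, one genome per file.
#' @param manifest Optional data frame with columns `path` and `strain_id`
#'   mapping files to strain identifiers.
#' @return A named list of `genome_record` objects, each with `strain_id`
#'   and `contigs` (a [Biostrings::DNAStringSet]).
#' @export
read_genomes <- function(paths, manifest = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("unreadable FASTA file(s): ", paste(missing, collapse = ", "))
  }
  ids <- fasta_stem(paths)
  if (!is.null(manifest)) {
    stopifnot(all(c("path", "strain_id") %in% names(manifest)))
    hit <- match(basename(paths), basename(manifest$path))
    ids[!is.na(hit)] <- manifest$strain_id[hit[!is.na(hit)]]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate strain_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs <- lapply(seq_along(paths), function(i) {
    contigs <- Biostrings::readDNAStringSet(paths[i])
    if (length(contigs) == 0) {
      stop("empty FASTA: ", paths[i])
    }
    if (any(Biostrings::width(contigs) == 0)) {
      stop("empty contig in ", paths[i])
    }
    genome_record(ids[i], contigs)
  })
  stats::setNames(recs, ids)
}

#' @noRd
fasta_stem <- function(paths) {
  sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(paths), ignore.case = TRUE)
}

#' Construct a genome record
#'
#' @param strain_id Non-empty strain identifier.
#' @param contigs Character vector or [Biostrings::DNAStringSet] of contig
#'   sequences.
#' @return A `genome_record` object.
#' @export
genome_record <- function(strain_id, contigs) {
  stopifnot(is.character(strain_id), length(strain_id) == 1, nzchar(strain_id))
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(toupper(contigs))
  }
  stopifnot(methods::is(contigs, "DNAStringSet"), length(contigs) >= 1,
            all(Biostrings::width(contigs) > 0))
  structure(list(strain_id = strain_id, contigs = contigs),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$strain_id, ": ", length(x$contigs),
      " contig(s), ", sum(Biostrings::width(x$contigs)), " bp\n", sep = "")
  invisible(x)
}

#' Build a multi-order k-mer vocabulary
#'
#' The vocabulary concatenates all DNA words of each order k, ordered by
#' ascending k and then lexicographically with A < C < G < T, so that column
#' indices are portable across runs and serialized model bundles. For the
#' default orders 5--9 the total dimension is
#' 4^5 + 4^6 + 4^7 + 4^8 + 4^9 = 349,184.
#'
#' @param k_values Strictly increasing positive integers (default `5:9`).
#' @return A `kmer_vocabulary` with `k_values`, per-order sizes and offsets,
#'   and total `size`.
#' @export
kmer_vocabulary <- function(k_values = 5:9) {
  k_values <- as.integer(k_values)
  if (length(k_values) == 0) stop("k_values must be non-empty")
  if (any(k_values < 1) || any(diff(k_values) <= 0)) {
    stop("k_values must be strictly increasing positive integers")
  }
  sizes <- as.integer(4^k_values)
  offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
  structure(
    list(k_values = k_values, sizes = sizes, offsets = as.integer(offsets),
         size = as.integer(sum(sizes))),
    class = "kmer_vocabulary"
  )
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat("<kmer_vocabulary> k = {", paste(x$k_values, collapse = ","),
      "}, ", format(x$size, big.mark = ","), " columns\n", sep = "")
  invisible(x)
}

#' Column index of a k-mer in a vocabulary
#'
#' Computes the 1-based column index in O(k) by base-4 positional arithmetic
#' (A=0, C=1, G=2, T=3) plus the order offset.
#'
#' @param vocab A [kmer_vocabulary()].
#' @param kmers Character vector of DNA words whose lengths are in
#'   `vocab$k_values`.
#' @return Integer vector of column indices.
#' @export
kmer_index <- function(vocab, kmers) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  vapply(kmers, function(km) {
    k <- nchar(km)
    ki <- match(k, vocab$k_values)
    if (is.na(ki)) stop("k-mer length ", k, " not in vocabulary")
    digits <- match(strsplit(km, "", fixed = TRUE)[[1]],
                    c("A", "C", "G", "T")) - 1L
    if (anyNA(digits)) stop("k-mer contains non-ACGT symbol: ", km)
    as.integer(vocab$offsets[ki] + sum(digits * 4^((k - 1):0)) + 1)
  }, integer(1), USE.NAMES = FALSE)
}

#' k-mer string at a vocabulary column index
#'
#' Inverse of [kmer_index()].
#'
#' @inheritParams kmer_index
#' @param index Integer vector of 1-based column indices.
#' @return Character vector of k-mer strings.
#' @export
kmer_at <- function(vocab, index) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  bases <- c("A", "C", "G", "T")
  vapply(index, function(j) {
    stopifnot(j >= 1, j <= vocab$size)
    ki <- findInterval(j - 1L, c(vocab$offsets, vocab$size))
    k <- vocab$k_values[ki]
    r <- j - 1L - vocab$offsets[ki]
    out <- character(k)
    for (p in k:1) {
      out[p] <- bases[r %% 4 + 1]
      r <- r %/% 4
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Count k-mers in a genome with a sliding window
#'
#' Every contig of length L contributes max(0, L - k + 1) windows; windows
#' containing any non-ACGT symbol are skipped and excluded from the valid
#' window total; windows never span contig boundaries. Counting is delegated
#' to [Biostrings::oligonucleotideFrequency()], whose word order matches the
#' vocabulary's lexicographic A < C < G < T convention.
#'
#' @param genome A `genome_record`.
#' @param k Single positive integer word length.
#' @return List with `counts` (integer vector of length 4^k, named by k-mer)
#'   and `valid_windows` (number of fully unambiguous windows).
#' @export
count_kmers <- function(genome, k) {
  stopifnot(inherits(genome, "genome_record"), k >= 1)
  freq <- Biostrings::oligonucleotideFrequency(genome$contigs, width = k,
                                               step = 1)
  counts <- if (is.matrix(freq)) colSums(freq) else freq
  counts <- stats::setNames(as.integer(counts), colnames(freq) %||% names(freq))
  list(counts = counts, valid_windows = sum(counts))
}

#' Build the concatenated multi-order k-mer feature matrix
#'
#' Row i holds strain i's concatenated per-order feature blocks in vocabulary
#' column order. In `"frequency"` mode (default) each count is divided by the
#' strain's valid window total for that order, so each order block sums to 1
#' when at least one unambiguous window exists; `"count"` mode keeps raw
#' counts. A strain with zero valid windows at some order gets an all-zero
#' block for that order, with a warning.
#'
#' @param genomes List of `genome_record` objects (as from [read_genomes()]).
#' @param vocab A [kmer_vocabulary()].
#' @param mode `"frequency"` (per-order relative frequency) or `"count"`.
#' @return A `kmer_matrix`: sparse strains-by-vocabulary matrix plus
#'   `strain_ids`, per-order `window_totals`, the vocabulary and the mode.
#' @export
build_feature_matrix <- function(genomes, vocab = kmer_vocabulary(),
                                 mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1, inherits(vocab, "kmer_vocabulary"))
  ids <- vapply(genomes, function(g) g$strain_id, character(1))
  nk <- length(vocab$k_values)
  window_totals <- matrix(0L, length(genomes), nk,
                          dimnames = list(ids, paste0("k", vocab$k_values)))
  rows <- vector("list", length(genomes))
  for (i in seq_along(genomes)) {
    blocks <- vector("list", nk)
    for (ki in seq_len(nk)) {
      k <- vocab$k_values[ki]
      cnt <- count_kmers(genomes[[i]], k)
      window_totals[i, ki] <- cnt$valid_windows
      v <- as.numeric(cnt$counts)
      if (mode == "frequency") {
        if (cnt$valid_windows > 0) {
          v <- v / cnt$valid_windows
        } else {
          warning("strain ", ids[i], " has zero valid ", k,
                  "-mer windows; block left all-zero")
        }
      }
      blocks[[ki]] <- v
    }
    rows[[i]] <- Matrix::Matrix(matrix(unlist(blocks), nrow = 1),
                                sparse = TRUE)
  }
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  structure(
    list(strain_ids = ids, values = values, window_totals = window_totals,
         vocabulary = vocab, mode = mode),
    class = "kmer_matrix"
  )
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("<kmer_matrix> ", length(x$strain_ids), " strains x ",
      format(ncol(x$values), big.mark = ","), " k-mer columns (",
      x$mode, " mode)\n", sep = "")
  invisible(x)
}

#' @export
dim.kmer_matrix <- function(x) dim(x$values)

#' Fit z-score standardization parameters on training strains
#'
#' Per-column mean and population (divide-by-n) standard deviation over the
#' given training rows only, so that held-out strains are later scaled with
#' training statistics and never their own.
#'
#' @param x A `kmer_matrix` or numeric matrix.
#' @param rows Training strain ids (character) or row indices; default all.
#' @return A `std_params` object with `mu`, `sigma` and `fitted_on`.
#' @export
fit_standardization <- function(x, rows = NULL) {
  m <- as_values(x)
  idx <- resolve_rows(m, rows)
  if (length(idx) < 2) stop("need at least 2 training rows")
  sub <- m[idx, , drop = FALSE]
  n <- nrow(sub)
  mu <- Matrix::colMeans(sub)
  ex2 <- Matrix::colMeans(sub^2)
  sigma <- sqrt(pmax(ex2 - mu^2, 0))
  structure(
    list(mu = as.numeric(mu), sigma = as.numeric(sigma),
         fitted_on = rownames(m)[idx] %||% idx, n_cols = ncol(m)),
    class = "std_params"
  )
}

#' Apply fitted z-score standardization
#'
#' Columns with zero training standard deviation map to 0 for all rows (a
#' documented convention; such columns carry no information and are removed
#' by the variance filter in the selection pipeline anyway).
#'
#' @param x A `kmer_matrix` or numeric matrix with the same columns the
#'   parameters were fitted on.
#' @param params A `std_params` from [fit_standardization()].
#' @return Dense numeric matrix of z-scores.
#' @export
apply_standardization <- function(x, params) {
  stopifnot(inherits(params, "std_params"))
  m <- as_values(x)
  if (ncol(m) != params$n_cols) {
    stop("column mismatch: matrix has ", ncol(m), " columns, parameters ",
         "were fitted on ", params$n_cols)
  }
  m <- as.matrix(m)
  denom <- ifelse(params$sigma > 0, params$sigma, 1)
  z <- sweep(sweep(m, 2, params$mu, "-"), 2, denom, "/")
  z[, params$sigma == 0] <- 0
  z
}

#' @noRd
as_values <- function(x) {
  if (inherits(x, "kmer_matrix")) x$values else x
}

#' @noRd
resolve_rows <- function(m, rows) {
  if (is.null(rows)) return(seq_len(nrow(m)))
  if (is.character(rows)) {
    idx <- match(rows, rownames(m))
    if (anyNA(idx)) stop("unknown strain id(s): ",
                         paste(rows[is.na(idx)], collapse = ", "))
    idx
  } else {
    as.integer(rows)
  }
}

#' Export a k-mer matrix subset as a tibble
#'
#' @param x A `kmer_matrix`.
#' @param columns Vocabulary column indices to export (all columns of a
#'   full 5--9 matrix would be unwieldy).
#' @return Tibble with `strain_id` plus one named column per k-mer.
#' @export
kmer_tibble <- function(x, columns) {
  stopifnot(inherits(x, "kmer_matrix"))
  sub <- as.matrix(x$values[, columns, drop = FALSE])
  colnames(sub) <- kmer_at(x$vocabulary, columns)
  dplyr::bind_cols(tibble::tibble(strain_id = x$strain_ids),
                   tibble::as_tibble(sub))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
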