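# Independent brute-force oracles used to check the implementation paths.
# Each oracle deliberately avoids the code path it verifies.

# sliding-window k-mer counts by naive substring enumeration
naive_count_kmers <- function(contigs, k) {
  counts <- new.env(parent = emptyenv())
  valid <- 0L
  for (s in contigs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      valid <- valid + 1L
      cur <- if (is.null(counts[[w]])) 0L else counts[[w]]
      counts[[w]] <- cur + 1L
    }
  }
  list(counts = mget(ls(counts), envir = counts), valid = valid)
}

# AUC by exhaustive pair enumeration
naive_auc <- function(scores, labels, positive = "SFS") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# average-linkage agglomeration by explicit O(m^3) recomputation of all
# pairwise cluster linkages, merging while the minimum linkage <= cut
naive_average_linkage <- function(D, cut) {
  m <- nrow(D)
  clusters <- as.list(seq_len(m))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    if (best_d > cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assignment <- integer(m)
  for (ci in seq_along(clusters)) assignment[clusters[[ci]]] <- ci
  assignment
}

# canonical form of a partition so two labelings can be compared
canonical_partition <- function(assignment) {
  match(assignment, unique(assignment))
}

# one-way ANOVA F per column through R's linear-model machinery
lm_anova_f <- function(m, labels) {
  g <- as.factor(labels)
  apply(m, 2, function(col) {
    stats::anova(stats::lm(col ~ g))[1, "F value"]
  })
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
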