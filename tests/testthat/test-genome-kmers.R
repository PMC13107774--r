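test_that("FASTA ingest produces one upper-cased record per file", {
  p1 <- write_fasta("acgt", names = "c1")
  g <- read_genomes(p1)[[1]]
  expect_s3_class(g, "genome_record")
  expect_equal(as.character(g$contigs[[1]]), "ACGT")

  p2 <- write_fasta(c("ACGTAC", "GGTT"))
  expect_length(read_genomes(p2)[[1]]$contigs, 2)

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_genomes(empty), "empty FASTA")
  expect_error(read_genomes("/nonexistent/x.fasta"), "unreadable")

  dup <- c(write_fasta("ACGT", file.path(tempdir(), "same.fasta")),
           file.path(tempdir(), "same.fasta"))
  expect_error(read_genomes(dup), "duplicate strain_id")
})

test_that("manifest overrides the file-stem strain id", {
  p <- write_fasta("ACGTACGT")
  man <- data.frame(path = basename(p), strain_id = "custom_id")
  expect_named(read_genomes(p, manifest = man), "custom_id")
})

test_that("vocabulary dimension and ordering follow ascending k, A<C<G<T", {
  expect_equal(kmer_vocabulary(5:9)$size, 349184L)
  v1 <- kmer_vocabulary(1)
  expect_equal(v1$size, 4L)
  expect_equal(kmer_at(v1, 1:4), c("A", "C", "G", "T"))
  expect_equal(kmer_vocabulary(c(2, 3))$size, 80L)
  expect_error(kmer_vocabulary(integer(0)), "non-empty")
  expect_error(kmer_vocabulary(c(3, 2)), "strictly increasing")
})

test_that("kmer_index and kmer_at are inverse bijections", {
  v <- kmer_vocabulary(c(2, 4))
  set.seed(42)
  idx <- sample(v$size, 40)
  expect_equal(kmer_index(v, kmer_at(v, idx)), idx)
  expect_equal(kmer_index(v, "AA"), 1L)
  expect_equal(kmer_index(v, "TT"), 16L)
  expect_equal(kmer_index(v, "AAAA"), 17L)
  expect_error(kmer_index(v, "ACN"), "not in vocabulary")
  expect_error(kmer_index(v, "ACNT"), "non-ACGT")
})

test_that("sliding-window counts match enumerated windows and skip rules", {
  g <- genome_record("s1", "ACGTACGTA")
  res <- count_kmers(g, 5)
  expect_equal(res$valid_windows, 5L)
  expect_equal(res$counts[["ACGTA"]], 2L)
  expect_equal(res$counts[["CGTAC"]], 1L)
  expect_equal(sum(res$counts), 5L)

  expect_equal(count_kmers(genome_record("s2", "AAAAA"), 5)$counts[["AAAAA"]],
               1L)
  # all 4 windows of ACGNACGT contain the N and are skipped
  amb <- count_kmers(genome_record("s3", "ACGNACGT"), 5)
  expect_equal(amb$valid_windows, 0L)
  expect_true(all(amb$counts == 0))
})

test_that("counts agree with the naive substring-enumeration oracle", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(10:2000, 1)
    k <- sample(5:9, 1)
    s <- random_dna(L, alphabet = c("A", "C", "G", "T",
                                    if (rep %% 4 == 0) "N"))
    got <- count_kmers(genome_record("x", s), k)
    want <- naive_count_kmers(s, k)
    expect_equal(got$valid_windows, want$valid)
    nz <- got$counts[got$counts > 0]
    expect_equal(as.list(nz[order(names(nz))]),
                 want$counts[order(names(want$counts))])
    if (!grepl("N", s) && L >= k) {
      expect_equal(got$valid_windows, L - k + 1L)
    }
  }
})

test_that("feature matrix holds per-order relative frequencies", {
  v5 <- kmer_vocabulary(5)
  km <- build_feature_matrix(genome_record("a", "AAAAA"), v5)
  row <- as.numeric(km$values[1, ])
  expect_equal(row[kmer_index(v5, "AAAAA")], 1.0)
  expect_equal(sum(row), 1.0)

  co <- tiny_cohort()
  expect_equal(ncol(co$kmat$values), 349184)
  # every per-order block of frequencies sums to 1
  v <- co$kmat$vocabulary
  for (ki in seq_along(v$k_values)) {
    cols <- (v$offsets[ki] + 1):(v$offsets[ki] + v$sizes[ki])
    sums <- Matrix::rowSums(co$kmat$values[, cols])
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  expect_true(all(co$kmat$values >= 0))
})

test_that("matrix is equivariant in genome order, invariant to contig order", {
  v <- kmer_vocabulary(c(3, 4))
  g1 <- genome_record("g1", c("ACGTACGTGG", "TTTACGGA"))
  g1r <- genome_record("g1", c("TTTACGGA", "ACGTACGTGG"))
  g2 <- genome_record("g2", "GGGTTTACACAC")
  m12 <- build_feature_matrix(list(g1, g2), v)
  m21 <- build_feature_matrix(list(g2, g1), v)
  expect_equal(as.numeric(m12$values["g1", ]), as.numeric(m21$values["g1", ]))
  expect_equal(as.numeric(m12$values["g2", ]), as.numeric(m21$values["g2", ]))
  mr <- build_feature_matrix(list(g1r, g2), v)
  expect_equal(as.numeric(mr$values["g1", ]), as.numeric(m12$values["g1", ]))
  # identical duplicate genomes give identical rows
  md <- build_feature_matrix(list(g1, genome_record("copy", g1$contigs)), v)
  expect_equal(as.numeric(md$values[1, ]), as.numeric(md$values[2, ]))
})

test_that("an order with zero valid windows yields an all-zero block", {
  v <- kmer_vocabulary(c(2, 5))
  expect_warning(km <- build_feature_matrix(genome_record("tiny", "ACG"), v),
                 "zero valid 5-mer windows")
  row <- as.numeric(km$values[1, ])
  expect_equal(sum(row[1:16]), 1)      # 2-mer block normal
  expect_equal(sum(row[17:length(row)]), 0)
})

test_that("standardization uses training-only population statistics", {
  m <- matrix(c(0, 2, 5, 5), 2, 2, dimnames = list(c("a", "b"), NULL))
  par <- fit_standardization(m)
  expect_equal(par$mu, c(1, 5))
  expect_equal(par$sigma, c(1, 0))
  z <- apply_standardization(m, par)
  expect_equal(z[, 1], c(a = -1, b = 1))
  expect_equal(z[, 2], c(a = 0, b = 0))   # sigma = 0 convention

  set.seed(3)
  r <- matrix(rnorm(15), 5, 3)
  pr <- fit_standardization(r)
  for (j in 1:3) {
    expect_equal(pr$mu[j], sum(r[, j]) / 5)
    expect_equal(pr$sigma[j], sqrt(sum((r[, j] - pr$mu[j])^2) / 5))
  }
  zr <- apply_standardization(r, pr)
  expect_true(all(abs(colMeans(zr)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(zr^2) - colMeans(zr)^2) - 1) < 1e-9))

  # a held-out row is scaled with the training mu/sigma, not its own
  held <- matrix(c(10, 7, -2), 1, 3)
  zh <- apply_standardization(held, pr)
  expect_equal(as.numeric(zh), (as.numeric(held) - pr$mu) / pr$sigma)

  expect_error(fit_standardization(r[1, , drop = FALSE]), "at least 2")
  expect_error(apply_standardization(r[, 1:2], pr), "column mismatch")
})
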