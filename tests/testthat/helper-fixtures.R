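# Shared small simulated cohort, built once per test run. Desk-scale easy
# profile: 6 strains per class, 12 kb genomes, strong planted contrast.
.fixture_cache <- new.env(parent = emptyenv())

tiny_cohort <- function() {
  if (is.null(.fixture_cache$tiny)) {
    dir <- file.path(tempdir(), "lactoscreen-tiny")
    fx <- make_fixture("easy", dir, n_per_class = 6, genome_length = 12000,
                       seed = 11)
    genomes <- read_genomes(fx$fasta)
    kmat <- build_feature_matrix(genomes, kmer_vocabulary(5:9))
    scores <- score_phenotypes(fx$phenotypes)
    .fixture_cache$tiny <- list(fx = fx, genomes = genomes, kmat = kmat,
                                scores = scores)
  }
  .fixture_cache$tiny
}

# write a one-off FASTA file and return its path
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                        names = paste0("contig", seq_along(seqs))) {
  writeLines(paste0(">", names, "\n", seqs), path)
  path
}

# minimal valid phenotype tibble from a named list of per-trait vectors
pheno_table <- function(n, overrides = list()) {
  base <- list(
    mu_max = seq(0.05, 0.15, length.out = n),
    cfs_ph = seq(3.9, 4.3, length.out = n),
    lactic_gL = seq(3, 9, length.out = n),
    h2o2_cfs = seq(10, 17, length.out = n),
    h2o2_pellet = seq(2.5, 5.5, length.out = n)
  )
  for (z in c("zone_gv_cfs", "zone_se_cfs", "zone_fv_cfs", "zone_pb_cfs",
              "zone_gv_pellet", "zone_se_pellet", "zone_fv_pellet",
              "zone_pb_pellet")) {
    base[[z]] <- seq(5, 20, length.out = n)
  }
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  tibble::as_tibble(c(list(strain_id = sprintf("s%02d", seq_len(n))), base))
}

# normalized-trait tibble where every sub-trait of every block is `value`
uniform_normalized <- function(value, n = 1) {
  cols <- c("mu_max", "cfs_ph", "lactic_gL", "h2o2_cfs", "h2o2_pellet",
            "zone_gv_cfs", "zone_se_cfs", "zone_fv_cfs", "zone_pb_cfs",
            "zone_gv_pellet", "zone_se_pellet", "zone_fv_pellet",
            "zone_pb_pellet")
  out <- tibble::tibble(strain_id = sprintf("s%02d", seq_len(n)))
  for (cl in cols) out[[cl]] <- rep(value, n)
  out
}
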