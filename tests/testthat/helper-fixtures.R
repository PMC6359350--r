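# Shared fixtures: everything is generated in code, no binary files.

# a small, diverse protein used across modules (sequence fixed, not random)
fixture_protein <- function(id = "wt") {
  make_toy_protein("AHKDSWFTGV", chain_id = "A", id = id)
}

# protein + ligand placed near the middle residues
fixture_complex <- function() {
  p <- fixture_protein(id = "ref")
  mid <- colMeans(coords(p)[p$atoms$seq_num %in% 5:6, , drop = FALSE])
  add_toy_ligand(p, center = mid + c(0, 3, 0), res_name = "LIG",
                 seq_num = 900L)
}

# random toy structure over realizable class sets (for property tests)
random_toy <- function(n, seed, spread = 8) {
  keys <- names(ssv:::CLASS_SET_ATOMS)
  with_seed(seed, {
    classes <- lapply(sample(keys, n, replace = TRUE),
                      function(k) strsplit(k, ",")[[1L]])
    make_toy_structure(classes, matrix(runif(3 * n) * spread, ncol = 3),
                       id = paste0("rnd", seed))
  })
}

# single-class-only toy (for the pair-count conservation property)
random_single_class_toy <- function(n, seed, spread = 8) {
  keys <- c("hydrophobic", "donor", "acceptor", "aromatic", "sulfur",
            "neutral")
  with_seed(seed, {
    classes <- as.list(sample(keys, n, replace = TRUE))
    make_toy_structure(classes, matrix(runif(3 * n) * spread, ncol = 3),
                       id = paste0("sng", seed))
  })
}

tmp_path <- function(ext) tempfile(fileext = ext)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
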