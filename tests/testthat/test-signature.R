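test_that("class_pair_index enumerates 36 symmetric indices", {
  expect_identical(class_pair_index("hydrophobic", "hydrophobic"), 0L)
  expect_identical(class_pair_index("positive", "negative"),
                   class_pair_index("negative", "positive"))
  grid_pairs <- expand.grid(a = PHARMACOPHORE_CLASSES,
                            b = PHARMACOPHORE_CLASSES,
                            stringsAsFactors = FALSE)
  idx <- class_pair_index(grid_pairs$a, grid_pairs$b)
  expect_equal(sort(unique(idx)), 0:35)
  expect_error(class_pair_index("hydrophobic", "greasy"),
               class = "ssv_typing_error")
})

test_that("default grid has 101 points and signatures have 3636 components", {
  g <- cutoff_grid()
  expect_length(g$points, 101L)
  expect_equal(g$points[c(1, 101)], c(0, 10))
  s <- random_toy(5, seed = 11)
  expect_length(compute_signature(s), 3636L)
})

test_that("single hydrophobic pair at 3.05 A fills the HH row from cutoff 3.1", {
  s <- make_toy_structure(list("hydrophobic", "hydrophobic"),
                          rbind(c(0, 0, 0), c(3.05, 0, 0)))
  sig <- compute_signature(s)
  hh <- as.numeric(sig[1:101])
  expect_equal(hh[1:31], rep(0, 31))     # cutoffs 0.0 .. 3.0
  expect_equal(hh[32:101], rep(1, 70))   # cutoffs 3.1 .. 10.0
  expect_equal(sum(sig[-(1:101)]), 0)
})

test_that("empty and single-atom structures give the zero vector", {
  empty <- fixture_protein()
  empty$atoms <- empty$atoms[0, ]
  expect_equal(sum(compute_signature(empty)), 0)
  one <- make_toy_structure(list("sulfur"), rbind(c(0, 0, 0)))
  expect_equal(sum(compute_signature(one)), 0)
  expect_equal(sum(brute_force_signature(list("sulfur"),
                                         rbind(c(0, 0, 0)))), 0)
})

test_that("signature equals the brute-force oracle on random instances", {
  for (seed in 1:25) {
    s <- random_toy(n = 5 + (seed %% 16), seed = seed)
    main <- as.numeric(compute_signature(s))
    oracle <- brute_force_signature(assign_pharmacophores(s), coords(s))
    expect_identical(main, oracle)
  }
  # also on a realistic multi-residue structure with intra-residue pairs
  p <- extract_pocket(fixture_protein(), whole_protein_pocket(fixture_protein()))
  expect_identical(as.numeric(compute_signature(p)),
                   brute_force_signature(assign_pharmacophores(p), coords(p)))
})

test_that("cumulative monotonicity holds within every class-pair row", {
  s <- random_toy(20, seed = 42)
  sig <- as.numeric(compute_signature(s))
  rows <- matrix(sig, nrow = 36, byrow = TRUE)
  expect_true(all(apply(rows, 1, function(r) all(diff(r) >= 0))))
})

test_that("signature is invariant to rigid motion and atom permutation", {
  s <- random_toy(15, seed = 7)
  sig <- as.numeric(compute_signature(s))
  a <- c(0.3, -1.2, 2.0)
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  moved <- s
  xyz <- coords(s) %*% t(Rz %*% Rx)
  moved$atoms$x <- xyz[, 1] + 5; moved$atoms$y <- xyz[, 2] - 3
  moved$atoms$z <- xyz[, 3] + 0.25
  expect_equal(as.numeric(compute_signature(moved)), sig, tolerance = 1e-9)

  perm <- with_seed(1, sample(n_atoms(s)))
  shuffled <- new_structure(s$atoms[perm, ], id = "perm")
  expect_identical(as.numeric(compute_signature(shuffled)), sig)
})

test_that("single-class typing conserves the total pair count", {
  for (seed in 1:10) {
    s <- random_single_class_toy(n = 12, seed = seed, spread = 6)
    sig <- as.numeric(compute_signature(s))
    rows <- matrix(sig, nrow = 36, byrow = TRUE)
    xyz <- coords(s)
    d <- as.numeric(dist(xyz))
    expect_equal(sum(rows[, 101]), sum(d <= 10 + 1e-9))
    expect_lte(sum(rows[, 101]), choose(nrow(xyz), 2))
  }
})

test_that("signature_distance is a Euclidean metric with shape checks", {
  g <- cutoff_grid()
  zeros <- ssv:::new_signature(numeric(3636), g)
  pyth <- ssv:::new_signature(`[<-`(numeric(3636), c(10, 2000), c(3, 4)), g)
  expect_equal(signature_distance(zeros, zeros), 0)
  expect_equal(signature_distance(zeros, pyth), 5)
  a <- random_toy(8, seed = 1); b <- random_toy(8, seed = 2)
  sa <- compute_signature(a); sb <- compute_signature(b)
  expect_equal(signature_distance(sa, sb), signature_distance(sb, sa))
  expect_error(signature_distance(sa, numeric(100)), class = "ssv_shape_error")
})

test_that("signature TSV round-trips with headers", {
  sigs <- lapply(1:3, function(i) {
    s <- random_toy(6, seed = i)
    sig <- compute_signature(s)
    attr(sig, "id") <- paste0("S", i)
    sig
  })
  path <- tmp_path(".tsv")
  write_signature_tsv(sigs, path)
  back <- read_signature_tsv(path)
  expect_named(back, c("S1", "S2", "S3"))
  expect_equal(as.numeric(back$S2), as.numeric(sigs[[2]]))
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header[1], "id")
  expect_equal(header[2], "hydrophobic:hydrophobic:0.0")
  expect_length(header, 3637)
})
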