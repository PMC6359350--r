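db_from_toys <- function(seeds, n = 8) {
  sigs <- lapply(seeds, function(s) compute_signature(random_toy(n, s)))
  names(sigs) <- sprintf("T%02d", seq_along(seeds))
  new_template_db(sigs)
}

test_that("template databases validate ids, dimensions and grids", {
  db <- db_from_toys(1:3)
  expect_s3_class(db, "ssv_template_db")
  expect_equal(nrow(db$signatures), 3L)

  sigs <- list(A = compute_signature(random_toy(5, 1)),
               A = compute_signature(random_toy(5, 2)))
  expect_error(new_template_db(sigs), class = "ssv_config_error")
  expect_error(new_template_db(list()), class = "ssv_config_error")
  expect_error(new_template_db(list(A = numeric(10))),
               class = "ssv_shape_error")
})

test_that("load_template_db works from PDB files and signature TSVs", {
  dir <- tempfile(); dir.create(dir)
  for (i in 1:3)
    write_pdb(random_toy(6, seed = i), file.path(dir, sprintf("t%d.pdb", i)))
  paths <- sort(list.files(dir, full.names = TRUE))
  db <- load_template_db(paths)
  expect_equal(db$ids, c("t1", "t2", "t3"))
  expect_equal(ncol(db$signatures), 3636L)

  tsv <- tmp_path(".tsv")
  sigs <- lapply(seq_along(db$ids), function(i) {
    sig <- ssv:::new_signature(db$signatures[i, ], db$grid, id = db$ids[i])
    sig
  })
  write_signature_tsv(sigs, tsv)
  db2 <- load_template_db(tsv)
  expect_equal(db2$signatures, db$signatures, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(db2$ids, db$ids)

  expect_error(load_template_db(character(0)), class = "ssv_config_error")
  expect_error(load_template_db(c(paths, paths[1])),
               class = "ssv_config_error")   # duplicate id
})

test_that("nearest_template matches an exhaustive scan and breaks ties by id", {
  db <- db_from_toys(1:5)
  for (seed in 11:20) {
    q <- compute_signature(random_toy(8, seed))
    got <- nearest_template(q, db)
    dists <- apply(db$signatures, 1, function(row)
      sqrt(sum((row - as.numeric(q))^2)))
    expect_equal(got$distance, min(dists))
    expect_equal(got$template_id, db$ids[which.min(dists)])
    expect_true(all(got$distance <= dists))
  }
  # self-query hits its own template at distance 0
  self <- ssv:::new_signature(db$signatures[3, ], db$grid)
  hit <- nearest_template(self, db)
  expect_equal(hit$template_id, "T03")
  expect_equal(hit$distance, 0)

  # equidistant templates: lexicographically smallest id wins
  g <- cutoff_grid()
  mat <- rbind(B = rep(1, 3636), A = rep(1, 3636))
  tie <- new_template_db(mat, g)
  expect_equal(nearest_template(numeric(3636), tie)$template_id, "A")
})

test_that("score_mutation implements the ddSSV semantics", {
  db <- db_from_toys(1:4)
  wild <- compute_signature(random_toy(8, 100))
  # mutant equal to a db template: dSSV_mt = 0, ddSSV = -dSSV_wt
  mut <- ssv:::new_signature(db$signatures[2, ], db$grid, id = "mt")
  res <- score_mutation(wild, mut, db)
  expect_equal(res$dssv_mt, 0)
  expect_equal(res$ddssv, -res$dssv_wt)
  expect_equal(res$label, "beneficial")
  expect_equal(res$ddssv, res$dssv_mt - res$dssv_wt)

  # mutant identical to wild: ddSSV = 0, neutral
  same <- score_mutation(wild, wild, db)
  expect_equal(same$ddssv, 0)
  expect_equal(same$label, "neutral")

  # antisymmetry under wild/mutant swap
  for (seed in 1:10) {
    a <- compute_signature(random_toy(7, seed + 200))
    b <- compute_signature(random_toy(7, seed + 300))
    expect_equal(score_mutation(a, b, db)$ddssv,
                 -score_mutation(b, a, db)$ddssv)
  }
})

test_that("adding an irrelevant far-away template never changes results", {
  db <- db_from_toys(1:3)
  far <- matrix(rep(1e6, 3636), nrow = 1,
                dimnames = list("ZZ_far", NULL))
  db_far <- new_template_db(rbind(db$signatures, far), db$grid)
  for (seed in 1:5) {
    w <- compute_signature(random_toy(8, seed + 400))
    m <- compute_signature(random_toy(8, seed + 500))
    expect_equal(score_mutation(w, m, db)[c("wild_template_id",
                                            "mutant_template_id", "ddssv")],
                 score_mutation(w, m, db_far)[c("wild_template_id",
                                                "mutant_template_id",
                                                "ddssv")])
  }
})

test_that("classify follows the sign rule with a neutral band", {
  expect_equal(classify(-186.18), "beneficial")
  expect_equal(classify(264.34), "not_beneficial")
  expect_equal(classify(0), "neutral")
  expect_equal(classify(c(-1, 0.5, 2), neutral_tol = 1),
               c("neutral", "neutral", "not_beneficial"))
  expect_error(classify(1, neutral_tol = -1), class = "ssv_config_error")
})
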