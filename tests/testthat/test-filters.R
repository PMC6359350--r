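test_that("conservation_profile computes per-position match fractions", {
  aln <- c(query = "AEG", r1 = "AEG", r2 = "AEG", r3 = "ATG", r4 = "A-G")
  prof <- conservation_profile(aln, "query")
  expect_equal(unname(prof[1]), 1.0)         # all 4 rows match A
  expect_equal(unname(prof[2]), 2 / 3)       # gap row excluded
  expect_equal(unname(prof[3]), 1.0)

  expect_error(conservation_profile(c(a = "AA", b = "AAA"), "a"),
               class = "ssv_format_error")
  expect_error(conservation_profile(aln, "nope"), class = "ssv_lookup_error")
})

test_that("the synthetic pocket alignment has exactly its planted conserved columns", {
  aln <- make_conservation_alignment(conserved_positions = c(3, 5, 8, 13, 17, 20))
  prof <- conservation_profile(aln, "query")
  expect_length(prof, 22L)
  expect_equal(as.integer(names(which(prof >= 1))), c(3, 5, 8, 13, 17, 20))
})

test_that("filter_conserved partitions exactly at the threshold", {
  prof <- setNames(c(1.0, 0.99, 0.5), c("10", "11", "12"))
  cand <- lapply(c("A10G", "A11G", "A12G", "A10V"), parse_mutation)
  res <- filter_conserved(cand, prof, threshold = 1.0)
  expect_length(res$survivors, 2L)
  expect_length(res$removed, 2L)
  expect_setequal(vapply(res$removed, format_mutation, ""),
                  c("A10G", "A10V"))
  # partition law
  expect_equal(length(res$survivors) + length(res$removed), length(cand))

  # no column at 1.0 -> identity
  res2 <- filter_conserved(cand, prof - 0.01, threshold = 1.0)
  expect_length(res2$survivors, length(cand))

  expect_error(filter_conserved(list(parse_mutation("A99G")), prof),
               class = "ssv_lookup_error")
  expect_error(filter_conserved(cand, prof, threshold = 0),
               class = "ssv_config_error")
})

test_that("read_sift_table handles flag and score layouts", {
  flag <- write_tsv(data.frame(position = c(228, 228, 230),
                               aa = c("T", "W", "G"),
                               tolerated = c("yes", "no", "yes")),
                    tmp_path(".tsv"))
  allowed <- read_sift_table(flag)
  expect_true("T" %in% allowed[["228"]])
  expect_false("W" %in% allowed[["228"]])

  score <- write_tsv(data.frame(position = c(1, 1), aa = c("A", "C"),
                                score = c(0.03, 0.2)),
                     tmp_path(".tsv"))
  allowed2 <- read_sift_table(score, cutoff = 0.05)
  expect_false("A" %in% allowed2[["1"]])
  expect_true("C" %in% allowed2[["1"]])

  empty <- write_tsv(data.frame(position = integer(0), aa = character(0),
                                tolerated = character(0)),
                     tmp_path(".tsv"))
  expect_warning(m <- read_sift_table(empty), "empty")
  expect_length(m, 0L)

  bad <- write_tsv(data.frame(position = 1, aa = "A"), tmp_path(".tsv"))
  expect_error(read_sift_table(bad), class = "ssv_format_error")
})

test_that("read_mcsm_table validates keys and values", {
  ok <- write_tsv(data.frame(mutation = c("H228T", "H228C"),
                             ddg = c(-0.5, -2.4)), tmp_path(".tsv"))
  ddg <- read_mcsm_table(ok)
  expect_equal(ddg[["H228T"]], -0.5)

  dup <- write_tsv(data.frame(mutation = c("H228T", "H228T"),
                              ddg = c(-0.5, -1)), tmp_path(".tsv"))
  expect_error(read_mcsm_table(dup), class = "ssv_format_error")

  nocol <- write_tsv(data.frame(mutation = "H228T"), tmp_path(".tsv"))
  expect_error(read_mcsm_table(nocol), class = "ssv_format_error")

  badmut <- write_tsv(data.frame(mutation = "H228H", ddg = 1),
                      tmp_path(".tsv"))
  expect_error(read_mcsm_table(badmut), class = "ssv_parse_error")
})

test_that("apply_filter_chain keeps exact audit bookkeeping", {
  fx <- make_screen_filter_fixture()
  res <- apply_filter_chain(fx$candidates, fx$stages)
  audit <- res$audit
  expect_equal(attr(audit, "initial"), 86L)
  expect_equal(audit$removed, c(9L, 58L, 4L))
  expect_equal(audit$remaining, c(77L, 19L, 15L))
  expect_length(res$survivors, 15L)
  # bookkeeping identity
  expect_equal(attr(audit, "initial") - sum(audit$removed),
               audit$remaining[nrow(audit)])

  # empty stage list: identity with empty audit
  none <- apply_filter_chain(fx$candidates)
  expect_length(none$survivors, 86L)
  expect_equal(nrow(none$audit), 0L)

  # stage removing everything
  allgone <- apply_filter_chain(fx$candidates,
                                list(wipe = function(spec) FALSE))
  expect_length(allgone$survivors, 0L)
  expect_equal(allgone$audit$remaining, 0L)
})

test_that("independent predicate stages give order-insensitive survivor sets", {
  fx <- make_screen_filter_fixture()
  orders <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  keysets <- lapply(orders, function(ord) {
    out <- apply_filter_chain(fx$candidates, fx$stages[ord])
    sort(vapply(out$survivors, format_mutation, ""))
  })
  expect_equal(keysets[[2]], keysets[[1]])
  expect_equal(keysets[[3]], keysets[[1]])
})
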