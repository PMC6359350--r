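test_that("residues_near_ligand includes the boundary and orders residues", {
  # ligand atom at origin; residue A atom at 6.4, residue B at 6.6
  base <- make_toy_structure(list("hydrophobic", "hydrophobic"),
                             rbind(c(6.4, 0, 0), c(6.6, 0, 0)))
  lig <- add_toy_ligand(base, center = c(0, 0, 0))
  # shrink ligand to its single C1 atom at the origin
  lig$atoms <- lig$atoms[!lig$atoms$is_hetero | lig$atoms$name == "C1", ]
  pocket <- residues_near_ligand(lig, "A:900", cutoff = 6.5)
  expect_equal(nrow(pocket$residues), 1L)
  expect_equal(pocket$residues$seq_num, 1L)

  # monotone in cutoff
  p2 <- residues_near_ligand(lig, "A:900", cutoff = 7.0)
  expect_true(all(ssv:::residue_key(pocket$residues) %in%
                    ssv:::residue_key(p2$residues)))

  expect_error(residues_near_ligand(lig, "A:900", cutoff = 0.0),
               class = "ssv_lookup_error")
  expect_error(residues_near_ligand(lig, "B:900", cutoff = 6.5),
               class = "ssv_lookup_error")
})

test_that("residues_near_ligand on the complex fixture selects nearby residues only", {
  cx <- fixture_complex()
  pocket <- residues_near_ligand(cx, "A:900:LIG", cutoff = 6.5)
  expect_gt(nrow(pocket$residues), 0)
  expect_lt(nrow(pocket$residues), nrow(residue_table(cx)))
  # every selected residue really has an atom within the cutoff
  at <- cx$atoms
  lig_xyz <- as.matrix(at[at$is_hetero, c("x", "y", "z")])
  for (i in seq_len(nrow(pocket$residues))) {
    rsel <- !at$is_hetero & at$seq_num == pocket$residues$seq_num[i]
    rx <- as.matrix(at[rsel, c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(rx^2), rowSums(lig_xyz^2), "+") -
                       2 * rx %*% t(lig_xyz)))
    expect_lte(dmin, 6.5 + 1e-9)
  }
})

test_that("kabsch_superpose recovers rigid motions and the frozen optimum", {
  pts <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  id <- kabsch_superpose(pts, pts)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)

  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- pts %*% t(R) + matrix(c(3, -2, 7), 4, 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(moved %*% t(fit$rotation) +
                 matrix(fit$translation, 4, 3, byrow = TRUE),
               pts, tolerance = 1e-9)

  # frozen value from an independent rotation-grid/Nelder-Mead oracle on
  # this instance: square with one corner displaced 1 A out of plane
  mobile <- pts; mobile[1, ] <- mobile[1, ] + c(0, 0, 1)
  expect_equal(kabsch_superpose(mobile, pts)$rmsd, 0.2572540698,
               tolerance = 1e-6)

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]),
               class = "ssv_input_error")
  expect_error(kabsch_superpose(pts, pts[1:3, ]), class = "ssv_input_error")
})

test_that("kabsch rmsd is invariant under rigid pre-transformation of mobile", {
  s <- fixture_protein()
  target <- coords(s)
  mobile <- target
  mobile[1, ] <- mobile[1, ] + c(0.5, -0.2, 0.1)
  base <- kabsch_superpose(mobile, target)$rmsd
  for (seed in 1:5) {
    rot <- with_seed(seed, {
      a <- runif(3, -pi, pi)
      Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
                  c(0, sin(a[1]), cos(a[1])))
      Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0),
                  c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
      list(R = Rz %*% Rx, t = runif(3, -10, 10))
    })
    pre <- mobile %*% t(rot$R) + matrix(rot$t, nrow(mobile), 3, byrow = TRUE)
    expect_equal(kabsch_superpose(pre, target)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("map_pocket is the identity on identical structures and tracks substitutions", {
  ref <- fixture_protein("ref")
  pocket <- new_pocket(residue_table(ref)[3:5, c("chain_id", "seq_num",
                                                 "icode", "res_name")],
                       reference_id = "ref", cutoff = 6.5)
  same <- map_pocket(ref, pocket, ref)
  expect_equal(same$residues, pocket$residues)

  mut <- apply_mutation(ref, "K3R", mode = "graft")
  moved <- map_pocket(ref, pocket, mut)
  expect_equal(moved$residues$seq_num, pocket$residues$seq_num)
  expect_equal(moved$residues$res_name[1], "ARG")
})

test_that("map_pocket shifts numbering across an N-terminal insertion", {
  ref <- fixture_protein("ref")
  # target: same sequence with a two-residue N-terminal extension
  seq_ref <- paste(ssv:::three_to_one(residue_table(ref)$res_name),
                   collapse = "")
  target <- make_toy_protein(paste0("GG", seq_ref), chain_id = "A",
                             id = "ins")
  pocket <- new_pocket(residue_table(ref)[c(2, 6, 9), c("chain_id",
                                                        "seq_num", "icode",
                                                        "res_name")],
                       reference_id = "ref")
  mapped <- map_pocket(ref, pocket, target)
  expect_equal(mapped$residues$seq_num, pocket$residues$seq_num + 2L)
  expect_equal(mapped$residues$res_name, pocket$residues$res_name)
})

test_that("map_pocket enforces the identity floor", {
  ref <- make_toy_protein("AAAAAAAAAA", id = "polyA")
  tgt <- make_toy_protein("WWWWWWWWWW", id = "polyW")
  pocket <- whole_protein_pocket(ref)
  expect_error(map_pocket(ref, pocket, tgt, min_identity = 20),
               class = "ssv_input_error")
})

test_that("extract_pocket selects exactly the pocket residues, errors on absences", {
  s <- fixture_protein()
  rt <- residue_table(s)
  pocket <- new_pocket(rt[c(2, 5), c("chain_id", "seq_num", "icode",
                                     "res_name")])
  sub <- extract_pocket(s, pocket)
  expect_equal(nrow(residue_table(sub)), 2L)
  expect_equal(residue_table(sub)$seq_num, c(2L, 5L))
  expect_equal(n_atoms(sub), sum(rt$n_atoms[c(2, 5)]))

  whole <- extract_pocket(s, whole_protein_pocket(s))
  expect_equal(coords(whole), coords(s))

  ghost <- new_pocket(data.frame(chain_id = "A", seq_num = 99L, icode = "",
                                 res_name = "ALA"))
  err <- expect_error(extract_pocket(s, ghost), class = "ssv_lookup_error")
  expect_match(conditionMessage(err), "99")
})

test_that("pocket TSV round-trips", {
  s <- fixture_protein()
  pocket <- new_pocket(residue_table(s)[1:4, c("chain_id", "seq_num",
                                               "icode", "res_name")],
                       reference_id = s$id, cutoff = 6.5)
  path <- tmp_path(".tsv")
  write_pocket_tsv(pocket, path)
  back <- read_pocket_tsv(path, reference_id = s$id, cutoff = 6.5)
  expect_equal(back$residues, pocket$residues)
})
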