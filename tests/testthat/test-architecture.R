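test_that("default interaction table reproduces the parameter set", {
  tab <- default_interactions()
  expect_equal(tab$chi["C", "W"], 1.2)
  expect_equal(tab$chi["NH", "W"], -0.6)
  expect_equal(tab$chi["O", "W"], -0.6)
  expect_equal(tab$chi["C", "NH3+"], 3)
  expect_equal(unname(tab$chi["C", c("NH", "O", "Na", "Cl")]), rep(2, 4))
  expect_true(all(diag(tab$chi) == 0))
  expect_identical(tab$chi, t(tab$chi))
  # chi pairs not listed are athermal
  expect_equal(tab$chi["Na", "Cl"], 0)
  expect_equal(tab$chi["NH3+", "W"], 0)

  kd <- tab$kinds
  expect_equal(kd$valency[kd$kind == "NH3+"], 1L)
  expect_equal(kd$valency[kd$kind == "Na"], 1L)
  expect_equal(kd$valency[kd$kind == "Cl"], -1L)
  expect_equal(sum(abs(kd$valency)), 3L)
  expect_equal(kd$eps_r[kd$kind == "W"], 80)
  expect_equal(kd$eps_r[kd$kind == "C"], 2)
  expect_equal(kd$eps_r[kd$kind == "Na"], 10)
})

test_that("molecule builder obeys the dendron counting rules", {
  # the two-tailed generation-1 molecule: 4 charged terminals
  mol <- build_molecule(1, 2, 12)
  expect_equal(sum(mol$nodes$terminal), 4L)
  expect_equal(sum(mol$nodes$part == "tail"), 24L)
  expect_true(all(mol$nodes$kind[mol$nodes$terminal] == "NH3+"))

  # terminal count 2^(G+1), property over G = 0..5
  for (G in 0:5) {
    m <- build_molecule(G, 1, 4)
    expect_equal(sum(m$nodes$terminal), 2L^(G + 1L))
    expect_equal(kind_counts(m)[["NH3+"]], 2L^(G + 1L))
  }

  # tail bookkeeping
  m <- build_molecule(2, 6, 16)
  expect_equal(sum(m$nodes$part == "tail"), 96L)
  expect_equal(sum(m$nodes$terminal), 8L)
  expect_equal(n_segments(m),
               sum(m$nodes$part == "dendron") + 6L * 16L)

  # invalid inputs
  expect_error(build_molecule(-1, 2, 12))
  expect_error(build_molecule(1, 0, 12))
  expect_error(build_molecule(1, 2, 0))
  bad <- lysine_repeat_unit(); bad$long_term <- c("C", "NH")
  expect_error(build_molecule(1, 2, 12, repeat_unit = bad),
               "charged")
})

test_that("contour classes match exhaustive root-to-leaf path walks", {
  walk_contour <- function(mol, id) {
    # independent oracle: follow parent pointers and count edges
    n <- 0L
    while (mol$nodes$parent[id] != 0L) {
      id <- mol$nodes$parent[id]
      n <- n + 1L
    }
    n
  }
  # linear chain: a single class
  lin <- linear_chain(c(rep("C", 5), "NH3+"))
  cc <- contour_classes(lin)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$contour, walk_contour(lin, cc$id))

  # symmetric dendron: one class for the whole tree
  sym <- make_fixture("symmetric-dendron-G2")$value
  cs <- contour_classes(sym)
  expect_equal(length(unique(cs$contour)), 1L)

  # asymmetric lysine dendron, G = 2: classes equal the oracle walks
  mol <- build_molecule(2, 1, 5)
  cm <- contour_classes(mol)
  oracle <- vapply(cm$id, function(i) walk_contour(mol, i), 0L)
  expect_equal(cm$contour, oracle)
  # G+2 distinct classes for the default (short/long) asymmetric unit
  expect_equal(length(unique(cm$contour)), 2L + 2L)
})

test_that("serialization round-trips preserve the molecule", {
  mol <- build_molecule(2, 3, 7)
  cfg <- as_config(mol)
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  back <- molecule_from_config(jsonlite::fromJSON(js))
  expect_identical(back$nodes, mol$nodes)
  expect_equal(n_segments(back), n_segments(mol))
})

test_that("perturb_table applies symmetric perturbations only", {
  tb <- default_interactions()
  t2 <- perturb_table(tb, c("C", "W"), 0.1)
  expect_equal(t2$chi["C", "W"], 1.3)
  expect_equal(t2$chi["W", "C"], 1.3)
  expect_identical(perturb_table(tb, c("C", "W"), 0)$chi, tb$chi)
  expect_error(perturb_table(tb, c("C", "C"), 0.1), "diagonal")
})
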