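test_that("zero rate yields a constant matrix with no recorded changes", {
  cfg <- sim_config(n_taxa = 10, rate = 0)
  tree <- simulate_tree(10, seed = 1)
  ev <- evolve_characters(tree, cfg, seed = 1)
  expect_true(all(ev$true_changes == 0))
  expect_true(all(apply(ev$states, 2, function(x) length(unique(x))) == 1))
})

test_that("expected change counts equal rate x total branch length", {
  cfg <- sim_config(n_taxa = 15, rate = 0.08,
                    n_char_by_category = c(architectural = 400L))
  tree <- simulate_tree(15, seed = 2)
  L <- sum(tree$edge.length)
  ev <- evolve_characters(tree, cfg, seed = 2)
  per_char <- rowSums(ev$true_changes)
  expeced <- 0.08 * L
  se <- sqrt(expeced / length(per_char))
  expect_lt(abs(mean(per_char) - expeced), 4 * se)
})

test_that("at low rates parsimony recovers the true change count exactly", {
  cfg <- sim_config(n_taxa = 12, rate = 0.004, pct_unknown = 0,
                    pct_inapplicable = 0, pct_polymorphic = 0)
  ds <- simulate_dataset(cfg, seed = 5)
  s <- fitch_length(ds$tree, ds$matrix)$per_character
  expect_equal(s, unname(rowSums(ds$true_changes)))
})

test_that("masking hits its targets exactly on the study profile", {
  cfg <- sim_config()          # defaults: 79 taxa, 89 characters
  ds <- simulate_dataset(cfg, seed = 9)
  s <- summarize_matrix(ds$matrix)
  expect_equal(s$n_cells, 7031L)
  ncell <- 79 * 89
  expect_equal(s$pct_unknown, 100 * round(0.139 * ncell) / ncell)
  expect_equal(s$pct_inapplicable, 100 * round(0.105 * ncell) / ncell)
  expect_lt(abs(s$pct_missing - 24.4), 0.5)
  expect_lt(abs(s$pct_polymorphic - 0.1), 0.05)
  # masked matrix differs from the complete one only at masked cells
  unmasked <- ds$mask == ""
  tokens <- mc$cell_tokens(ds$matrix)
  expect_identical(tokens[unmasked],
                   as.character(ds$states)[unmasked])
})

test_that("all-zero masking targets return the complete matrix", {
  cfg <- sim_config(n_taxa = 10, pct_unknown = 0, pct_inapplicable = 0,
                    pct_polymorphic = 0)
  ds <- simulate_dataset(cfg, seed = 4)
  expect_true(all(ds$mask == ""))
  expect_true(all(ds$matrix$kind == "d"))
})

test_that("fully hierarchical inapplicables co-occur with their controlling state", {
  cfg <- sim_config(n_taxa = 40, hierarchy_fraction = 1,
                    pct_unknown = 5, pct_inapplicable = 8,
                    pct_polymorphic = 0)
  ds <- simulate_dataset(cfg, seed = 6)
  inap <- which(ds$mask == "i", arr.ind = TRUE)
  ctrl <- ds$controllers
  expect_gt(nrow(inap), 0)
  ok <- vapply(seq_len(nrow(inap)), function(r) {
    i <- inap[r, 1]; j <- inap[r, 2]
    any(ctrl$dependent == j & ds$states[i, ctrl$controller] == ctrl$state)
  }, logical(1))
  expect_true(all(ok))
})

test_that("state-count distribution reproduces the study's total state count", {
  cfg <- sim_config()
  tot <- replicate(30, sum(sample(2:5, 89, TRUE,
                                  prob = c(0.70, 0.18, 0.09, 0.03))))
  expect_lt(abs(mean(tot) - 218), 6)
})

test_that("simulated grades slice the tree into a clade and two grades", {
  cfg <- sim_config(n_taxa = 24)
  ds <- simulate_dataset(cfg, seed = 8)
  expect_setequal(unlist(ds$groups), ds$tree$tip.label)
  expect_equal(length(ds$groups), 3L)
  # the third group is a clade on the true tree
  tr <- mc$phylo_to_ptree(ds$tree, ds$tree$tip.label)
  below <- mc$ptree_clades(tr)
  keys <- vapply(below[-seq_len(tr$nleaf)], mc$clade_key, character(1))
  g3 <- mc$clade_key(sort(match(ds$groups[[3]], ds$tree$tip.label)))
  expect_true(g3 %in% keys)
})

test_that("more unknown cells never sharpen the consensus", {
  set.seed(1401)
  res <- sapply(c(0, 40), function(pu) {
    mean(sapply(1:6, function(sd0) {
      cfg <- strong_signal_config(12)
      cfg$pct_unknown <- pu
      ds <- simulate_dataset(cfg, seed = 100 + sd0)
      s <- mp_search(ds$matrix, replicates = 2, hold = 5, seed = sd0)
      cons <- strict_consensus(s)
      length(mc$tree_biparts(cons, sort(ds$matrix$taxa), 1L))
    }))
  })
  expect_gte(res[1], res[2])
})
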