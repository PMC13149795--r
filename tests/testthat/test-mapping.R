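quartet <- ape::read.tree(text = "((A,B),(C,D));")

qmat <- function(states, nch = 1) {
  tok <- matrix(states, 4, nch)
  rownames(tok) <- LETTERS[1:4]
  morph_matrix(tok)
}

test_that("unambiguous synapomorphy maps to the internal branch under every policy", {
  # on the rooted quartet the internal branch is subdivided by the root,
  # so the single change sits on one root-child edge (or is split half
  # and half under MPR averaging) — never on a terminal branch
  m <- qmat(c("0", "0", "1", "1"))
  for (pol in c("acctran", "deltran", "mpr_average")) {
    r <- optimize_character(quartet, m, 1, pol)
    expect_equal(sum(r$branch_changes), 1, tolerance = 1e-9)
    below <- mc$ptree_clades(r$tree)
    hot <- r$children[r$branch_changes > 1e-9]
    for (v in hot)
      expect_true(mc$clade_key(below[[v]]) %in% c("1,2", "3,4"))
  }
})

test_that("conflicting character: equal totals, different placements under acctran/deltran", {
  m <- qmat(c("0", "1", "0", "1"))
  acc <- optimize_character(quartet, m, 1, "acctran")
  del <- optimize_character(quartet, m, 1, "deltran")
  expect_equal(acc$total, 2L)
  expect_equal(del$total, 2L)
  expect_false(identical(acc$branch_changes, del$branch_changes))
  avg <- optimize_character(quartet, m, 1, "mpr_average")
  expect_equal(sum(avg$branch_changes), 2, tolerance = 1e-9)
})

test_that("constant characters map zero changes everywhere", {
  m <- qmat(c("0", "0", "0", "0"))
  for (pol in c("acctran", "deltran", "mpr_average"))
    expect_true(all(optimize_character(quartet, m, 1, pol)$branch_changes == 0))
})

test_that("hard polytomy: three states on a star need two changes", {
  tok <- matrix(c("0", "1", "2"), 3, 1, dimnames = list(c("A", "B", "C")))
  m <- morph_matrix(tok)
  star <- ape::read.tree(text = "(A,B,C);")
  for (pol in c("acctran", "deltran", "mpr_average")) {
    r <- optimize_character(star, m, 1, pol)
    expect_equal(sum(r$branch_changes), 2, tolerance = 1e-9)
  }
})

test_that("per-branch totals equal Fitch steps for every policy (random cases)", {
  set.seed(909)
  for (rep in 1:10) {
    tok <- rand_tokens(7, 6, k = 3, p_unknown = 0.15, p_poly = 0.05)
    m <- morph_matrix(tok)
    tree <- rand_tree(m)
    steps <- fitch_length(tree, m)$per_character
    for (pol in c("acctran", "deltran", "mpr_average")) {
      ch <- mc$branch_change_matrix(mc$phylo_to_ptree(tree, m$taxa), m, pol)
      expect_equal(unname(rowSums(ch)), as.numeric(steps),
                   tolerance = 1e-9)
    }
  }
})

test_that("per-edge MPR change bounds and averages match brute-force enumeration", {
  set.seed(910)
  for (rep in 1:12) {
    ntax <- sample(4:6, 1)
    tok <- rand_tokens(ntax, 2, k = sample(2:3, 1), p_unknown = 0.2)
    m <- morph_matrix(tok)
    tr <- mc$phylo_to_ptree(rand_tree(m), m$taxa)
    mp <- mc$map_characters(tr, m)
    for (ch in 1:2) {
      bf <- brute_edge_stats(tr, m, ch)
      expect_equal(mp$steps[ch], bf$steps)
      expect_equal(unname(mp$edge_min[ch, ]), unname(bf$emin))
      expect_equal(unname(mp$edge_max[ch, ]), unname(bf$emax))
      expect_equal(unname(mp$edge_frac[ch, ]), unname(bf$efrac),
                   tolerance = 1e-6)
    }
  }
})

test_that("branches are assigned to groups only when all assigned descendants agree", {
  tree <- ape::read.tree(text = "((((a1,a2),(a3,a4)),((b1,b2),(c1,c2))),o);")
  tok <- rand_tokens(9, 4, k = 2)
  rownames(tok) <- c(paste0("a", 1:4), "b1", "b2", "c1", "c2", "o")
  m <- morph_matrix(tok)
  groups <- list(ga = paste0("a", 1:4), gb = c("b1", "b2"),
                 gc = c("c1", "c2"))
  asg <- assign_branches(tree, m, groups)
  key_of <- function(labs) mc$clade_key(sort(match(labs, m$taxa)))
  expect_equal(asg$group[asg$branch == key_of("a1")], "ga")      # terminal
  expect_equal(asg$group[asg$branch == key_of(c("a1", "a2"))], "ga")
  expect_true(is.na(asg$group[asg$branch ==
                                key_of(c("b1", "b2", "c1", "c2"))]))
  expect_true(is.na(asg$group[asg$branch == key_of("o")]))       # unassigned

  expect_error(assign_branches(tree, m,
                               list(ga = c("a1", "a2"), gb = c("a1", "b1"))),
               "overlap")
})

test_that("segment rates match a hand-counted toy construction", {
  # one character changing once inside a 4-taxon group, fully scorable
  tree <- ape::read.tree(text = "(((a1,a2),(a3,a4)),(b1,b2));")
  tok <- cbind(c("0", "0", "1", "1", "0", "0"),
               c("0", "0", "0", "0", "0", "1"))
  rownames(tok) <- c(paste0("a", 1:4), "b1", "b2")
  m <- morph_matrix(tok)
  groups <- list(ga = paste0("a", 1:4), gb = c("b1", "b2"))
  rt <- segment_rates(tree, m, groups,
                      categories = c("architectural", "cellular"))
  expect_equal(rt$transitions[1, "ga"], 1)
  expect_equal(rt$scorable[1, "ga"], 4)
  expect_equal(rt$rates[1, "ga"], 0.25)
  expect_equal(rt$rates[1, "gb"], 0)
  expect_equal(rt$rates[2, "gb"], 0.5)      # autapomorphy of b2
  expect_equal(unname(rt$overall["ga"]), mean(c(0.25, 0)))
})

test_that("group-wise transition sums never exceed total transitions", {
  set.seed(911)
  tok <- rand_tokens(10, 8, k = 2, p_unknown = 0.1)
  m <- morph_matrix(tok)
  tree <- rand_tree(m)
  groups <- list(g1 = m$taxa[1:3], g2 = m$taxa[4:6], g3 = m$taxa[7:9])
  rt <- segment_rates(tree, m, groups,
                      categories = rep("cellular", 8))
  total <- fitch_length(tree, m)$per_character
  expect_true(all(rowSums(rt$transitions) <= total + 1e-9))
})
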