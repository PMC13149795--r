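mkranges <- function(...) {
  x <- list(...)
  data.frame(taxon = names(x),
             fad = vapply(x, `[`, numeric(1), 1),
             lad = vapply(x, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}

test_that("node ages follow the oldest-descendant-FAD rule", {
  tree <- ape::read.tree(text = "(A,B);")
  r <- mkranges(A = c(350, 340), B = c(340, 330))
  ts <- timescale(tree, r, epsilon_ma = 0)
  expect_equal(ts$node_ages[3], 350)     # root = max(fads)
  expect_equal(ts$node_ages[1:2], c(350, 340))

  # a cherry inside a clade whose other member is older: the internal
  # node inherits the older FAD
  t4 <- ape::read.tree(text = "((A,(B,C)),D);")
  r4 <- mkranges(A = c(360, 350), B = c(330, 320), C = c(335, 325),
                 D = c(365, 300))
  ts4 <- timescale(t4, r4, epsilon_ma = 0)
  n <- 4L
  lab <- t4$tip.label
  bc_node <- t4$edge[t4$edge[, 2] == which(lab == "B"), 1]
  abc_node <- t4$edge[t4$edge[, 2] == bc_node, 1]
  expect_equal(ts4$node_ages[bc_node], 335)    # max(B, C)
  expect_equal(ts4$node_ages[abc_node], 360)   # inherits A's older FAD
  root <- t4$edge[1, 1]
  expect_equal(ts4$node_ages[root], 365)
})

test_that("ages are monotone and epsilon imposes minimum internal durations", {
  set.seed(1301)
  tree <- ape::rtree(8, br = NULL)
  fads <- sort(runif(8, 300, 360), decreasing = TRUE)
  r <- data.frame(taxon = tree$tip.label, fad = fads, lad = fads - 5)
  ts0 <- timescale(tree, r, epsilon_ma = 0)
  expect_true(all(ts0$tree$edge.length >= -1e-12))
  ts <- timescale(tree, r, epsilon_ma = 0.5)
  internal <- ts$tree$edge[, 2] > 8
  expect_true(all(ts$tree$edge.length[internal] >= 0.5 - 1e-12))
  for (e in seq_len(nrow(ts$tree$edge)))
    expect_gte(ts$node_ages[ts$tree$edge[e, 1]],
               ts$node_ages[ts$tree$edge[e, 2]])
  # terminal nodes sit at their FAD
  expect_equal(unname(ts$node_ages[1:8]),
               r$fad[match(tree$tip.label, r$taxon)])
})

test_that("a missing range is reported by taxon name", {
  tree <- ape::read.tree(text = "(A,B);")
  expect_error(timescale(tree, mkranges(A = c(350, 340))), "B")
})

test_that("record gaps are the exact complement of the range union", {
  r <- mkranges(a = c(360, 350), b = c(355, 330), c = c(330, 300))
  expect_equal(nrow(record_gaps(r)), 0L)   # continuous coverage

  r2 <- mkranges(a = c(360, 350), b = c(340, 300))
  g2 <- record_gaps(r2)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$older, 350)
  expect_equal(g2$younger, 340)
  expect_equal(g2$duration, 10)

  # synthetic emulation of a long mid-window hiatus
  r3 <- mkranges(a = c(365, 340), b = c(345, 293), c = c(259, 252),
                 d = c(255, 251.9))
  g3 <- record_gaps(r3)
  expect_equal(nrow(g3), 1L)
  expect_equal(g3$duration, 34)
  expect_equal(g3$older, 293)

  # short gaps suppressed below the resolution
  r4 <- mkranges(a = c(360, 352), b = c(350, 340), c = c(330, 320))
  g4 <- record_gaps(r4, resolution_myr = 5)
  expect_equal(nrow(g4), 1L)               # the 2-Myr gap is dropped
  expect_equal(g4$duration, 10)
})

test_that("gap finding matches a brute-force grid scan", {
  set.seed(1302)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    fad <- runif(n, 310, 360)
    lad <- fad - runif(n, 2, 25)
    r <- data.frame(taxon = paste0("t", 1:n), fad = fad, lad = lad)
    g <- record_gaps(r)
    grid <- seq(min(lad) + 0.05, max(fad) - 0.05, by = 0.1)
    covered <- rowSums(outer(grid, r$lad, ">=") &
                         outer(grid, r$fad, "<=")) > 0
    in_gap <- rowSums(outer(grid, g$younger, ">") &
                        outer(grid, g$older, "<")) > 0
    expect_equal(in_gap, !covered)
  }
})

test_that("the bundled stage lookup is ordered and contiguous", {
  st <- ics_stages()
  expect_true(all(diff(st$older) < 0))
  expect_equal(st$older[-1], st$younger[-nrow(st)])
})
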