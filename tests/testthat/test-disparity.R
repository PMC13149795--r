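test_that("Gower distance is the mismatch proportion over mutually scored characters", {
  tok <- rbind(ta = c("0", "1", "2", "0", "1"),
               tb = c("0", "1", "2", "0", "1"),
               tc = c("1", "0", "0", "1", "0"),
               td = c("0", "1", "?", "-", "0"))
  m <- morph_matrix(tok)
  g <- gower_distance(m)
  expect_equal(g$d["ta", "tb"], 0)
  expect_equal(g$d["ta", "tc"], 1)
  # ta vs td: 3 shared characters (col 3 unknown, col 4 inapplicable
  # in td), one mismatch (col 5)
  expect_equal(g$d["ta", "td"], 1 / 3)
  expect_equal(g$n_shared["ta", "td"], 3L)
})

test_that("Gower matches cluster::daisy on random masked matrices", {
  skip_if_not_installed("cluster")
  set.seed(1201)
  for (rep in 1:5) {
    tok <- rand_tokens(8, 12, k = 3, p_unknown = 0.2, p_inapp = 0.1)
    m <- morph_matrix(tok)
    g <- gower_distance(m)
    df <- as.data.frame(lapply(seq_len(ncol(tok)), function(j) {
      x <- tok[, j]
      x[x %in% c("?", "-")] <- NA
      factor(x)
    }))
    d2 <- as.matrix(cluster::daisy(df, metric = "gower"))
    dimnames(d2) <- dimnames(g$d)
    expect_equal(g$d, d2, tolerance = 1e-12)
  }
})

test_that("a taxon pair with no mutually scored characters is an error", {
  tok <- rbind(ta = c("0", "?"), tb = c("?", "1"), tc = c("0", "1"))
  m <- morph_matrix(tok)
  expect_error(gower_distance(m), "ta / tb")
})

test_that("polymorphic cells are recoded before distances are computed", {
  tok <- rbind(ta = c("{01}", "0"), tb = c("0", "0"), tc = c("1", "1"))
  m <- morph_matrix(tok)
  g <- gower_distance(m)
  expect_equal(g$n_shared["ta", "tb"], 1L)   # polymorphic cell excluded
})

test_that("PCoA of collinear points loads everything on one axis", {
  D <- as.matrix(dist(c(0, 1, 2)))
  rownames(D) <- colnames(D) <- paste0("t", 1:3)
  p <- pcoa(D)
  expect_equal(p$pct_variance[1], 100)
})

test_that("PCoA inverts Euclidean distances up to rotation", {
  set.seed(1202)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  p <- pcoa(D)
  D2 <- as.matrix(dist(p$coordinates[, 1:2]))
  expect_equal(unname(D2), unname(D), tolerance = 1e-9)
  # Procrustes residual against the generating configuration
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(p$coordinates[, 1:2], scale = FALSE)
  sv <- svd(crossprod(Yc, Xc))
  rot <- Yc %*% (sv$u %*% t(sv$v))
  expect_lt(sqrt(sum((rot - Xc)^2)), 1e-6)
  # and against base R cmdscale
  cs <- stats::cmdscale(D, k = 2)
  expect_equal(abs(unname(p$coordinates[, 1:2])), abs(unname(cs)),
               tolerance = 1e-9)
})

test_that("percent variance is invariant to taxon order", {
  set.seed(1203)
  tok <- rand_tokens(8, 15, k = 3, p_unknown = 0.1)
  m <- morph_matrix(tok)
  g <- gower_distance(m)
  p1 <- pcoa(g)
  perm <- sample(8)
  p2 <- pcoa(g$d[perm, perm])
  expect_equal(p1$pct_variance, p2$pct_variance, tolerance = 1e-9)
})

test_that("similarity export has a unit diagonal and honours the given order", {
  set.seed(1204)
  tok <- rand_tokens(6, 10, k = 2)
  m <- morph_matrix(tok)
  g <- gower_distance(m)
  S <- similarity_heatmap_export(g)
  expect_equal(unname(diag(S)), rep(1, 6))
  expect_equal(S, t(S))
  rev_order <- rev(m$taxa)
  S2 <- similarity_heatmap_export(g, rev_order)
  expect_equal(S2, S[rev_order, rev_order])
  expect_error(similarity_heatmap_export(g, m$taxa[-1]), "permutation")
})

test_that("two divergent simulated clades produce block structure", {
  set.seed(1205)
  cfg <- sim_config(n_taxa = 10, rate = 0.08, pct_unknown = 0,
                    pct_inapplicable = 0, pct_polymorphic = 0,
                    brlen_min = 0.5)
  ds <- simulate_dataset(cfg, seed = 3)
  g <- gower_distance(ds$matrix)
  ord <- consensus_leaf_order(ds$tree)
  S <- similarity_heatmap_export(g, ord)
  # mean similarity between tree-adjacent taxa exceeds the off-block mean
  adj <- mean(S[cbind(1:9, 2:10)])
  far <- mean(S[1:3, 8:10])
  expect_gt(adj, far)
})
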