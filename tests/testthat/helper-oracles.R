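# Shared fixtures and independent oracles used across the test files.
# All fixtures are generated in code; all oracles are brute-force or
# third-party implementations independent of the package's own code
# paths.

mc <- asNamespace("morphclade")

# random token matrix with optional ambiguity
rand_tokens <- function(ntax, nchr, k = 2, p_unknown = 0, p_inapp = 0,
                        p_poly = 0) {
  tok <- matrix(as.character(sample(0:(k - 1), ntax * nchr, TRUE)),
                ntax, nchr)
  ncell <- length(tok)
  pick <- sample(ncell)
  nu <- round(p_unknown * ncell); ni <- round(p_inapp * ncell)
  np <- round(p_poly * ncell)
  if (nu) tok[pick[seq_len(nu)]] <- "?"
  if (ni) tok[pick[nu + seq_len(ni)]] <- "-"
  if (np && k >= 2) {
    for (cell in pick[nu + ni + seq_len(np)]) {
      ss <- sort(sample(0:(k - 1), 2))
      tok[cell] <- paste0("{", ss[1], ss[2], "}")
    }
  }
  rownames(tok) <- paste0("t", seq_len(ntax))
  tok
}

# exact minimum changes for one character by enumerating every ancestral
# assignment (leaves restricted to their allowed sets)
brute_fitch_char <- function(tr, m, char) {
  M <- length(tr$parent)
  n <- tr$nleaf
  allst <- mc$mask_to_states(m$full_mask[char])
  leafsets <- lapply(seq_len(n), function(i)
    mc$mask_to_states(m$masks[tr$tips[i], char]))
  grids <- c(leafsets, rep(list(allst), M - n))
  combos <- do.call(expand.grid, grids)
  children <- which(tr$parent > 0L)
  cost <- rep(0L, nrow(combos))
  for (v in children)
    cost <- cost + (combos[[v]] != combos[[tr$parent[v]]])
  min(cost)
}

# per-edge change statistics over all most-parsimonious reconstructions,
# by the same enumeration
brute_edge_stats <- function(tr, m, char) {
  M <- length(tr$parent)
  n <- tr$nleaf
  allst <- mc$mask_to_states(m$full_mask[char])
  leafsets <- lapply(seq_len(n), function(i)
    mc$mask_to_states(m$masks[tr$tips[i], char]))
  grids <- c(leafsets, rep(list(allst), M - n))
  combos <- do.call(expand.grid, grids)
  children <- which(tr$parent > 0L)
  cost <- rep(0L, nrow(combos))
  for (v in children)
    cost <- cost + (combos[[v]] != combos[[tr$parent[v]]])
  opt <- combos[cost == min(cost), , drop = FALSE]
  ch <- vapply(children, function(v)
    as.numeric(opt[[v]] != opt[[tr$parent[v]]]), numeric(nrow(opt)))
  if (is.null(dim(ch))) ch <- matrix(ch, nrow = 1)
  list(steps = min(cost), emin = apply(ch, 2, min),
       emax = apply(ch, 2, max), efrac = colMeans(ch),
       children = children)
}

# random rooted binary tree over the taxa of a matrix
rand_tree <- function(m) ape::rtree(length(m$taxa), tip.label = m$taxa,
                                    br = NULL)

# six-taxon matrix of perfectly nested synapomorphies; true unrooted
# topology is the caterpillar (((((t1,t2),t3),t4),t5),t6)
clean_hierarchy_matrix <- function() {
  tok <- rbind(t1 = c("1", "1", "1", "1"),
               t2 = c("1", "1", "1", "0"),
               t3 = c("1", "1", "0", "0"),
               t4 = c("1", "0", "0", "0"),
               t5 = c("0", "0", "0", "0"),
               t6 = c("0", "0", "0", "0"))
  morph_matrix(tok)
}

clean_hierarchy_tree <- function()
  ape::read.tree(text = "(((((t1,t2),t3),t4),t5),t6);")

demo_path <- function(f) system.file("extdata", f, package = "morphclade")

# study-profile strong-signal recovery configuration (see the methods
# vignette): 20 taxa, 3x the study's per-category character counts,
# state-rich characters, expected ~12 changes per internal branch
strong_signal_config <- function(n_taxa = 20L)
  sim_config(n_taxa = n_taxa,
             n_char_by_category = c(architectural = 75L,
                                    wall_structure = 24L,
                                    external_topography = 54L,
                                    cellular = 60L,
                                    pollination = 54L),
             state_count_probs = c(`2` = 0.2, `3` = 0.3, `4` = 0.3,
                                   `5` = 0.2),
             rate = 0.045, brlen_mean = 0.5, brlen_min = 1,
             pct_unknown = 0, pct_inapplicable = 0, pct_polymorphic = 0)

# exhaustive decay-index oracle: for every bipartition of the strict
# consensus of the MPTs, the smallest extra length of a tree lacking it
enumeration_bremer <- function(m, max_k = 3L) {
  ex <- exhaustive_search(m, all = TRUE)
  taxa_sorted <- sort(m$taxa)
  keysets <- lapply(ex$all_trees, function(t)
    vapply(mc$tree_biparts(t, taxa_sorted, 1L), mc$clade_key, character(1)))
  L <- min(ex$all_lengths)
  sc0 <- Reduce(intersect, keysets[ex$all_lengths == L])
  out <- stats::setNames(integer(length(sc0)), sc0)
  for (key in sc0) {
    lacking <- ex$all_lengths[!vapply(keysets, function(k) key %in% k,
                                      logical(1))]
    out[key] <- if (length(lacking)) min(lacking) - L else max_k
  }
  out
}
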