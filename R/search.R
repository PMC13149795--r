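# Heuristic and exhaustive maximum-parsimony tree search.
#
# The search works on unrooted binary trees stored as integer edge
# matrices (leaf ids = taxon indices, internal ids above ntax), scored by
# the C Fitch/Hartigan kernel.  Strategy mirrors a classic "traditional
# search": seeded random-addition starting trees, tree
# bisection-reconnection (TBR) branch swapping accepting equal-or-better
# trees up to a hold limit, merging replicates, filtering to the global
# minimum, collapsing unsupported branches and deduplicating by
# bipartition set.

# star tree on the first three taxa of `ord`, then insert the rest at the
# attachment point minimising total length (ties broken by the current RNG)
random_addition_edges <- function(masksT, ntax, ord) {
  hub <- ntax + 1L
  E <- cbind(ord[1:3], hub)
  nexti <- ntax + 2L
  for (i in seq_len(ntax)[-(1:3)]) {
    x <- ord[i]
    w <- nexti
    scores <- vapply(seq_len(nrow(E)), function(k) {
      cand <- rbind(E[-k, , drop = FALSE],
                    c(E[k, 1L], w), c(w, E[k, 2L]), c(w, x))
      fitch_edges(cand, masksT)
    }, integer(1))
    ks <- which(scores == min(scores))
    k <- if (length(ks) > 1L) ks[sample.int(length(ks), 1L)] else ks
    E <- rbind(E[-k, , drop = FALSE],
               c(E[k, 1L], w), c(w, E[k, 2L]), c(w, x))
    nexti <- nexti + 1L
  }
  E
}

#' Random-addition starting tree
#'
#' Builds a tree by adding taxa in seeded-random order, each at the
#' attachment point minimising total parsimony length (greedy stepwise
#' addition, as used to start each search replicate).
#'
#' @param m a [morph_matrix()].
#' @param seed integer seed (set before drawing the addition order).
#' @return an `ape::phylo` tree rooted on the first taxon's pendant edge.
#' @export
random_addition_tree <- function(m, seed = 1L) {
  if (length(m$taxa) < 3L) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  masksT <- tmasks(m)
  ntax <- length(m$taxa)
  E <- random_addition_edges(masksT, ntax, sample.int(ntax))
  edges_to_phylo(E, ntax, m$taxa)
}

# connected component containing `from` after deleting edge row `k`
edge_side <- function(E, k, from, nnode_max) {
  inx <- logical(nnode_max)
  inx[from] <- TRUE
  repeat {
    hit <- (inx[E[, 1L]] | inx[E[, 2L]])
    hit[k] <- FALSE
    new_nodes <- unique(c(E[hit, 1L], E[hit, 2L]))
    if (all(inx[new_nodes])) break
    inx[new_nodes] <- TRUE
  }
  inx
}

# call visit(newE) for every TBR neighbour; stop early if visit() returns TRUE
tbr_scan <- function(E, ntax, visit) {
  ne <- nrow(E)
  mx <- max(E)
  for (k in seq_len(ne)) {
    x <- E[k, 1L]; y <- E[k, 2L]
    if (x > ntax && y > ntax) {
      side_x <- edge_side(E, k, x, mx)
      rows_x <- which(seq_len(ne) != k & side_x[E[, 1L]])
      rows_y <- setdiff(which(seq_len(ne) != k), rows_x)
      inc_x <- rows_x[E[rows_x, 1L] == x | E[rows_x, 2L] == x]
      inc_y <- rows_y[E[rows_y, 1L] == y | E[rows_y, 2L] == y]
      ab <- setdiff(as.vector(E[inc_x, ]), x)
      cd <- setdiff(as.vector(E[inc_y, ]), y)
      P1 <- rbind(E[setdiff(rows_x, inc_x), , drop = FALSE], ab)
      P2 <- rbind(E[setdiff(rows_y, inc_y), , drop = FALSE], cd)
      n1 <- nrow(P1); n2 <- nrow(P2)
      for (i1 in seq_len(n1)) for (i2 in seq_len(n2)) {
        if (i1 == n1 && i2 == n2) next       # reproduces the original tree
        nE <- rbind(P1[-i1, , drop = FALSE],
                    c(P1[i1, 1L], x), c(x, P1[i1, 2L]),
                    P2[-i2, , drop = FALSE],
                    c(P2[i2, 1L], y), c(y, P2[i2, 2L]),
                    c(x, y))
        if (isTRUE(visit(nE))) return(invisible(TRUE))
      }
    } else {
      leaf <- if (x <= ntax) x else y
      hub <- if (x <= ntax) y else x
      if (hub <= ntax) next                   # two-taxon tree
      inc <- which(seq_len(ne) != k & (E[, 1L] == hub | E[, 2L] == hub))
      cd <- setdiff(as.vector(E[inc, ]), hub)
      P <- rbind(E[setdiff(seq_len(ne), c(k, inc)), , drop = FALSE], cd)
      np <- nrow(P)
      for (i in seq_len(np)) {
        if (i == np) next                     # reproduces the original tree
        nE <- rbind(P[-i, , drop = FALSE],
                    c(P[i, 1L], hub), c(hub, P[i, 2L]),
                    c(leaf, hub))
        if (isTRUE(visit(nE))) return(invisible(TRUE))
      }
    }
  }
  invisible(FALSE)
}

# TBR hill-climb with plateau (or suboptimality-band) exploration.
# Keeps up to `hold` trees with length <= best + band, exploring the TBR
# neighbourhood of each held tree until closure or `max_explore` trees
# have been expanded.
search_core <- function(E0, masksT, ntax, hold = 20L, band = 0L,
                        max_explore = Inf) {
  if (is.matrix(E0)) E0 <- list(E0)
  lens0 <- vapply(E0, fitch_edges, integer(1), masks = masksT)
  keys0 <- vapply(E0, edges_key, character(1), ntax = ntax)
  dup <- duplicated(keys0)
  E0 <- E0[!dup]; lens0 <- lens0[!dup]; keys0 <- keys0[!dup]
  st <- new.env(parent = emptyenv())
  st$best <- min(lens0)
  keep <- lens0 <= st$best + band
  st$E <- E0[keep]
  st$len <- lens0[keep]
  st$keys <- keys0[keep]
  st$open <- seq_along(st$E)
  st$restart <- FALSE
  explored <- 0L

  visit <- function(nE) {
    len <- fitch_edges(nE, masksT)
    if (len < st$best) {
      st$best <- len
      keep <- st$len <= len + band
      st$E <- c(st$E[keep], list(nE))
      st$len <- c(st$len[keep], len)
      st$keys <- c(st$keys[keep], edges_key(nE, ntax))
      st$open <- seq_along(st$E)
      st$restart <- TRUE
      return(TRUE)
    }
    if (len <= st$best + band && length(st$E) < hold) {
      key <- edges_key(nE, ntax)
      if (!(key %in% st$keys)) {
        st$E <- c(st$E, list(nE))
        st$len <- c(st$len, len)
        st$keys <- c(st$keys, key)
        st$open <- c(st$open, length(st$E))
      }
    }
    FALSE
  }

  while (length(st$open) && explored < max_explore) {
    i <- st$open[1L]
    st$open <- st$open[-1L]
    st$restart <- FALSE
    tbr_scan(st$E[[i]], ntax, visit)
    explored <- explored + 1L
  }
  list(best = st$best, E = st$E, len = st$len, keys = st$keys)
}

#' Heuristic maximum-parsimony search
#'
#' Replicated random-addition + TBR branch-swapping search.  Each
#' replicate starts from a seeded random-addition tree and swaps until no
#' TBR move improves the tree, holding up to `hold` equally parsimonious
#' trees.  Replicate results are merged, filtered to the global minimum
#' length, collapsed under the chosen zero-length-branch rule, and
#' deduplicated by bipartition set.
#'
#' @param m a [morph_matrix()].
#' @param replicates number of random-addition replicates.
#' @param hold maximum trees held per replicate.
#' @param seed integer seed; the whole search is reproducible given
#'   (matrix, configuration, seed).
#' @param collapse zero-length branch rule: `"max_zero"` collapses a
#'   branch whose maximum length over all most-parsimonious
#'   reconstructions is zero, `"min_zero"` collapses when the minimum is
#'   zero, `"none"` keeps all branches.
#' @param outgroup taxon label used to root reported trees (default: the
#'   first taxon of the matrix).
#' @param max_trees cap on the total number of distinct trees returned.
#' @param max_explore cap on the number of held trees whose TBR
#'   neighbourhood is expanded per replicate (`Inf` = run to closure).
#' @param verbose print per-replicate progress.
#' @return an object of class `mp_search`: a list with `trees` (a
#'   `multiPhylo` of distinct most-parsimonious trees), `length`, `fit`
#'   (ensemble CI/RI), and the search configuration.
#' @export
mp_search <- function(m, replicates = 50L, hold = 20L, seed = 1L,
                      collapse = c("max_zero", "min_zero", "none"),
                      outgroup = m$taxa[1L], max_trees = 1000L,
                      max_explore = Inf, verbose = FALSE) {
  collapse <- match.arg(collapse)
  if (!is.null(seed)) set.seed(seed)
  masksT <- tmasks(m)
  ntax <- length(m$taxa)
  og <- match(outgroup, m$taxa)
  if (is.na(og)) stop("outgroup not a matrix taxon: ", outgroup)

  all_E <- list(); all_len <- integer(0)
  for (r in seq_len(replicates)) {
    E0 <- random_addition_edges(masksT, ntax, sample.int(ntax))
    res <- search_core(E0, masksT, ntax, hold = hold,
                       max_explore = max_explore)
    keep <- res$len == res$best
    all_E <- c(all_E, res$E[keep])
    all_len <- c(all_len, res$len[keep])
    if (verbose)
      message(sprintf("replicate %d: best length %d, held %d",
                      r, res$best, sum(keep)))
  }
  best <- min(all_len)
  cand <- all_E[all_len == best]
  bkeys <- vapply(cand, edges_key, character(1), ntax = ntax)
  cand <- cand[!duplicated(bkeys)]
  ptrees <- lapply(cand, edges_to_ptree, ntax = ntax, og = og)
  if (collapse != "none")
    ptrees <- lapply(ptrees, collapse_ptree, m = m, rule = collapse)
  keys <- vapply(ptrees, function(tr)
    paste(sort.int(ptree_bipartitions(tr)), collapse = ";"), character(1))
  ptrees <- ptrees[!duplicated(keys)]
  if (length(ptrees) > max_trees) ptrees <- ptrees[seq_len(max_trees)]
  trees <- lapply(ptrees, ptree_to_phylo, taxa = m$taxa)
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, length = best, n_trees = length(trees),
                 binary_edges = cand,
                 config = list(replicates = replicates, hold = hold,
                               seed = seed, collapse = collapse,
                               outgroup = outgroup,
                               max_explore = max_explore)),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat("Maximum-parsimony search: ", x$n_trees, " tree(s) of length ",
      x$length, "\n", sep = "")
  cat("  (", x$config$replicates, " replicates, hold ", x$config$hold,
      ", seed ", x$config$seed, ", collapse ", x$config$collapse, ")\n",
      sep = "")
  invisible(x)
}

#' Collapse zero-length branches
#'
#' Collapses internal branches of a binary tree whose length is zero
#' under the chosen reading: `"max_zero"` (default) collapses a branch
#' only when *no* most-parsimonious reconstruction places a change on it;
#' `"min_zero"` collapses whenever *some* reconstruction leaves it
#' changeless.
#'
#' @param tree an `ape::phylo` tree.
#' @param m a [morph_matrix()].
#' @param rule `"max_zero"` or `"min_zero"`.
#' @return an `ape::phylo` tree, possibly with polytomies.
#' @export
collapse_branches <- function(tree, m, rule = c("max_zero", "min_zero")) {
  rule <- match.arg(rule)
  tr <- as_ptree(tree, m)
  ptree_to_phylo(collapse_ptree(tr, m, rule), m$taxa)
}

collapse_ptree <- function(tr, m, rule = c("max_zero", "min_zero")) {
  rule <- match.arg(rule)
  mp <- map_characters(tr, m)
  tot <- colSums(if (rule == "max_zero") mp$edge_max else mp$edge_min)
  root <- ptree_root(tr)
  v <- mp$children
  rootkids <- which(tr$parent == root)
  deg2 <- length(rootkids) == 2L
  # a child edge is a true unrooted internal edge unless it hangs off a
  # degree-2 root (there the two root edges jointly subdivide one edge,
  # and a single change can sit on either half)
  drop <- v[v > tr$nleaf & tot < 1e-9 & (tr$parent[v] != root | !deg2)]
  if (deg2) {
    ik <- rootkids[rootkids > tr$nleaf]
    if (length(ik) == 2L) {      # joint stats of the subdivided edge
      g1 <- mp$g[[ik[1L]]]; g2 <- mp$g[[ik[2L]]]
      steps <- mp$steps
      zero_ok <- rowmin(g1 + g2) <= steps + 1e-9
      min1 <- rowmin(g1)
      cnt1 <- rowSums(abs(g1 - min1) < 1e-9)
      A2 <- g1; A2[abs(g1 - min1) < 1e-9] <- INF
      min2 <- rowmin(A2)
      cross <- rep(INF, length(steps))
      for (t in seq_len(ncol(g1))) {
        excl <- ifelse(abs(g1[, t] - min1) < 1e-9 & cnt1 == 1L, min2, min1)
        cross <- pmin(cross, g2[, t] + excl)
      }
      change_ok <- cross + 1 <= steps + 1e-9
      tot_root <- if (rule == "max_zero") sum(change_ok) else sum(!zero_ok)
      if (tot_root < 1e-9) drop <- c(drop, ik)
    }
  }
  ptree_collapse(tr, unique(drop))
}

ptree_collapse <- function(tr, drop) {
  if (!length(drop)) return(tr)
  stopifnot(all(drop > tr$nleaf), !ptree_root(tr) %in% drop)
  par <- tr$parent
  newpar <- par
  for (v in seq_along(par)) {
    if (v %in% drop || par[v] == 0L) next
    p <- par[v]
    while (p %in% drop) p <- par[p]
    newpar[v] <- p
  }
  keep <- setdiff(seq_along(par), drop)
  map <- integer(length(par))
  map[keep] <- seq_along(keep)
  np <- newpar[keep]
  parent2 <- integer(length(keep))
  nz <- np > 0L
  parent2[nz] <- map[np[nz]]
  new_ptree(parent2, tr$nleaf, tr$tips, tr$ntax, tr$labels)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology (feasible up to 9 taxa:
#' 135,135 topologies) and returns all trees of globally minimal length.
#' Intended as an oracle against which the heuristic search is validated.
#'
#' @param m a [morph_matrix()] with at most 9 taxa.
#' @param all also return every topology with its length (at most 8
#'   taxa), for decay-index oracles.
#' @return a list with `trees` (`multiPhylo`), `length`, `n_topologies`;
#'   with `all = TRUE` also `all_trees` and `all_lengths`.
#' @export
exhaustive_search <- function(m, all = FALSE) {
  ntax <- length(m$taxa)
  if (ntax < 3L) stop("need at least 3 taxa")
  if (ntax > 9L) stop("refusing exhaustive search beyond 9 taxa")
  if (all && ntax > 8L) stop("all-topology return capped at 8 taxa")
  masksT <- tmasks(m)

  results <- new.env(parent = emptyenv())
  results$best <- Inf
  results$E <- list()
  results$all_E <- if (all) list() else NULL
  results$all_len <- integer(0)
  results$count <- 0L

  recurse <- function(E, nexttax, nexti) {
    if (nexttax > ntax) {
      len <- fitch_edges(E, masksT)
      results$count <- results$count + 1L
      if (all) {
        results$all_E[[results$count]] <- E
        results$all_len[results$count] <- len
      }
      if (len < results$best) {
        results$best <- len
        results$E <- list(E)
      } else if (len == results$best) {
        results$E <- c(results$E, list(E))
      }
      return(invisible(NULL))
    }
    for (k in seq_len(nrow(E))) {
      cand <- rbind(E[-k, , drop = FALSE],
                    c(E[k, 1L], nexti), c(nexti, E[k, 2L]),
                    c(nexti, nexttax))
      recurse(cand, nexttax + 1L, nexti + 1L)
    }
    invisible(NULL)
  }
  E0 <- cbind(1:3, ntax + 1L)
  recurse(E0, 4L, ntax + 2L)

  trees <- lapply(results$E, edges_to_phylo, ntax = ntax, taxa = m$taxa)
  class(trees) <- "multiPhylo"
  out <- list(trees = trees, length = results$best,
              n_topologies = results$count)
  if (all) {
    at <- lapply(results$all_E, edges_to_phylo, ntax = ntax, taxa = m$taxa)
    class(at) <- "multiPhylo"
    out$all_trees <- at
    out$all_lengths <- results$all_len
  }
  out
}
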