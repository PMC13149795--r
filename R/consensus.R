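# Consensus trees and branch support (bootstrap, Bremer).

# canonical informative bipartitions of a tree: the side of each internal
# edge NOT containing the outgroup taxon, as sorted taxon-id vectors
canonical_biparts <- function(tr, og_id) {
  below <- ptree_clades(tr)
  root <- ptree_root(tr)
  allt <- below[[root]]
  nt <- length(allt)
  sets <- below[setdiff(which(seq_along(below) > tr$nleaf), root)]
  sets <- lapply(sets, function(s)
    if (og_id %in% s) setdiff(allt, s) else s)
  sets <- sets[vapply(sets, length, integer(1)) >= 2L &
               vapply(sets, length, integer(1)) <= nt - 2L]
  keys <- vapply(sets, clade_key, character(1))
  sets[!duplicated(keys)]
}

tree_biparts <- function(tree, taxa, og_id) {
  tr <- if (inherits(tree, "ptree")) tree else phylo_to_ptree(tree, taxa)
  canonical_biparts(tr, og_id)
}

# build a rooted multifurcating tree from a compatible clade list
build_from_clades <- function(clades, taxa_present, og_id, taxa) {
  ord <- order(-lengths(clades))
  clades <- clades[ord]
  L <- length(taxa_present)
  nclade <- length(clades)
  owner <- integer(max(taxa_present))          # 0 = root
  parent <- integer(L + 1L + nclade)
  root <- L + 1L
  for (i in seq_len(nclade)) {
    node <- L + 1L + i
    ow <- owner[clades[[i]][1L]]
    parent[node] <- if (ow == 0L) root else ow
    owner[clades[[i]]] <- node
  }
  tips <- sort.int(taxa_present)
  for (j in seq_len(L)) {
    ow <- owner[tips[j]]
    parent[j] <- if (ow == 0L) root else ow
  }
  parent[root] <- 0L
  new_ptree(parent, L, tips, length(taxa))
}

as_tree_list <- function(trees) {
  if (inherits(trees, "mp_search")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees
}

consensus_core <- function(trees, taxa, og_id, cutoff = NULL) {
  labs <- lapply(trees, function(t)
    if (inherits(t, "phylo")) t$tip.label else taxa[t$tips])
  if (length(unique(lapply(labs, function(x) paste(sort.int(x), collapse = "\r")))) != 1L)
    stop("trees do not share a common leaf set")
  leafsets <- lapply(labs, function(x) sort.int(match(x, taxa)))
  sets <- lapply(trees, tree_biparts, taxa = taxa, og_id = og_id)
  keysets <- lapply(sets, function(s) vapply(s, clade_key, character(1)))
  all_keys <- unlist(keysets, use.names = FALSE)
  all_sets <- unlist(sets, recursive = FALSE, use.names = FALSE)
  counts <- table(all_keys)
  keep_keys <- if (is.null(cutoff)) {
    names(counts)[counts == length(trees)]
  } else {
    names(counts)[counts > length(trees) * cutoff / 100]
  }
  chosen <- all_sets[match(keep_keys, all_keys)]
  build_from_clades(chosen, leafsets[[1L]], og_id, taxa)
}

#' Strict consensus tree
#'
#' The strict consensus contains exactly the bipartitions present in
#' every input tree; clades on which the trees disagree collapse to
#' polytomies.
#'
#' @param trees a list of `phylo` trees, a `multiPhylo`, or an
#'   [mp_search()] result.
#' @param outgroup taxon label used to orient bipartitions and root the
#'   result (default: first tip of the first tree, alphabetical taxa
#'   ordering).
#' @return an `ape::phylo` tree, possibly with polytomies.
#' @export
strict_consensus <- function(trees, outgroup = NULL) {
  trees <- as_tree_list(trees)
  taxa <- sort.int(trees[[1L]]$tip.label)
  og <- if (is.null(outgroup)) match(trees[[1L]]$tip.label[1L], taxa)
        else match(outgroup, taxa)
  if (is.na(og)) stop("outgroup not among tree tips")
  ptree_to_phylo(consensus_core(trees, taxa, og), taxa)
}

#' Majority-rule consensus tree
#'
#' Contains the bipartitions occurring in more than `cutoff` percent of
#' the input trees (strict majority: a clade in exactly half the trees
#' is excluded).  Cutoffs below 50 are refused, since compatibility of
#' the retained bipartitions is then no longer guaranteed.
#'
#' @inheritParams strict_consensus
#' @param cutoff percentage threshold, at least 50.
#' @return an `ape::phylo` tree, possibly with polytomies.
#' @export
majority_consensus <- function(trees, cutoff = 50, outgroup = NULL) {
  if (cutoff < 50) stop("majority-rule cutoff below 50% is not supported")
  trees <- as_tree_list(trees)
  taxa <- sort.int(trees[[1L]]$tip.label)
  og <- if (is.null(outgroup)) match(trees[[1L]]$tip.label[1L], taxa)
        else match(outgroup, taxa)
  if (is.na(og)) stop("outgroup not among tree tips")
  ptree_to_phylo(consensus_core(trees, taxa, og, cutoff = cutoff), taxa)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the bipartitions present in one tree but not the other
#' (symmetric difference); 0 means identical unrooted topologies.
#'
#' @param t1,t2 `ape::phylo` trees on the same tips.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  taxa <- sort.int(t1$tip.label)
  og <- 1L
  k1 <- vapply(tree_biparts(t1, taxa, og), clade_key, character(1))
  k2 <- vapply(tree_biparts(t2, taxa, og), clade_key, character(1))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# subset a morph_matrix to a set of character columns (with repeats, as
# in a bootstrap pseudoreplicate)
morph_subset_chars <- function(m, idx) {
  m$masks <- m$masks[, idx, drop = FALSE]
  m$kind <- m$kind[, idx, drop = FALSE]
  m$full_mask <- m$full_mask[idx]
  m$n_states <- m$n_states[idx]
  m$char_labels <- make.unique(m$char_labels[idx])
  if (!is.null(m$category)) m$category <- m$category[idx]
  m
}

#' Bootstrap branch support
#'
#' Resamples characters with replacement, runs a reduced heuristic
#' search on each pseudoreplicate, and records the bipartitions of the
#' pseudoreplicate's strict consensus.  Support for a bipartition is the
#' percentage of pseudoreplicates whose consensus contains it.
#'
#' @param m a [morph_matrix()].
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates.
#' @param seed integer seed.
#' @param replicates,hold,max_explore reduced search profile used within
#'   each pseudoreplicate.
#' @param outgroup taxon label orienting bipartitions.
#' @return a data frame of class `support_table` with columns `key`
#'   (sorted taxon indices), `clade` (taxon labels), `n_taxa` and
#'   `bootstrap` (percent).
#' @export
bootstrap_support <- function(m, n_pseudoreplicates = 200L, seed = 1L,
                              replicates = 2L, hold = 10L, max_explore = 20L,
                              outgroup = m$taxa[1L]) {
  if (!is.null(seed)) set.seed(seed)
  ntax <- length(m$taxa)
  nchr <- length(m$char_labels)
  og <- match(outgroup, m$taxa)
  tally <- new.env(parent = emptyenv())
  for (b in seq_len(n_pseudoreplicates)) {
    mb <- morph_subset_chars(m, sample.int(nchr, nchr, replace = TRUE))
    masksT <- tmasks(mb)
    all_E <- list(); all_len <- integer(0)
    for (r in seq_len(replicates)) {
      E0 <- random_addition_edges(masksT, ntax, sample.int(ntax))
      res <- search_core(E0, masksT, ntax, hold = hold,
                         max_explore = max_explore)
      keep <- res$len == res$best
      all_E <- c(all_E, res$E[keep])
      all_len <- c(all_len, res$len[keep])
    }
    cand <- all_E[all_len == min(all_len)]
    ptrees <- lapply(cand, edges_to_ptree, ntax = ntax, og = og)
    cons <- consensus_core(ptrees, m$taxa, og)
    for (s in canonical_biparts(cons, og)) {
      key <- clade_key(s)
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    }
  }
  keys <- ls(tally)
  pct <- vapply(keys, function(k) 100 * tally[[k]] / n_pseudoreplicates,
                numeric(1))
  ids <- lapply(strsplit(keys, ","), as.integer)
  out <- data.frame(key = keys,
                    clade = vapply(ids, function(i)
                      paste(m$taxa[i], collapse = ", "), character(1)),
                    label_key = vapply(ids, function(i)
                      paste(sort(m$taxa[i]), collapse = "|"), character(1)),
                    n_taxa = lengths(ids),
                    bootstrap = unname(pct),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$bootstrap), ]
  class(out) <- c("support_table", "data.frame")
  out
}

#' Bremer (decay) branch support
#'
#' Runs a suboptimal-retention sweep: starting from the
#' most-parsimonious trees, TBR search retains every distinct tree
#' within `max_k` steps of the minimum length.  A bipartition's Bremer
#' value is the smallest k at which it vanishes from the strict
#' consensus of all retained trees of length <= minimum + k; values
#' never vanishing by `max_k` are censored (reported as `max_k` with
#' `censored = TRUE`).
#'
#' @param m a [morph_matrix()].
#' @param mpts an [mp_search()] result (or list of equally parsimonious
#'   `phylo` trees).
#' @param max_k largest suboptimality band swept.
#' @param hold cap on retained trees during the sweep.
#' @param max_explore cap on neighbourhood expansions (`Inf` = closure).
#' @param outgroup taxon label orienting bipartitions.
#' @return a data frame of class `support_table` with columns `key`,
#'   `clade`, `n_taxa`, `bremer`, `censored`.
#' @export
bremer_support <- function(m, mpts, max_k = 3L, hold = 5000L,
                           max_explore = Inf, outgroup = m$taxa[1L]) {
  ntax <- length(m$taxa)
  og <- match(outgroup, m$taxa)
  masksT <- tmasks(m)
  if (inherits(mpts, "mp_search") && !is.null(mpts$binary_edges)) {
    E0s <- mpts$binary_edges      # uncollapsed binary forms of the MPTs
  } else {
    trees <- as_tree_list(mpts)
    if (!all(vapply(trees, ape::is.binary, logical(1))))
      stop("Bremer sweep needs binary (uncollapsed) starting trees")
    E0s <- lapply(trees, phylo_to_edges, taxa = m$taxa)
  }
  res <- search_core(E0s, masksT, ntax, hold = hold, band = max_k,
                     max_explore = max_explore)
  L <- res$best

  keysets <- lapply(res$E, function(E)
    vapply(canonical_biparts(edges_to_ptree(E, ntax, og), og),
           clade_key, character(1)))
  sc0 <- Reduce(intersect, keysets[res$len == L])
  if (!length(sc0)) {
    out <- data.frame(key = character(0), clade = character(0),
                      n_taxa = integer(0), bremer = integer(0),
                      censored = logical(0))
    class(out) <- c("support_table", "data.frame")
    return(out)
  }
  bremer <- rep(NA_integer_, length(sc0))
  for (k in seq_len(max_k)) {
    sck <- Reduce(intersect, keysets[res$len <= L + k])
    gone <- is.na(bremer) & !(sc0 %in% sck)
    bremer[gone] <- k
  }
  censored <- is.na(bremer)
  bremer[censored] <- max_k
  ids <- lapply(strsplit(sc0, ","), as.integer)
  out <- data.frame(key = sc0,
                    clade = vapply(ids, function(i)
                      paste(m$taxa[i], collapse = ", "), character(1)),
                    label_key = vapply(ids, function(i)
                      paste(sort(m$taxa[i]), collapse = "|"), character(1)),
                    n_taxa = lengths(ids),
                    bremer = bremer, censored = censored,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("support_table", "data.frame")
  out
}
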