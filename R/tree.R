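# Internal tree representations.
#
# Two forms are used:
#  * unrooted binary trees as 2-column integer edge matrices ("E"), with
#    leaf node ids equal to taxon indices (1..ntax, possibly a subset) and
#    internal nodes numbered above ntax.  This is the form the heuristic
#    search manipulates.
#  * rooted, polytomy-capable trees as parent vectors ("ptree"): nodes
#    1..nleaf are tips (tips[i] = taxon index of tip slot i), parent of the
#    root is 0.  This is the form consensus, mapping and time-scaling use.
#
# User-facing functions take and return ape "phylo" objects; conversion
# happens at the boundary.

new_ptree <- function(parent, nleaf, tips, ntax, labels = NULL) {
  structure(list(parent = as.integer(parent), nleaf = as.integer(nleaf),
                 tips = as.integer(tips), ntax = as.integer(ntax),
                 labels = labels),
            class = "ptree")
}

ptree_root <- function(tr) which(tr$parent == 0L)

ptree_children <- function(tr) {
  M <- length(tr$parent)
  kids <- vector("list", M)
  idx <- which(tr$parent > 0L)
  sp <- split(idx, tr$parent[idx])
  kids[as.integer(names(sp))] <- sp
  kids
}

# internal nodes in an order where children precede parents
ptree_postorder <- function(tr) {
  M <- length(tr$parent)
  kids <- ptree_children(tr)
  root <- ptree_root(tr)
  stack <- integer(M); po <- integer(M)
  top <- 1L; stack[1L] <- root; k <- M
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    po[k] <- v; k <- k - 1L
    for (ch in kids[[v]]) { top <- top + 1L; stack[top] <- ch }
  }
  po
}

# taxon-id sets below every node (list indexed by node id)
ptree_clades <- function(tr) {
  M <- length(tr$parent)
  below <- vector("list", M)
  for (i in seq_len(tr$nleaf)) below[[i]] <- tr$tips[i]
  po <- ptree_postorder(tr)
  kids <- ptree_children(tr)
  for (v in po) {
    if (v > tr$nleaf || length(kids[[v]]))
      below[[v]] <- sort.int(unique.default(
        c(if (v <= tr$nleaf) tr$tips[v],
          unlist(below[kids[[v]]], use.names = FALSE))))
  }
  below
}

clade_key <- function(ids) paste(ids, collapse = ",")

# informative bipartitions of a rooted-at-outgroup tree, as canonical keys
# (the side not containing the outgroup taxon)
ptree_bipartitions <- function(tr) {
  below <- ptree_clades(tr)
  root <- ptree_root(tr)
  nt <- length(below[[root]])
  keep <- vapply(seq_along(below), function(v) {
    v != root && v > tr$nleaf &&
      length(below[[v]]) >= 2L && length(below[[v]]) <= nt - 2L
  }, logical(1))
  vapply(below[keep], clade_key, character(1))
}

# --- edge-matrix (unrooted, binary) helpers ---------------------------------

# orient an edge matrix and score it; masks is the nchar x ntax bitmask
# matrix.  what: 0 total steps, 1 per-character steps.
fitch_edges <- function(E, masks, what = 0L) {
  nodes <- sort.int(unique.default(as.vector(E)))
  M <- length(nodes)
  ntax <- ncol(masks)
  if (nodes[M] == M) {               # dense numbering: full tree fast path
    nleaf <- sum(nodes <= ntax)
    tips <- seq_len(nleaf)
    E2 <- E
  } else {
    leaf_ids <- nodes[nodes <= ntax]
    int_ids <- nodes[nodes > ntax]
    map <- integer(nodes[M])
    map[leaf_ids] <- seq_along(leaf_ids)
    map[int_ids] <- length(leaf_ids) + seq_along(int_ids)
    E2 <- cbind(map[E[, 1L]], map[E[, 2L]])
    nleaf <- length(leaf_ids)
    tips <- leaf_ids
  }
  parent <- .Call(C_orient, E2, M, 1L)
  .Call(C_fitch, parent, nleaf, masks, as.integer(tips), as.integer(what))
}

# root an unrooted edge matrix on the pendant edge of taxon `og`,
# producing a binary ptree whose root has the outgroup tip as one child
edges_to_ptree <- function(E, ntax, og = 1L, labels = NULL) {
  nodes <- sort.int(unique.default(as.vector(E)))
  leaf_ids <- nodes[nodes <= ntax]
  int_ids <- nodes[nodes > ntax]
  nleaf <- length(leaf_ids)
  M <- nleaf + length(int_ids) + 1L     # + new root
  map <- integer(max(nodes))
  map[leaf_ids] <- seq_along(leaf_ids)
  map[int_ids] <- nleaf + seq_along(int_ids)
  rootid <- M
  E2 <- cbind(map[E[, 1L]], map[E[, 2L]])
  og_slot <- map[og]
  if (og_slot == 0L) stop("outgroup taxon not present in tree")
  hit <- which(E2[, 1L] == og_slot | E2[, 2L] == og_slot)
  if (length(hit) != 1L) stop("outgroup tip is not a pendant node")
  other <- setdiff(E2[hit, ], og_slot)
  E2 <- rbind(E2[-hit, , drop = FALSE],
              c(og_slot, rootid), c(other, rootid))
  parent <- .Call(C_orient, E2, M, rootid)
  new_ptree(parent, nleaf, leaf_ids, ntax, labels)
}

# drop the (degree-2) root of a binary ptree, returning an edge matrix in
# taxon/internal numbering
ptree_to_edges <- function(tr) {
  M <- length(tr$parent)
  id <- integer(M)
  id[seq_len(tr$nleaf)] <- tr$tips
  ints <- seq.int(tr$nleaf + 1L, M)
  id[ints] <- tr$ntax + seq_along(ints)
  rk <- ptree_root(tr)
  child <- which(tr$parent > 0L)
  E <- cbind(id[tr$parent[child]], id[child])
  kids <- which(tr$parent == rk)
  if (length(kids) == 2L) {       # splice out the degree-2 root
    E <- E[E[, 1L] != id[rk], , drop = FALSE]
    E <- rbind(E, c(id[kids[1L]], id[kids[2L]]))
  }
  E
}

# --- ape interop ------------------------------------------------------------

#' Convert an internal tree to an ape \code{phylo} object
#'
#' @param tr internal tree representation
#' @param taxa character vector of taxon labels (indexed by taxon id)
#' @return an object of class \code{phylo}
#' @noRd
ptree_to_phylo <- function(tr, taxa) {
  M <- length(tr$parent)
  nleaf <- tr$nleaf
  kids <- ptree_children(tr)
  root <- ptree_root(tr)
  # preorder numbering of internal nodes, root first (ape convention)
  renum <- integer(M)
  renum[seq_len(nleaf)] <- seq_len(nleaf)
  nxt <- nleaf + 1L
  stack <- root
  order_pre <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v > nleaf) {
      renum[v] <- nxt; nxt <- nxt + 1L
      stack <- c(kids[[v]], stack)
    }
  }
  idx <- which(tr$parent > 0L)
  edge <- cbind(renum[tr$parent[idx]], renum[idx])
  edge <- edge[order(edge[, 1L], edge[, 2L]), , drop = FALSE]
  phy <- list(edge = edge,
              tip.label = taxa[tr$tips],
              Nnode = M - nleaf)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

# phylo -> ptree, taxon ids resolved against `taxa`
phylo_to_ptree <- function(phy, taxa) {
  tips <- match(phy$tip.label, taxa)
  if (anyNA(tips))
    stop("tree tips not in matrix: ",
         paste(phy$tip.label[is.na(tips)], collapse = ", "))
  n <- length(tips)
  M <- n + phy$Nnode
  parent <- integer(M)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  new_ptree(parent, n, tips, length(taxa))
}

# unrooted edge matrix -> phylo (for returning search results)
edges_to_phylo <- function(E, ntax, taxa, og = 1L) {
  ptree_to_phylo(edges_to_ptree(E, ntax, og), taxa)
}

# phylo (binary, any rooting) -> unrooted edge matrix in taxon numbering
phylo_to_edges <- function(phy, taxa) {
  tr <- phylo_to_ptree(phy, taxa)
  ptree_to_edges(tr)
}

# canonical topology key of an unrooted edge matrix (sorted informative
# bipartition keys, sides chosen away from the smallest taxon present)
edges_key <- function(E, ntax) {
  tr <- edges_to_ptree(E, ntax, og = min(E[E <= ntax]))
  paste(sort.int(ptree_bipartitions(tr)), collapse = ";")
}
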