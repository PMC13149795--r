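# Per-branch character mapping on a fixed (possibly multifurcating) tree.
#
# All quantities derive from the uniform-cost Sankoff dynamic programme
# run down (subtree cost vectors g) and up (rest-of-tree cost vectors R)
# the rooted tree.  For an edge (u = parent, v = child) of a tree whose
# per-character length is m:
#   * the edge can carry 0 changes in some most-parsimonious
#     reconstruction (MPR) iff min_s g_v(s) + R_v(s) == m;
#   * it can carry 1 change iff min_{s != t} g_v(s) + R_v(t) + 1 == m;
#   * the expected number of changes over all MPRs follows from the
#     parallel counting DP (counts normalised per node to avoid overflow;
#     only ratios are used).
# Any single reconstruction places 0 or 1 change of a character on an
# edge, so these bounds are exhaustive.

INF <- 1e7

rowmin <- function(X) do.call(pmin, lapply(seq_len(ncol(X)), function(j) X[, j]))

# number of state columns needed: highest observed state index + 1
# (observed state sets need not be contiguous)
state_dim <- function(m)
  max(vapply(m$full_mask, function(fm) max(mask_to_states(fm)) + 1L,
             integer(1)))

# leaf cost matrix (nchar x kmax): 0 where the state is allowed, INF otherwise
leaf_cost <- function(m, taxon, kmax) {
  out <- matrix(INF, length(m$full_mask), kmax)
  for (s in seq_len(kmax) - 1L) {
    ok <- bitwAnd(m$masks[taxon, ], bitwShiftL(1L, s)) > 0L
    out[ok, s + 1L] <- 0
  }
  out
}

# Down/up Sankoff pass over all characters at once.
# Returns cost vectors, per-edge change bounds and MPR change fractions.
map_characters <- function(tr, m) {
  M <- length(tr$parent)
  nchar <- length(m$full_mask)
  kmax <- state_dim(m)
  kids <- ptree_children(tr)
  po <- ptree_postorder(tr)
  root <- ptree_root(tr)

  g <- h <- vector("list", M)    # subtree cost; through-edge cost
  N <- Hc <- vector("list", M)   # assignment counts; through-edge counts
  for (v in po) {
    if (v <= tr$nleaf) {
      g[[v]] <- leaf_cost(m, tr$tips[v], kmax)
      N[[v]] <- (g[[v]] == 0) * 1
    } else {
      acc <- matrix(0, nchar, kmax)
      accN <- matrix(1, nchar, kmax)
      for (cn in kids[[v]]) {
        acc <- acc + h[[cn]]
        accN <- accN * Hc[[cn]]
      }
      g[[v]] <- acc
      N[[v]] <- accN / pmax(apply(accN, 1L, max), 1e-300)
    }
    mc <- rowmin(g[[v]])
    h[[v]] <- pmin(g[[v]], mc + 1)
    # counts through the edge above v
    Nv <- N[[v]]
    Nmin <- rowSums(Nv * (g[[v]] == mc))
    Hv <- (g[[v]] == h[[v]]) * Nv +
      ((mc + 1) == h[[v]]) * (Nmin - (g[[v]] == mc) * Nv)
    Hc[[v]] <- Hv / pmax(apply(Hv, 1L, max), 1e-300)
  }
  steps <- rowmin(g[[root]])

  R <- NR <- vector("list", M)   # rest-of-tree costs/counts, by parent state
  R[[root]] <- matrix(0, nchar, kmax)
  NR[[root]] <- matrix(1, nchar, kmax)
  pre <- rev(po)
  for (u in pre) {
    if (u <= tr$nleaf) next
    if (u == root) {
      D <- matrix(0, nchar, kmax)
      ND <- matrix(1, nchar, kmax)
    } else {
      mu <- rowmin(R[[u]])
      D <- pmin(R[[u]], mu + 1)
      NRu <- NR[[u]]
      NRmin <- rowSums(NRu * (R[[u]] == mu))
      ND <- (R[[u]] == D) * NRu +
        ((mu + 1) == D) * (NRmin - (R[[u]] == mu) * NRu)
    }
    for (v in kids[[u]]) {
      acc <- D
      accN <- ND
      for (w in kids[[u]]) {
        if (w == v) next
        acc <- acc + h[[w]]
        accN <- accN * Hc[[w]]
      }
      R[[v]] <- acc
      NR[[v]] <- accN / pmax(apply(accN, 1L, max), 1e-300)
    }
  }

  children <- which(tr$parent > 0L)
  nedge <- length(children)
  edge_min <- edge_max <- edge_frac <- matrix(0, nchar, nedge)
  colnames(edge_min) <- colnames(edge_max) <- colnames(edge_frac) <- children
  for (e in seq_len(nedge)) {
    v <- children[e]
    A <- g[[v]]; B <- R[[v]]
    zero_ok <- rowmin(A + B) <= steps + 1e-9
    min1 <- rowmin(A)
    cnt1 <- rowSums(abs(A - min1) < 1e-9)
    A2 <- A; A2[abs(A - min1) < 1e-9] <- INF
    min2 <- rowmin(A2)
    cross <- rep(INF, nchar)
    for (t in seq_len(kmax)) {
      excl <- ifelse(abs(A[, t] - min1) < 1e-9 & cnt1 == 1L, min2, min1)
      cross <- pmin(cross, B[, t] + excl)
    }
    change_ok <- cross + 1 <= steps + 1e-9
    edge_min[, e] <- as.numeric(!zero_ok)
    edge_max[, e] <- as.numeric(change_ok)
    # MPR counting
    Nv <- N[[v]]; NRv <- NR[[v]]
    C0 <- rowSums(Nv * NRv * (abs(A + B - steps) < 1e-9))
    C1 <- numeric(nchar)
    for (s in seq_len(kmax)) for (t in seq_len(kmax)) {
      if (s == t) next
      ok <- abs(A[, s] + B[, t] + 1 - steps) < 1e-9
      if (any(ok)) C1[ok] <- C1[ok] + Nv[ok, s] * NRv[ok, t]
    }
    tot <- C0 + C1
    edge_frac[, e] <- ifelse(tot > 0, C1 / tot, 0)
  }
  list(steps = as.integer(round(steps)), children = children,
       g = g, edge_min = edge_min, edge_max = edge_max,
       edge_frac = edge_frac)
}

# One most-parsimonious assignment per character under an explicit
# resolution policy.  Both policies pick, top-down, a child state
# minimising (subtree cost + change indicator), which keeps the joint
# assignment most parsimonious; DELTRAN breaks ties toward the parent
# state (delaying changes), ACCTRAN away from it (accelerating them).
policy_states <- function(tr, m, policy = c("acctran", "deltran")) {
  policy <- match.arg(policy)
  M <- length(tr$parent)
  nchar <- length(m$full_mask)
  kmax <- state_dim(m)
  kids <- ptree_children(tr)
  po <- ptree_postorder(tr)
  root <- ptree_root(tr)

  g <- vector("list", M)
  for (v in po) {
    if (v <= tr$nleaf) {
      g[[v]] <- leaf_cost(m, tr$tips[v], kmax)
    } else {
      acc <- matrix(0, nchar, kmax)
      for (cn in kids[[v]]) {
        mc <- rowmin(g[[cn]])
        acc <- acc + pmin(g[[cn]], mc + 1)
      }
      g[[v]] <- acc
    }
  }
  st <- matrix(NA_integer_, nchar, M)
  tiebase <- matrix(rep(seq_len(kmax) * 1e-4, each = nchar), nchar, kmax)
  key <- g[[root]] + if (policy == "deltran") tiebase else -tiebase
  st[, root] <- max.col(-key, ties.method = "first") - 1L
  for (u in rev(po)) {
    if (u <= tr$nleaf) next
    P <- st[, u]
    for (v in kids[[u]]) {
      same <- matrix(0, nchar, kmax)
      same[cbind(seq_len(nchar), P + 1L)] <- 1
      cost <- g[[v]] + 1 - same
      pref <- if (policy == "deltran") tiebase + (1 - same) * 1e-2
              else tiebase + same * 1e-2
      st[, v] <- max.col(-(cost + pref), ties.method = "first") - 1L
    }
  }
  children <- which(tr$parent > 0L)
  changes <- matrix(0L, nchar, length(children))
  colnames(changes) <- children
  for (e in seq_along(children)) {
    v <- children[e]
    changes[, e] <- as.integer(st[, v] != st[, tr$parent[v]])
  }
  list(states = st, children = children, changes = changes)
}

#' Optimise one character on a tree
#'
#' Reconstructs ancestral states and per-branch change counts for a
#' single character under a stated resolution policy.  `"acctran"` and
#' `"deltran"` return one explicit most-parsimonious reconstruction
#' (changes accelerated toward, or delayed away from, the root);
#' `"mpr_average"` assigns each branch the mean change count over all
#' most-parsimonious reconstructions, which may be fractional.
#'
#' @param tree an `ape::phylo` tree (polytomies allowed, treated as hard).
#' @param m a [morph_matrix()].
#' @param char character index (1-based).
#' @param policy `"acctran"`, `"deltran"` or `"mpr_average"`.
#' @return a list of class `reconstruction` with `character`, `policy`,
#'   `total` (Fitch steps), `branch_changes` (named by the clade below
#'   each branch), and for the explicit policies `node_states`.
#' @export
optimize_character <- function(tree, m, char,
                               policy = c("acctran", "deltran", "mpr_average")) {
  policy <- match.arg(policy)
  tr <- as_ptree(tree, m)
  if (policy == "mpr_average") {
    mp <- map_characters(tr, m)
    ch <- mp$edge_frac[char, ]
    total <- mp$steps[char]
    states <- NULL
    children <- mp$children
  } else {
    ps <- policy_states(tr, m, policy)
    ch <- ps$changes[char, ]
    total <- sum(ch)
    states <- ps$states[char, ]
    children <- ps$children
  }
  structure(list(character = char, policy = policy,
                 total = total, branch_changes = ch,
                 children = children, node_states = states, tree = tr),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("Character ", x$character, " (", x$policy, "): ",
      round(x$total, 3), " change(s) on ",
      sum(x$branch_changes > 0), " branch(es)\n", sep = "")
  invisible(x)
}

#' Optimise all characters on one or more trees
#'
#' @param trees a `phylo`, list of `phylo`, or [mp_search()] result; when
#'   several trees are given, per-branch counts are averaged over trees
#'   that share a branch (keyed by the clade below it).
#' @param m a [morph_matrix()].
#' @param policy resolution policy, as in [optimize_character()].
#' @return a list with `per_character` (data frame: character, total
#'   changes, minimum steps, homoplasy excess) and `branch_changes`
#'   (characters x branches matrix for the first tree, columns named by
#'   clade keys).
#' @export
optimize_all <- function(trees, m,
                         policy = c("acctran", "deltran", "mpr_average")) {
  policy <- match.arg(policy)
  if (inherits(trees, "mp_search")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  tr <- as_ptree(trees[[1L]], m)
  ch <- branch_change_matrix(tr, m, policy)
  totals <- rowSums(ch)
  mn <- min_steps(m)
  data_per <- data.frame(character = m$char_labels,
                         changes = totals, m = mn,
                         homoplasy = totals - mn,
                         stringsAsFactors = FALSE)
  list(per_character = data_per, branch_changes = ch)
}

# characters x edges change matrix with clade-key column names
branch_change_matrix <- function(tr, m, policy) {
  if (policy == "mpr_average") {
    mp <- map_characters(tr, m)
    ch <- mp$edge_frac
    children <- mp$children
  } else {
    ps <- policy_states(tr, m, policy)
    ch <- ps$changes
    children <- ps$children
  }
  below <- ptree_clades(tr)
  colnames(ch) <- vapply(below[children], clade_key, character(1))
  ch
}
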