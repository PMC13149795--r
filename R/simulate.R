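# Seeded Mk-style matrix simulator with full ground truth.
#
# The generator emulates the statistical structure of a fossil-seed
# morphological matrix: unordered multistate characters evolving
# independently under a symmetric k-state Markov process on a pure-birth
# tree, followed by a masking step reproducing the observed missingness
# profile (uniform unknowns, hierarchically placed inapplicables, rare
# polymorphic cells).  Every change event is recorded, so downstream
# inferences can be compared against known truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the seed matrix: 79 taxa;
#' 89 characters in five categories (25/8/18/20/18); per-character state
#' counts drawn from 2-5 with mean about 2.45 (so roughly 218 states in
#' total); 13.9% unknown, 10.5% inapplicable and 0.1% polymorphic cells,
#' with half of the inapplicables driven hierarchically by a controlling
#' character.
#'
#' @param n_taxa number of taxa.
#' @param n_char_by_category named integer vector of characters per
#'   category.
#' @param state_count_probs probabilities of 2, 3, 4, 5 states per
#'   character.
#' @param rate expected state changes per character per unit branch
#'   length.
#' @param brlen_mean,brlen_min branch-length distribution: exponential
#'   with mean `brlen_mean`, shifted by `brlen_min`.
#' @param pct_unknown,pct_inapplicable,pct_polymorphic masking targets
#'   (percent of cells).
#' @param hierarchy_fraction fraction of inapplicable cells placed via a
#'   controlling character's state (the rest uniformly).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 79L,
                       n_char_by_category = c(architectural = 25L,
                                              wall_structure = 8L,
                                              external_topography = 18L,
                                              cellular = 20L,
                                              pollination = 18L),
                       state_count_probs = c(`2` = 0.70, `3` = 0.18,
                                             `4` = 0.09, `5` = 0.03),
                       rate = 0.045,
                       brlen_mean = 1, brlen_min = 0,
                       pct_unknown = 13.9,
                       pct_inapplicable = 10.5,
                       pct_polymorphic = 0.1,
                       hierarchy_fraction = 0.5) {
  if (pct_unknown + pct_inapplicable + pct_polymorphic >= 100)
    stop("masking targets jointly reach 100% of cells")
  stopifnot(n_taxa >= 3, all(n_char_by_category > 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth tree
#'
#' Yule topology (a uniformly chosen extant lineage splits at each
#' event) with independent exponential branch lengths.
#'
#' @param n_taxa number of tips (at least 3).
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param brlen_mean,brlen_min branch-length distribution parameters.
#' @return an `ape::phylo` tree with branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, brlen_mean = 1,
                          brlen_min = 0) {
  if (n_taxa < 3L) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  # grow with temporary ids; node 1 = root
  par_tmp <- c(0L, 1L, 1L)
  leaf <- c(FALSE, TRUE, TRUE)
  while (sum(leaf) < n_taxa) {
    act <- which(leaf)
    v <- act[sample.int(length(act), 1L)]
    leaf[v] <- FALSE
    par_tmp <- c(par_tmp, v, v)
    leaf <- c(leaf, TRUE, TRUE)
  }
  M <- length(par_tmp)
  leaves <- which(leaf)
  internals <- which(!leaf)
  map <- integer(M)
  map[leaves] <- seq_along(leaves)
  map[internals] <- n_taxa + seq_along(internals)
  parent <- integer(M)
  parent[map] <- ifelse(par_tmp > 0L, map[pmax(par_tmp, 1L)], 0L)
  tr <- new_ptree(parent, n_taxa, seq_len(n_taxa), n_taxa)
  phy <- ptree_to_phylo(tr, paste0("t", seq_len(n_taxa)))
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / brlen_mean) +
    brlen_min
  phy
}

#' Evolve characters along a tree
#'
#' Each character evolves independently under a symmetric k-state
#' Markov jump process: change events arrive as a Poisson process at
#' the character's rate, and each event moves to one of the other
#' k - 1 states uniformly, so the rate is directly the expected number
#' of realised changes per unit branch length.  Every event is recorded
#' on its branch.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param config a [sim_config()] (supplies character counts, state
#'   counts and rate); `n_taxa` is ignored.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @return list with `states` (taxa x characters 0-based state matrix),
#'   `true_changes` (characters x branches change-count matrix, columns
#'   keyed by the phylo child node), `k` (states per character),
#'   `category` (per character), `tree`.
#' @export
evolve_characters <- function(tree, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nchr <- sum(config$n_char_by_category)
  category <- rep(names(config$n_char_by_category),
                  config$n_char_by_category)
  k <- sample(as.integer(names(config$state_count_probs)), nchr,
              replace = TRUE, prob = config$state_count_probs)
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  pre <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  root <- pre$edge[1L, 1L]
  rate <- rep_len(config$rate, nchr)

  node_state <- matrix(0L, nchr, M)
  for (c0 in seq_len(nchr))
    node_state[c0, root] <- sample.int(k[c0], 1L) - 1L
  changes <- matrix(0L, nchr, nrow(pre$edge))
  colnames(changes) <- pre$edge[, 2L]
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; v <- pre$edge[e, 2L]
    len <- pre$edge.length[e]
    nev <- stats::rpois(nchr, rate * len)
    st <- node_state[, p]
    for (c0 in which(nev > 0L)) {
      s <- st[c0]
      for (j in seq_len(nev[c0])) {
        s2 <- sample.int(k[c0] - 1L, 1L) - 1L
        s <- if (s2 >= s) s2 + 1L else s2    # uniform over other states
      }
      st[c0] <- s
    }
    changes[, e] <- nev
    node_state[, v] <- st
  }
  states <- t(node_state[, seq_len(n), drop = FALSE])
  rownames(states) <- tree$tip.label
  list(states = states, true_changes = changes, k = k,
       category = category, tree = tree)
}

#' Mask a complete matrix with the study missingness profile
#'
#' Unknown cells are drawn uniformly; inapplicable cells are placed
#' hierarchically (a controlling character's state switches a dependent
#' character to inapplicable for the affected taxa) and topped up (or
#' trimmed) uniformly to the exact target count; polymorphic cells gain
#' one extra random state.  Realised percentages therefore match the
#' targets to rounding.
#'
#' @param states taxa x characters 0-based state matrix (from
#'   [evolve_characters()]).
#' @param k states per character.
#' @param config a [sim_config()] (supplies the masking targets).
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param category optional per-character categories to attach.
#' @return list with `matrix` (a [morph_matrix()]), `mask` (character
#'   matrix: "" kept, "u"/"i"/"p" masked) and `controllers` (data frame
#'   of hierarchical dependencies used).
#' @export
apply_missingness <- function(states, k, config = sim_config(),
                              seed = NULL, category = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntax <- nrow(states); nchr <- ncol(states)
  ncell <- ntax * nchr
  n_u <- round(config$pct_unknown / 100 * ncell)
  n_i <- round(config$pct_inapplicable / 100 * ncell)
  n_p <- round(config$pct_polymorphic / 100 * ncell)
  mask <- matrix("", ntax, nchr)

  controllers <- NULL
  if (n_i > 0L) {
    want_h <- round(config$hierarchy_fraction * n_i)
    guard <- 0L
    while (sum(mask == "i") < want_h && guard < 50L * nchr) {
      guard <- guard + 1L
      c0 <- sample.int(nchr, 1L)
      c1 <- sample.int(nchr, 1L)
      if (c1 == c0) next
      s <- sample.int(k[c0], 1L) - 1L
      hit <- which(states[, c0] == s & mask[, c1] == "")
      if (!length(hit)) next
      need <- want_h - sum(mask == "i")
      if (length(hit) > need) hit <- sample(hit, need)
      mask[hit, c1] <- "i"
      controllers <- rbind(controllers,
                           data.frame(controller = c0, state = s,
                                      dependent = c1, n = length(hit)))
    }
    ni_now <- sum(mask == "i")
    if (ni_now < n_i) {                       # uniform remainder
      free <- which(mask == "")
      mask[sample(free, n_i - ni_now)] <- "i"
    }
  }
  if (n_u > 0L) {
    free <- which(mask == "")
    mask[sample(free, n_u)] <- "u"
  }
  if (n_p > 0L) {
    free <- which(mask == "" & rep(k, each = ntax) >= 2L)
    mask[sample(free, min(n_p, length(free)))] <- "p"
  }

  tok <- matrix(as.character(states), ntax, nchr)
  tok[mask == "u"] <- "?"
  tok[mask == "i"] <- "-"
  pi <- which(mask == "p")
  for (cell in pi) {
    i <- (cell - 1L) %% ntax + 1L
    j <- (cell - 1L) %/% ntax + 1L
    s <- states[i, j]
    s2 <- sample.int(k[j] - 1L, 1L) - 1L
    s2 <- if (s2 >= s) s2 + 1L else s2
    tok[i, j] <- paste0("{", paste(sort(c(s, s2)), collapse = ""), "}")
  }
  rownames(tok) <- rownames(states)
  list(matrix = morph_matrix(tok, category = category),
       mask = mask, controllers = controllers)
}

#' Simulate a complete ground-truth dataset
#'
#' Chains [simulate_tree()], [evolve_characters()] and
#' [apply_missingness()], and derives three taxon groups by slicing the
#' true tree at two internal nodes — a terminal clade and two successive
#' paraphyletic grades below it, mirroring a clade nested within grades.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return an object of class `sim_dataset`: list with `tree`, `states`
#'   (complete matrix), `matrix` (masked [morph_matrix()]),
#'   `true_changes` (characters x branches, keyed by phylo child node),
#'   `k`, `groups` (named list of tip labels), `mask`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(config$n_taxa, seed = NULL,
                        brlen_mean = config$brlen_mean,
                        brlen_min = config$brlen_min)
  ev <- evolve_characters(tree, config, seed = NULL)
  ms <- apply_missingness(ev$states, ev$k, config, seed = NULL,
                          category = ev$category)
  groups <- slice_groups(tree)
  structure(list(tree = tree, states = ev$states, matrix = ms$matrix,
                 true_changes = ev$true_changes, k = ev$k,
                 groups = groups, mask = ms$mask,
                 controllers = ms$controllers,
                 config = config, seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset: ", length(x$tree$tip.label), " taxa x ",
      ncol(x$states), " characters (seed ", x$seed, ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

# split tips into clade + two grades by cutting at two internal nodes
slice_groups <- function(tree) {
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  kids <- vector("list", M)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  below <- vector("list", M)
  tips_below <- function(v) {
    if (!is.null(below[[v]])) return(below[[v]])
    out <- if (v <= n) v else
      unlist(lapply(kids[[v]], tips_below), use.names = FALSE)
    below[[v]] <<- out
    out
  }
  sizes <- vapply((n + 1L):M, function(v) length(tips_below(v)), integer(1))
  nodes <- (n + 1L):M
  a <- nodes[which.min(abs(sizes - n / 3))]
  tips_a <- tips_below(a)
  sup <- nodes[vapply(nodes, function(v)
    all(tips_a %in% tips_below(v)) && length(tips_below(v)) > length(tips_a),
    logical(1))]
  sizes_sup <- vapply(sup, function(v) length(tips_below(v)), integer(1))
  # aim for a middle grade of about n/3 taxa between the two cuts
  b <- sup[which.min(abs(sizes_sup - (length(tips_a) + n / 3)))]
  tips_b <- tips_below(b)
  g3 <- tree$tip.label[tips_a]
  g2 <- tree$tip.label[setdiff(tips_b, tips_a)]
  g1 <- tree$tip.label[setdiff(seq_len(n), tips_b)]
  out <- list(grade1 = g1, grade2 = g2, clade3 = g3)
  out[lengths(out) > 0L]
}
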