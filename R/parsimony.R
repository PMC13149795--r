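# Fitch parsimony scoring and ensemble fit indices.

# nchar x ntax bitmask matrix in the layout the C kernel expects
tmasks <- function(m) {
  x <- t(m$masks)
  storage.mode(x) <- "integer"
  x
}

as_ptree <- function(tree, m) {
  if (inherits(tree, "ptree")) return(tree)
  if (inherits(tree, "phylo")) return(phylo_to_ptree(tree, m$taxa))
  stop("expected a phylo or internal tree object")
}

#' Parsimony length of a tree
#'
#' Computes the minimum number of character-state changes each character
#' requires on a tree, treating every character as unordered.  Unknown
#' and inapplicable cells are expanded to the character's full observed
#' state set, polymorphic cells to their observed set.  Polytomies are
#' scored as hard; the result is the exact minimum over all ancestral
#' state assignments (Hartigan's generalisation of the Fitch downpass).
#'
#' @param tree an `ape::phylo` tree whose tips are matrix taxa.
#' @param m a [morph_matrix()].
#' @return a list with `total` (integer) and `per_character`
#'   (integer vector of steps).
#' @export
fitch_length <- function(tree, m) {
  tr <- as_ptree(tree, m)
  per <- .Call(C_fitch, tr$parent, tr$nleaf, tmasks(m), tr$tips, 1L)
  if (isTRUE(getOption("morphclade.debug"))) {
    mm <- min_steps(m)
    gg <- star_steps(m)
    keep <- tabulate(tr$tips, nbins = length(m$taxa)) > 0L
    if (all(keep) && (any(per < mm) || any(per > gg)))
      stop("internal error: steps outside [m, g]")
  }
  list(total = sum(per), per_character = per)
}

#' Minimum possible steps per character
#'
#' The minimum number of changes a character can require on any tree:
#' one less than the size of the smallest state set that intersects every
#' cell's allowed set (0 when one state is compatible with every cell,
#' including the all-missing case).
#'
#' @param m a [morph_matrix()].
#' @return integer vector, one value per character.
#' @export
min_steps <- function(m) {
  vapply(seq_along(m$full_mask), function(j) {
    full <- m$full_mask[j]
    cells <- m$masks[, j]
    cells <- cells[cells != full]
    if (!length(cells)) return(0L)
    bits <- mask_to_states(full)
    for (sz in seq_along(bits)) {
      for (comb in utils::combn(bits, sz, simplify = FALSE)) {
        S <- sum(bitwShiftL(1L, comb))
        if (all(bitwAnd(cells, S) > 0L)) return(sz - 1L)
      }
    }
    length(bits) - 1L
  }, integer(1))
}

#' Steps per character on the completely unresolved (star) tree
#'
#' The maximum parsimony length a character can attain on any tree
#' equals its length on the star tree: every cell not compatible with
#' the best single central state contributes one change.
#'
#' @param m a [morph_matrix()].
#' @return integer vector, one value per character.
#' @export
star_steps <- function(m) {
  vapply(seq_along(m$full_mask), function(j) {
    full <- m$full_mask[j]
    cells <- m$masks[, j]
    cells <- cells[cells != full]
    if (!length(cells)) return(0L)
    bits <- mask_to_states(full)
    hit <- vapply(bits, function(s)
      sum(bitwAnd(cells, bitwShiftL(1L, s)) > 0L), integer(1))
    length(cells) - max(hit)
  }, integer(1))
}

#' Phylogenetically informative characters
#'
#' A character is parsimony-informative when its step count can differ
#' between trees, i.e. its star-tree maximum exceeds its minimum.
#' Constant characters and autapomorphies are uninformative.
#'
#' @param m a [morph_matrix()].
#' @return logical vector, one value per character.
#' @export
is_informative <- function(m) star_steps(m) > min_steps(m)

#' Per-character fit table for a tree
#'
#' @param tree an `ape::phylo` tree.
#' @param m a [morph_matrix()].
#' @return data frame with columns `character`, `m` (minimum steps),
#'   `s` (observed steps), `g` (star-tree steps), `ci`, `ri`,
#'   `informative`.
#' @export
character_fits <- function(tree, m) {
  s <- fitch_length(tree, m)$per_character
  mn <- min_steps(m)
  g <- star_steps(m)
  ci <- ifelse(s > 0L, mn / s, NA_real_)
  ri <- ifelse(g > mn, (g - s) / (g - mn), 1)
  data.frame(character = m$char_labels, m = mn, s = s, g = g,
             ci = ci, ri = ri, informative = g > mn,
             stringsAsFactors = FALSE)
}

#' Ensemble consistency and retention indices
#'
#' Ensemble CI = sum(m)/sum(s) and ensemble RI =
#' (sum(g) - sum(s)) / (sum(g) - sum(m)), summed over characters, for a
#' tree or a set of equally parsimonious trees (the length, and hence
#' both indices, are identical across a set of most-parsimonious trees).
#'
#' @param trees a `phylo`, a list of them / `multiPhylo`, or an
#'   [mp_search()] result.
#' @param m a [morph_matrix()].
#' @param exclude_uninformative drop parsimony-uninformative characters
#'   from the sums before computing the indices.
#' @return list with `ci`, `ri`, `length` (total steps) and
#'   `per_character` (the [character_fits()] table of the first tree).
#' @export
ensemble_fit <- function(trees, m, exclude_uninformative = FALSE) {
  if (inherits(trees, "mp_search")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  fits <- character_fits(trees[[1L]], m)
  if (length(trees) > 1L) {
    lens <- vapply(trees, function(tr) fitch_length(tr, m)$total, numeric(1))
    if (length(unique(lens)) > 1L)
      warning("trees differ in length; indices reported for the first")
  }
  f <- if (exclude_uninformative) fits[fits$informative, ] else fits
  S <- sum(f$s); M <- sum(f$m); G <- sum(f$g)
  ci <- if (S == 0L) { warning("zero total length; CI set to 1"); 1 }
        else M / S
  ri <- if (G == M) 1 else (G - S) / (G - M)
  list(ci = ci, ri = ri, length = sum(fits$s), per_character = fits)
}
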