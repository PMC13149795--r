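# Per-grade character-change-rate statistics.

#' Assign tree branches to taxon groups
#'
#' A branch belongs to a group when every group-assigned leaf below it
#' belongs to that group (and at least one such leaf exists).  Spine
#' branches whose descendants span several groups, and branches leading
#' only to unassigned taxa, belong to no group; this makes paraphyletic
#' grade segments well defined and never double-counts a branch.
#'
#' @param tree an `ape::phylo` tree.
#' @param m a [morph_matrix()] (supplies the taxon universe).
#' @param groups named list of taxon-label vectors; groups must be
#'   pairwise disjoint.
#' @return data frame with one row per branch: `branch` (clade key of
#'   the taxa below it), `group` (name or `NA`).
#' @export
assign_branches <- function(tree, m, groups) {
  tr <- as_ptree(tree, m)
  asg <- branch_groups(tr, m, groups)
  below <- ptree_clades(tr)
  data.frame(branch = vapply(below[asg$children], clade_key, character(1)),
             group = asg$group,
             stringsAsFactors = FALSE)
}

# internal: group name (or NA) per edge, edges keyed by child node
branch_groups <- function(tr, m, groups) {
  memb <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(memb))
    stop("groups overlap on taxon: ", memb[duplicated(memb)][1L])
  bad <- setdiff(memb, m$taxa)
  if (length(bad)) stop("group member not a matrix taxon: ", bad[1L])
  if (any(lengths(groups) == 0L)) stop("empty group")
  gid <- stats::setNames(rep(names(groups), lengths(groups)), memb)

  below <- ptree_clades(tr)
  children <- which(tr$parent > 0L)
  grp <- vapply(children, function(v) {
    labs <- m$taxa[below[[v]]]
    gs <- unique(gid[labs[labs %in% names(gid)]])
    if (length(gs) == 1L) gs else NA_character_
  }, character(1))
  list(children = children, group = grp)
}

#' Grade-segment character-change rates
#'
#' For each character and taxon group, counts the state transitions
#' occurring on branches assigned to the group and divides by the number
#' of group members scorable for that character (determinate or
#' polymorphic cells), giving transitions per character per scorable
#' taxon.  Per-category means and standard deviations, and a per-group
#' overall mean, summarise the table.
#'
#' @param trees the mapping tree: a `phylo` (typically the strict
#'   consensus), or an [mp_search()] result (its strict consensus is
#'   used).
#' @param m a [morph_matrix()].
#' @param groups named list of taxon-label vectors (pairwise disjoint).
#' @param categories per-character category vector (defaults to
#'   `m$category`).
#' @param policy resolution policy, as in [optimize_character()].
#' @return an object of class `rate_table`: list with `rates`,
#'   `transitions`, `scorable` (character x group matrices),
#'   `by_category` (data frame of mean (SD) per category x group),
#'   `overall` (named vector of per-group means) and `policy`.
#' @export
segment_rates <- function(trees, m, groups, categories = m$category,
                          policy = c("acctran", "deltran", "mpr_average")) {
  policy <- match.arg(policy)
  if (inherits(trees, "mp_search")) trees <- strict_consensus(trees)
  tr <- as_ptree(trees, m)
  if (is.null(categories))
    stop("no character categories available; supply `categories`")

  ch <- branch_change_matrix(tr, m, policy)        # nchar x nedge
  asg <- branch_groups(tr, m, groups)
  gnames <- names(groups)
  nchar <- nrow(ch)

  trans <- scor <- matrix(0, nchar, length(gnames),
                          dimnames = list(m$char_labels, gnames))
  for (g in gnames) {
    cols <- which(!is.na(asg$group) & asg$group == g)
    trans[, g] <- if (length(cols)) rowSums(ch[, cols, drop = FALSE]) else 0
    rows <- match(groups[[g]], m$taxa)
    kd <- m$kind[rows, , drop = FALSE]
    scor[, g] <- colSums(kd == "d" | kd == "p")
  }
  rates <- ifelse(scor > 0, trans / scor, NA_real_)

  cats <- unique(categories)
  by_cat <- do.call(rbind, lapply(cats, function(ct) {
    idx <- which(categories == ct)
    row <- data.frame(category = ct, n_characters = length(idx),
                      stringsAsFactors = FALSE)
    for (g in gnames) {
      r <- rates[idx, g]
      row[[paste0(g, "_mean")]] <- mean(r, na.rm = TRUE)
      row[[paste0(g, "_sd")]] <- stats::sd(r, na.rm = TRUE)
    }
    row
  }))
  overall <- vapply(gnames, function(g) mean(rates[, g], na.rm = TRUE),
                    numeric(1))
  structure(list(rates = rates, transitions = trans, scorable = scor,
                 by_category = by_cat, overall = overall, policy = policy),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, digits = 3, ...) {
  cat("Character-change rates (transitions per character per scorable taxon),\n")
  cat("policy ", x$policy, ":\n\n", sep = "")
  bc <- x$by_category
  gnames <- names(x$overall)
  disp <- data.frame(category = bc$category, n = bc$n_characters)
  for (g in gnames)
    disp[[g]] <- sprintf("%.*f (%.*f)", digits, bc[[paste0(g, "_mean")]],
                         digits, bc[[paste0(g, "_sd")]])
  print(disp, row.names = FALSE)
  cat("\noverall means: ",
      paste(sprintf("%s %.*f", gnames, digits, x$overall), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
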