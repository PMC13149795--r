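# Gower distance, principal coordinates analysis and similarity export.

#' Gower distance between taxa
#'
#' For purely categorical data with pairwise deletion this is the
#' simple-matching mismatch proportion: the fraction of characters
#' scored determinately in *both* taxa at which their states differ.
#' Unknown and inapplicable cells are excluded pairwise; polymorphic
#' cells are re-scored as unknown first (see [recode_for_distance()]).
#'
#' @param m a [morph_matrix()].
#' @return an object of class `morph_gower`: list with `d` (symmetric
#'   distance matrix in \[0, 1\], taxa as dimnames) and `n_shared`
#'   (per-pair count of mutually scored characters).
#' @export
gower_distance <- function(m) {
  m <- recode_for_distance(m)
  ntax <- length(m$taxa)
  scored <- m$kind == "d"
  states <- matrix(NA_integer_, ntax, ncol(m$masks))
  st <- as.integer(round(log2(m$masks)))
  states[scored] <- st[scored]

  d <- matrix(0, ntax, ntax, dimnames = list(m$taxa, m$taxa))
  ns <- matrix(0L, ntax, ntax, dimnames = list(m$taxa, m$taxa))
  for (i in seq_len(ntax - 1L)) {
    for (j in seq.int(i + 1L, ntax)) {
      sh <- scored[i, ] & scored[j, ]
      nsh <- sum(sh)
      if (nsh == 0L)
        stop("taxa share no scored characters: ", m$taxa[i], " / ",
             m$taxa[j])
      dij <- sum(states[i, sh] != states[j, sh]) / nsh
      d[i, j] <- d[j, i] <- dij
      ns[i, j] <- ns[j, i] <- nsh
    }
  }
  diag(ns) <- ncol(m$masks)
  structure(list(d = d, n_shared = ns), class = "morph_gower")
}

#' @export
print.morph_gower <- function(x, ...) {
  cat("Gower distance matrix over ", nrow(x$d), " taxa; range ",
      sprintf("%.3f-%.3f", min(x$d[upper.tri(x$d)]),
              max(x$d[upper.tri(x$d)])), "\n", sep = "")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: the squared-distance matrix is double
#' centred (B = -1/2 J D^2 J), eigendecomposed, and taxon coordinates
#' are eigenvectors scaled by the square root of their eigenvalues.
#' Negative eigenvalues (possible because pairwise-deleted Gower
#' distances need not be Euclidean) are reported but excluded from the
#' percent-variance denominator; no Lingoes/Cailliez correction is
#' applied.
#'
#' @param d a [gower_distance()] result, a `dist`, or a symmetric
#'   distance matrix.
#' @return an object of class `morph_pcoa`: list with `coordinates`
#'   (taxa x retained axes), `eigenvalues` (all, descending),
#'   `pct_variance` (per positive axis, of the positive-eigenvalue sum)
#'   and `pct_variance_abs` (of the absolute-eigenvalue sum).
#' @export
pcoa <- function(d) {
  D <- if (inherits(d, "morph_gower")) d$d else as.matrix(d)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  ee <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- ee$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  coords <- ee$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]),
                                                    length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 pct_variance = 100 * ev[pos] / sum(ev[pos]),
                 pct_variance_abs = 100 * ev[pos] / sum(abs(ev))),
            class = "morph_pcoa")
}

#' @export
print.morph_pcoa <- function(x, ...) {
  k <- min(4L, length(x$pct_variance))
  cat("Principal coordinates analysis: ", ncol(x$coordinates),
      " positive axes\n", sep = "")
  cat("  % variance (positive-sum convention): ",
      paste(sprintf("%.1f", x$pct_variance[seq_len(k)]), collapse = ", "),
      if (length(x$pct_variance) > k) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
plot.morph_pcoa <- function(x, axes = c(1L, 2L), groups = NULL, ...) {
  xy <- x$coordinates[, axes, drop = FALSE]
  col <- 1L
  if (!is.null(groups)) {
    gid <- rep(NA_integer_, nrow(xy))
    for (k in seq_along(groups))
      gid[rownames(xy) %in% groups[[k]]] <- k
    col <- ifelse(is.na(gid), "grey60", gid + 1L)
  }
  graphics::plot(xy, col = col, pch = 19,
                 xlab = sprintf("PCo%d (%.1f%%)", axes[1L],
                                x$pct_variance[axes[1L]]),
                 ylab = sprintf("PCo%d (%.1f%%)", axes[2L],
                                x$pct_variance[axes[2L]]), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = names(groups), col = seq_along(groups) + 1L,
                     pch = 19, bty = "n")
  invisible(x)
}

#' Similarity matrix for heatmap display
#'
#' Emits 1 - distance with rows and columns permuted to a given taxon
#' order, typically the base-to-apex leaf sequence of the strict
#' consensus tree (see [consensus_leaf_order()]).
#'
#' @param d a [gower_distance()] result or symmetric distance matrix.
#' @param taxon_order permutation of the taxa (labels); default keeps
#'   the input order.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
similarity_heatmap_export <- function(d, taxon_order = NULL) {
  D <- if (inherits(d, "morph_gower")) d$d else as.matrix(d)
  taxa <- rownames(D)
  if (is.null(taxon_order)) taxon_order <- taxa
  if (length(taxon_order) != length(taxa) ||
      anyDuplicated(taxon_order) ||
      !all(taxon_order %in% taxa))
    stop("taxon_order is not a permutation of the taxa")
  S <- 1 - D[taxon_order, taxon_order]
  S
}

#' Base-to-apex leaf order of a tree
#'
#' The left-to-right tip sequence of the ladderised tree, read with the
#' outgroup first — the order used to arrange taxa in similarity
#' heatmaps so that phylogenetically adjacent taxa are adjacent rows.
#'
#' @param tree an `ape::phylo` tree (rooted on the outgroup edge).
#' @return character vector of tip labels.
#' @export
consensus_leaf_order <- function(tree) {
  lad <- ape::ladderize(tree, right = TRUE)
  tips <- lad$edge[lad$edge[, 2L] <= length(lad$tip.label), 2L]
  lad$tip.label[tips]
}
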