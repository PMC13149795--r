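# Stratigraphic time-scaling and fossil-record gap detection.

#' Time-scale a tree against stratigraphic ranges
#'
#' "Basic" a-priori dating: each terminal node is placed at its taxon's
#' first appearance (FAD), each internal node at the oldest FAD among
#' its descendants, and zero-duration internal branches are then
#' stretched by `epsilon_ma` working root-ward (purely presentational).
#'
#' @param tree an `ape::phylo` tree (polytomies allowed).
#' @param ranges data frame with columns `taxon`, `fad`, `lad`
#'   (see [read_strat_ranges()]); every tip needs a range.
#' @param epsilon_ma minimum duration, in Myr, imposed on internal
#'   branches.
#' @return an object of class `timescaled_tree`: list with `tree`
#'   (the input `phylo` with `edge.length` in Myr), `node_ages` (Ma,
#'   indexed by phylo node id), `ranges`, `epsilon_ma`.
#' @export
timescale <- function(tree, ranges, epsilon_ma = 0.5) {
  tips <- tree$tip.label
  idx <- match(tips, ranges$taxon)
  if (anyNA(idx))
    stop("no stratigraphic range for taxon: ",
         paste(tips[is.na(idx)], collapse = ", "))
  n <- length(tips)
  M <- n + tree$Nnode
  age <- numeric(M)
  age[seq_len(n)] <- ranges$fad[idx]

  # postorder over edges (ape pruningwise = children before parents):
  # first the raw max-of-descendant-FADs ages, then a second pass
  # imposing epsilon_ma as a minimum internal branch duration
  pw <- ape::reorder.phylo(tree, "pruningwise")
  for (e in seq_len(nrow(pw$edge))) {
    p <- pw$edge[e, 1L]; v <- pw$edge[e, 2L]
    age[p] <- max(age[p], age[v])
  }
  if (epsilon_ma > 0) {
    for (e in seq_len(nrow(pw$edge))) {
      p <- pw$edge[e, 1L]; v <- pw$edge[e, 2L]
      if (v > n) age[p] <- max(age[p], age[v] + epsilon_ma)
    }
  }
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  structure(list(tree = tree, node_ages = age,
                 ranges = ranges[idx, , drop = FALSE],
                 epsilon_ma = epsilon_ma),
            class = "timescaled_tree")
}

#' @export
print.timescaled_tree <- function(x, ...) {
  root <- x$tree$edge[1L, 1L]
  cat("Time-scaled tree: root at ", sprintf("%.1f", x$node_ages[root]),
      " Ma, tips ", sprintf("%.1f-%.1f", max(x$ranges$fad),
                            min(x$ranges$lad)), " Ma\n", sep = "")
  invisible(x)
}

#' @export
plot.timescaled_tree <- function(x, show_ranges = TRUE, ...) {
  n <- length(x$tree$tip.label)
  root_age <- max(x$node_ages)
  pp <- ape::plot.phylo(x$tree, x.lim = c(0, root_age - min(x$ranges$lad)),
                        ...)
  if (show_ranges) {
    lp <- get("last_plot.phylo", envir = ape::.PlotPhyloEnv)
    graphics::segments(root_age - x$ranges$fad, lp$yy[seq_len(n)],
                       root_age - x$ranges$lad, lp$yy[seq_len(n)],
                       lwd = 3,
                       col = grDevices::adjustcolor("steelblue", 0.7))
  }
  at <- pretty(c(min(x$ranges$lad), root_age))
  graphics::axis(1, at = root_age - at, labels = at)
  graphics::mtext("age (Ma)", side = 1, line = 2.5)
  invisible(pp)
}

#' Gaps in the sampled fossil record
#'
#' Computes the complement of the union of the taxon ranges within the
#' study window (oldest FAD to youngest LAD), merged into maximal empty
#' intervals reported oldest-first; intervals shorter than
#' `resolution_myr` are suppressed.
#'
#' @param ranges data frame with `taxon`, `fad`, `lad` columns.
#' @param resolution_myr minimum gap duration reported.
#' @param window optional `c(oldest, youngest)` Ma bounds overriding the
#'   data-derived window.
#' @return data frame with columns `older`, `younger`, `duration` (Ma).
#' @export
record_gaps <- function(ranges, resolution_myr = 0, window = NULL) {
  if (!nrow(ranges)) stop("no ranges supplied")
  if (is.null(window)) window <- c(max(ranges$fad), min(ranges$lad))
  lo <- window[2L]; hi <- window[1L]
  iv <- cbind(pmax(ranges$lad, lo), pmin(ranges$fad, hi))
  iv <- iv[iv[, 1L] < iv[, 2L], , drop = FALSE]
  ord <- order(iv[, 1L])
  iv <- iv[ord, , drop = FALSE]
  # merge the union, collect holes
  gaps <- NULL
  cur <- lo
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1L] > cur) gaps <- rbind(gaps, c(cur, iv[r, 1L]))
    cur <- max(cur, iv[r, 2L])
  }
  if (cur < hi) gaps <- rbind(gaps, c(cur, hi))
  if (is.null(gaps))
    return(data.frame(older = numeric(0), younger = numeric(0),
                      duration = numeric(0)))
  out <- data.frame(older = gaps[, 2L], younger = gaps[, 1L],
                    duration = gaps[, 2L] - gaps[, 1L])
  out <- out[out$duration >= resolution_myr - 1e-9, , drop = FALSE]
  out <- out[order(-out$older), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' International chronostratigraphic stage boundaries (Devonian-Permian)
#'
#' A bundled lookup of stage names and their age bounds (Ma), for
#' converting stage-resolved occurrence data to numeric FAD/LAD values.
#'
#' @return data frame with columns `stage`, `older`, `younger` (Ma).
#' @export
ics_stages <- function() {
  data.frame(
    stage = c("Givetian", "Frasnian", "Famennian", "Tournaisian",
              "Visean", "Serpukhovian", "Bashkirian", "Moscovian",
              "Kasimovian", "Gzhelian", "Asselian", "Sakmarian",
              "Artinskian", "Kungurian", "Roadian", "Wordian",
              "Capitanian", "Wuchiapingian", "Changhsingian"),
    older = c(387.7, 382.7, 372.2, 358.9, 346.7, 330.9, 323.2, 315.2,
              307.0, 303.7, 298.9, 293.52, 290.1, 283.5, 273.01,
              266.9, 264.28, 259.51, 254.14),
    younger = c(382.7, 372.2, 358.9, 346.7, 330.9, 323.2, 315.2, 307.0,
                303.7, 298.9, 293.52, 290.1, 283.5, 273.01, 266.9,
                264.28, 259.51, 254.14, 251.9),
    stringsAsFactors = FALSE)
}
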