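# Reading, writing and summarising discrete morphological matrices.

CATEGORIES <- c("architectural", "wall_structure", "external_topography",
                "cellular", "pollination")

#' Construct a morphological character matrix
#'
#' Builds a `morph_matrix` from a character matrix of cell tokens.  Each
#' cell is a single state symbol (e.g. `"0"`), a polymorphic set
#' (`"{01}"` or `"(01)"`), `"?"` for unknown, or `"-"` for inapplicable.
#' Unknown cells stand for the full set of states observed for that
#' character; inapplicable cells are kept distinct in summaries but are
#' treated as fully ambiguous by the parsimony machinery.
#'
#' @param x character matrix (taxa in rows, characters in columns); row
#'   names give taxon labels.
#' @param symbols ordered state alphabet; symbol position i encodes state
#'   index i - 1.
#' @param char_labels optional character labels (defaults to `C1`, `C2`, ...).
#' @param category optional per-character category, one of
#'   `"architectural"`, `"wall_structure"`, `"external_topography"`,
#'   `"cellular"`, `"pollination"`.
#' @param extrinsic optional data frame of per-taxon annotations excluded
#'   from all analyses.
#' @return an object of class `morph_matrix`.
#' @export
morph_matrix <- function(x, symbols = as.character(0:9), char_labels = NULL,
                         category = NULL, extrinsic = NULL) {
  stopifnot(is.matrix(x), is.character(x))
  taxa <- rownames(x)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(x)))
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ",
                                taxa[duplicated(taxa)][1L])
  ntax <- nrow(x); nchr <- ncol(x)
  if (is.null(char_labels)) char_labels <- paste0("C", seq_len(nchr))
  kind <- matrix("d", ntax, nchr)
  masks <- matrix(0L, ntax, nchr)
  for (j in seq_len(nchr)) {
    for (i in seq_len(ntax)) {
      tok <- x[i, j]
      if (tok == "?") { kind[i, j] <- "u"; next }
      if (tok %in% c("-", "–")) { kind[i, j] <- "i"; next }
      states <- strsplit(gsub("[{}() ]", "", tok), "")[[1L]]
      idx <- match(states, symbols)
      if (anyNA(idx))
        stop("undeclared state symbol '", states[is.na(idx)][1L],
             "' for taxon ", taxa[i], ", character ", char_labels[j])
      masks[i, j] <- sum(bitwShiftL(1L, idx - 1L))
      if (length(idx) > 1L) kind[i, j] <- "p"
    }
  }
  full <- integer(nchr)
  for (j in seq_len(nchr)) {
    fm <- Reduce(bitwOr, masks[kind[, j] %in% c("d", "p"), j], 0L)
    full[j] <- if (fm == 0L) 1L else fm
    amb <- kind[, j] %in% c("u", "i")
    masks[amb, j] <- full[j]
  }
  if (!is.null(category)) {
    category <- as.character(category)
    if (length(category) != nchr) stop("category map length != n characters")
    bad <- setdiff(unique(category), CATEGORIES)
    if (length(bad)) stop("unknown character category: ", bad[1L])
  }
  structure(list(taxa = taxa, char_labels = char_labels,
                 symbols = symbols, masks = masks, kind = kind,
                 full_mask = full, n_states = popcount(full),
                 category = category, extrinsic = extrinsic),
            class = "morph_matrix")
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

mask_to_states <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:30)) > 0L) - 1L

#' @export
print.morph_matrix <- function(x, ...) {
  cat("Morphological character matrix: ", length(x$taxa), " taxa x ",
      length(x$char_labels), " characters (",
      sum(x$n_states), " states)\n", sep = "")
  s <- summarize_matrix(x)
  cat(sprintf("  unknown %.1f%%, inapplicable %.1f%%, polymorphic %.1f%%\n",
              s$pct_unknown, s$pct_inapplicable, s$pct_polymorphic))
  invisible(x)
}

#' @export
dim.morph_matrix <- function(x) c(length(x$taxa), length(x$char_labels))

#' Summarise matrix completeness
#'
#' Computes cell counts and percentages of unknown, inapplicable,
#' missing (unknown + inapplicable) and polymorphic cells, overall and
#' per taxon / per character.  Extrinsic columns, if any, are excluded by
#' construction (they are never part of the analysis grid).
#'
#' @param m a [morph_matrix()].
#' @return an object of class `morph_summary` (a list with fields
#'   `n_taxa`, `n_characters`, `n_cells`, `n_states_total`, `pct_unknown`,
#'   `pct_inapplicable`, `pct_missing`, `pct_polymorphic`,
#'   `per_taxon_pct_missing`, `per_character_pct_missing`).
#' @export
summarize_matrix <- function(m) {
  stopifnot(inherits(m, "morph_matrix"))
  ncell <- length(m$kind)
  u <- m$kind == "u"; i <- m$kind == "i"; p <- m$kind == "p"
  miss <- u | i
  out <- list(
    n_taxa = length(m$taxa),
    n_characters = length(m$char_labels),
    n_cells = ncell,
    n_states_total = sum(m$n_states),
    pct_unknown = 100 * sum(u) / ncell,
    pct_inapplicable = 100 * sum(i) / ncell,
    pct_missing = 100 * sum(miss) / ncell,
    pct_polymorphic = 100 * sum(p) / ncell,
    per_taxon_pct_missing =
      stats::setNames(100 * rowMeans(miss), m$taxa),
    per_character_pct_missing =
      stats::setNames(100 * colMeans(miss), m$char_labels))
  class(out) <- "morph_summary"
  out
}

#' @export
print.morph_summary <- function(x, ...) {
  cat(sprintf("%d taxa x %d characters = %d cells (%d states)\n",
              x$n_taxa, x$n_characters, x$n_cells, x$n_states_total))
  cat(sprintf("  unknown %.1f%% + inapplicable %.1f%% = missing %.1f%%; polymorphic %.1f%%\n",
              x$pct_unknown, x$pct_inapplicable, x$pct_missing,
              x$pct_polymorphic))
  cat(sprintf("  least complete taxon: %s (%.0f%% missing); most complete: %s (%.0f%%)\n",
              names(which.max(x$per_taxon_pct_missing)),
              max(x$per_taxon_pct_missing),
              names(which.min(x$per_taxon_pct_missing)),
              min(x$per_taxon_pct_missing)))
  invisible(x)
}

#' Recode a matrix for distance computation
#'
#' Re-scores every polymorphic cell as unknown, so that downstream
#' distance calculations (which exclude unknown and inapplicable cells
#' pairwise) see only determinate scores.  Determinate cells are
#' unchanged.
#'
#' @param m a [morph_matrix()].
#' @return a `morph_matrix` with no polymorphic cells.
#' @export
recode_for_distance <- function(m) {
  stopifnot(inherits(m, "morph_matrix"))
  poly <- m$kind == "p"
  m$kind[poly] <- "u"
  m$masks[poly] <- rep(m$full_mask, each = nrow(m$masks))[poly]
  m
}

# cell tokens (for writing / round-trips)
cell_tokens <- function(m) {
  ntax <- nrow(m$masks); nchr <- ncol(m$masks)
  out <- matrix("?", ntax, nchr)
  for (j in seq_len(nchr)) {
    for (i in seq_len(ntax)) {
      k <- m$kind[i, j]
      if (k == "u") out[i, j] <- "?"
      else if (k == "i") out[i, j] <- "-"
      else {
        st <- m$symbols[mask_to_states(m$masks[i, j]) + 1L]
        out[i, j] <- if (k == "p") paste0("{", paste(st, collapse = ""), "}")
                     else st
      }
    }
  }
  out
}

#' Read a morphological matrix from a NEXUS file
#'
#' Parses the `DATA` (or `CHARACTERS`) block of a NEXUS file with the
#' usual morphological conventions: `?` unknown, `-` (gap) inapplicable,
#' `{...}` or `(...)` polymorphic, and a `SYMBOLS` list mapped
#' positionally to state indices 0, 1, 2, ...
#'
#' @param path file path.
#' @param n_extrinsic number of trailing columns to treat as extrinsic
#'   annotations (excluded from the analysis grid).
#' @return a [morph_matrix()].
#' @export
read_nexus <- function(path, n_extrinsic = 0L) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)     # NEXUS comments
  up <- toupper(txt)
  if (!grepl("#NEXUS", up)) stop("not a NEXUS file: ", path)

  grab <- function(re) {
    mm <- regmatches(txt, regexpr(re, txt, perl = TRUE, ignore.case = TRUE))
    if (!length(mm)) NA_character_ else mm
  }
  ntax <- as.integer(sub(".*?(\\d+)$", "\\1",
                         grab("NTAX\\s*=\\s*\\d+")))
  nchr <- as.integer(sub(".*?(\\d+)$", "\\1",
                         grab("NCHAR\\s*=\\s*\\d+")))
  if (is.na(ntax) || is.na(nchr)) stop("missing NTAX/NCHAR declaration")
  symtxt <- grab("SYMBOLS\\s*=\\s*\"[^\"]*\"")
  symbols <- if (is.na(symtxt)) as.character(0:9) else
    strsplit(gsub("\\s", "", sub(".*\"([^\"]*)\".*", "\\1", symtxt)), "")[[1L]]

  mat <- regmatches(txt, regexpr("MATRIX(.|\n)*?;", txt, perl = TRUE,
                                 ignore.case = TRUE))
  if (!length(mat)) stop("no MATRIX block found")
  body <- sub(";\\s*$", "", sub("^MATRIX", "", mat, ignore.case = TRUE))
  rows <- trimws(strsplit(body, "\n")[[1L]])
  rows <- rows[nzchar(rows)]

  taxa <- character(0)
  cells <- NULL
  for (r in rows) {
    if (startsWith(r, "'")) {
      nm <- sub("^'([^']*)'.*", "\\1", r)
      seqtxt <- sub("^'[^']*'", "", r)
    } else {
      nm <- sub("\\s.*$", "", r)
      seqtxt <- sub("^\\S+", "", r)
    }
    seqtxt <- gsub("\\s", "", seqtxt)
    toks <- parse_cell_tokens(seqtxt, nm)
    if (nm %in% taxa) stop("duplicate taxon in matrix: ", nm)
    if (length(toks) != nchr)
      stop("row for taxon ", nm, " has ", length(toks),
           " cells; NCHAR declares ", nchr)
    taxa <- c(taxa, nm)
    cells <- rbind(cells, toks)
  }
  if (length(taxa) != ntax)
    stop("matrix has ", length(taxa), " taxa; NTAX declares ", ntax)
  rownames(cells) <- taxa

  extr <- NULL
  if (n_extrinsic > 0L) {
    keep <- seq_len(nchr - n_extrinsic)
    extr <- as.data.frame(cells[, -keep, drop = FALSE])
    names(extr) <- paste0("X", seq_len(n_extrinsic))
    cells <- cells[, keep, drop = FALSE]
  }
  morph_matrix(cells, symbols = symbols, extrinsic = extr)
}

# split a cell string into per-character tokens, honouring {..} and (..)
parse_cell_tokens <- function(s, taxon) {
  chars <- strsplit(s, "")[[1L]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars))
        stop("unbalanced polymorphism brackets for taxon ", taxon)
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

#' Write a morphological matrix to a NEXUS file
#'
#' Inverse of [read_nexus()]: the written file reads back to an
#' identical cell grid, taxon order and symbol mapping.
#'
#' @param m a [morph_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path) {
  toks <- cell_tokens(m)
  nm <- m$taxa
  quoted <- grepl("[^A-Za-z0-9_.]", nm)
  nm[quoted] <- paste0("'", nm[quoted], "'")
  pad <- formatC(nm, width = max(nchar(nm)) + 2L, flag = "-")
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     nrow(toks), ncol(toks)),
             sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
                     paste(m$symbols, collapse = " ")),
             "  MATRIX",
             paste0("    ", pad, apply(toks, 1L, paste, collapse = "")),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a character-category sidecar table
#'
#' Expects a two-column delimited file `character_id<TAB>category`, with
#' 1-based character ids and categories drawn from the five recognised
#' classes (architectural, wall_structure, external_topography, cellular,
#' pollination).
#'
#' @param path file path.
#' @param n_characters number of characters the map must cover.
#' @return character vector of categories, indexed by character id.
#' @export
read_categories <- function(path, n_characters) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  id <- as.integer(d[[1L]])
  cat <- as.character(d[[2L]])
  out <- rep(NA_character_, n_characters)
  out[id] <- cat
  if (anyNA(out)) stop("category map does not cover all characters")
  bad <- setdiff(unique(cat), CATEGORIES)
  if (length(bad)) stop("unknown character category: ", bad[1L])
  out
}

#' Read a taxon-group sidecar table
#'
#' Expects `taxon<TAB>group`.  Groups must be pairwise disjoint; taxa of
#' uncertain affinity may simply be absent.
#'
#' @param path file path.
#' @return named list of character vectors (group name -> member taxa).
#' @export
read_groups <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1L]]))
    stop("taxon assigned to more than one group: ",
         d[[1L]][duplicated(d[[1L]])][1L])
  split(as.character(d[[1L]]), as.character(d[[2L]]))
}

#' Read a stratigraphic range sidecar table
#'
#' Expects `taxon<TAB>fad_ma<TAB>lad_ma` with first-appearance (older,
#' larger) and last-appearance ages in Ma.
#'
#' @param path file path.
#' @return data frame with columns `taxon`, `fad`, `lad`.
#' @export
read_strat_ranges <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(taxon = as.character(d[[1L]]),
                    fad = as.numeric(d[[2L]]),
                    lad = as.numeric(d[[3L]]),
                    stringsAsFactors = FALSE)
  bad <- out$fad < out$lad | out$lad <= 0
  if (any(bad)) stop("invalid range (need fad >= lad > 0) for taxon ",
                     out$taxon[bad][1L])
  out
}
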