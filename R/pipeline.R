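# One-call orchestration of the full analysis.

stage_seed <- function(seed, stage) {
  offs <- c(search = 101L, bootstrap = 211L, bremer = 307L,
            rates = 401L, disparity = 503L, simulate = 601L)
  (as.integer(seed) * 977L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full morphological-cladistics pipeline
#'
#' Executes, in order: matrix summary, parsimony-informativeness,
#' heuristic search, branch collapse, strict and majority-rule
#' consensus, bootstrap and Bremer support, character mapping and
#' grade-segment rates (when groups and categories are available),
#' Gower/PCoA/similarity-heatmap disparity, and stratigraphic
#' time-scaling with record-gap detection (when ranges are available).
#' Every stage draws its seed deterministically from the global seed, so
#' stages are individually reproducible.
#'
#' @param m a [morph_matrix()] or path to a NEXUS file.
#' @param categories per-character category vector, or path to a sidecar
#'   TSV (see [read_categories()]).
#' @param groups named list of taxon-label vectors, or path to a sidecar
#'   TSV (see [read_groups()]).
#' @param ranges data frame of stratigraphic ranges, or path to a
#'   sidecar TSV (see [read_strat_ranges()]).
#' @param outgroup taxon label (default: first taxon).
#' @param replicates,hold,max_explore heuristic search profile.
#' @param collapse zero-length-branch rule (see [mp_search()]).
#' @param bootstrap_n bootstrap pseudoreplicates (0 = skip).
#' @param bremer_k largest Bremer suboptimality band swept (0 = skip).
#' @param policy character-mapping resolution policy.
#' @param epsilon_ma minimum internal branch duration for time-scaling.
#' @param out_dir if non-NULL, write all artifacts (Newick trees, TSV
#'   tables, JSON summary) under this directory.
#' @param seed global seed.
#' @param verbose print stage progress.
#' @return an object of class `morphclade_report` with the results of
#'   every stage and a machine-readable `summary` list.
#' @export
run_pipeline <- function(m, categories = NULL, groups = NULL, ranges = NULL,
                         outgroup = NULL, replicates = 50L, hold = 20L,
                         max_explore = Inf,
                         collapse = "max_zero", bootstrap_n = 100L,
                         bremer_k = 3L,
                         policy = "acctran", epsilon_ma = 0.5,
                         out_dir = NULL, seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(m)) m <- read_nexus(m)
  if (is.character(categories) && length(categories) == 1L)
    categories <- read_categories(categories, length(m$char_labels))
  if (is.null(categories)) categories <- m$category
  if (is.character(groups)) groups <- read_groups(groups)
  if (is.character(ranges)) ranges <- read_strat_ranges(ranges)
  if (is.null(outgroup)) outgroup <- m$taxa[1L]

  say("summarising matrix")
  summ <- summarize_matrix(m)
  informative <- is_informative(m)

  say("heuristic search (%d replicates, hold %d)", replicates, hold)
  search <- mp_search(m, replicates = replicates, hold = hold,
                      seed = stage_seed(seed, "search"),
                      collapse = collapse, outgroup = outgroup,
                      max_explore = max_explore)
  fit <- ensemble_fit(search, m)
  fit_excl <- ensemble_fit(search, m, exclude_uninformative = TRUE)

  say("consensus trees")
  cons <- strict_consensus(search, outgroup = outgroup)
  maj <- majority_consensus(search, outgroup = outgroup)

  boot <- NULL
  if (bootstrap_n > 0L) {
    say("bootstrap (%d pseudoreplicates)", bootstrap_n)
    boot <- bootstrap_support(m, n_pseudoreplicates = bootstrap_n,
                              seed = stage_seed(seed, "bootstrap"),
                              outgroup = outgroup)
  }
  bremer <- NULL
  if (bremer_k > 0L) {
    say("Bremer sweep (max k = %d)", bremer_k)
    bremer <- bremer_support(m, search, max_k = bremer_k,
                             outgroup = outgroup)
  }

  mapping <- optimize_all(cons, m, policy = policy)
  rates <- NULL
  if (!is.null(groups) && !is.null(categories)) {
    say("grade-segment rates (policy %s)", policy)
    rates <- segment_rates(cons, m, groups, categories, policy = policy)
  }

  say("disparity (Gower + PCoA)")
  gd <- gower_distance(m)
  ord <- pcoa(gd)
  heat <- similarity_heatmap_export(gd, consensus_leaf_order(cons))

  ts <- gaps <- NULL
  if (!is.null(ranges)) {
    say("time-scaling against stratigraphic ranges")
    ts <- timescale(cons, ranges, epsilon_ma = epsilon_ma)
    gaps <- record_gaps(ranges)
  }

  summary <- list(
    seed = seed,
    n_taxa = summ$n_taxa, n_characters = summ$n_characters,
    n_cells = summ$n_cells,
    pct_unknown = summ$pct_unknown,
    pct_inapplicable = summ$pct_inapplicable,
    pct_missing = summ$pct_missing,
    pct_polymorphic = summ$pct_polymorphic,
    n_uninformative = sum(!informative),
    mpt_count = search$n_trees,
    tree_length = search$length,
    ensemble_ci = fit$ci, ensemble_ri = fit$ri,
    ensemble_ci_informative_only = fit_excl$ci,
    ensemble_ri_informative_only = fit_excl$ri,
    n_consensus_branches = cons$Nnode - 1L,
    pcoa_pct_var_axis1 = ord$pct_variance[1L],
    pcoa_pct_var_axis2 = ord$pct_variance[2L],
    pcoa_pct_var_axes12 = sum(ord$pct_variance[1:2]),
    overall_rates = if (!is.null(rates)) as.list(rates$overall) else NULL,
    n_record_gaps = if (!is.null(gaps)) nrow(gaps) else NULL)

  report <- structure(list(matrix = m, summary_stats = summ,
                           informative = informative,
                           search = search, fit = fit,
                           strict = cons, majority = maj,
                           bootstrap = boot, bremer = bremer,
                           mapping = mapping, rates = rates,
                           gower = gd, pcoa = ord, heatmap = heat,
                           timescaled = ts, gaps = gaps,
                           summary = summary, seed = seed),
                      class = "morphclade_report")
  if (!is.null(out_dir)) write_outputs(report, out_dir)
  report
}

#' @export
print.morphclade_report <- function(x, ...) {
  s <- x$summary
  cat("morphclade pipeline report (seed ", s$seed, ")\n", sep = "")
  cat(sprintf("  matrix: %d taxa x %d characters, %.1f%% missing\n",
              s$n_taxa, s$n_characters, s$pct_missing))
  cat(sprintf("  search: %d MPT(s), length %d, CI %.3f, RI %.3f\n",
              s$mpt_count, s$tree_length, s$ensemble_ci, s$ensemble_ri))
  cat(sprintf("  consensus: %d internal branches; PCoA axes 1+2 = %.1f%%\n",
              s$n_consensus_branches, s$pcoa_pct_var_axes12))
  if (!is.null(s$overall_rates))
    cat("  overall change rates: ",
        paste(sprintf("%s %.3f", names(s$overall_rates),
                      unlist(s$overall_rates)), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Serialises the trees as Newick (the strict consensus additionally
#' with `bootstrap/Bremer` branch annotations), the support, fit, rate
#' and disparity tables as TSV, and the machine-readable summary as
#' JSON.  Trees and tables round-trip through [ape::read.tree()] and
#' [utils::read.delim()].
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  ape::write.tree(report$search$trees, fp("mpts.nwk"))
  ape::write.tree(report$strict, fp("strict_consensus.nwk"))
  ape::write.tree(report$majority, fp("majority_consensus.nwk"))
  annotated <- annotate_support(report$strict, report$bootstrap,
                                report$bremer)
  ape::write.tree(annotated, fp("strict_consensus_annotated.nwk"))
  tsv <- function(d, f) utils::write.table(d, fp(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(report$fit$per_character, "character_fits.tsv")
  if (!is.null(report$bootstrap)) tsv(report$bootstrap, "bootstrap.tsv")
  if (!is.null(report$bremer)) tsv(report$bremer, "bremer.tsv")
  if (!is.null(report$rates)) {
    tsv(report$rates$by_category, "rates_by_category.tsv")
    utils::write.table(report$rates$rates, fp("rates_per_character.tsv"),
                       sep = "\t", quote = FALSE)
  }
  utils::write.table(report$gower$d, fp("gower_distance.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(report$heatmap, fp("similarity.tsv"),
                     sep = "\t", quote = FALSE)
  coords <- data.frame(taxon = rownames(report$pcoa$coordinates),
                       report$pcoa$coordinates)
  tsv(coords, "pcoa_coordinates.tsv")
  if (!is.null(report$gaps)) tsv(report$gaps, "record_gaps.tsv")
  jsonlite::write_json(report$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# attach "bootstrap/bremer" labels to consensus internal nodes, matching
# bipartitions by their sorted taxon-label key
annotate_support <- function(cons, boot, bremer) {
  taxa <- sort.int(cons$tip.label)
  tr <- phylo_to_ptree(cons, taxa)
  below <- ptree_clades(tr)
  root <- ptree_root(tr)
  allt <- below[[root]]
  n <- tr$nleaf
  lab <- character(cons$Nnode)
  for (v in seq.int(n + 1L, length(tr$parent))) {
    if (v == root) next
    ids <- below[[v]]
    if (1L %in% ids) ids <- setdiff(allt, ids)
    lk <- paste(sort(taxa[ids]), collapse = "|")
    b1 <- if (!is.null(boot)) boot$bootstrap[match(lk, boot$label_key)] else NA
    b2 <- if (!is.null(bremer)) bremer$bremer[match(lk, bremer$label_key)] else NA
    if (!is.na(b1) || !is.na(b2))
      lab[v - n] <- paste0(ifelse(is.na(b1), "", round(b1)), "/",
                           ifelse(is.na(b2), "", b2))
  }
  cons$node.label <- lab
  cons
}
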