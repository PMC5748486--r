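#' Default pipeline configuration
#'
#' @param ... Overrides for: `seed`, `min_alt` (2), `max_germline_alt` (1),
#'   `min_depth` (10), `mask_mode_heatmap` ("drop"),
#'   `mask_mode_tree` ("missing"), `exhaustive_limit` (9), `restarts` (10),
#'   `coding_only` (FALSE).
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1L, min_alt = 2L, max_germline_alt = 1L,
              min_depth = 10L, mask_mode_heatmap = "drop",
              mask_mode_tree = "missing", exhaustive_limit = 9L,
              restarts = 10L, coding_only = FALSE)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    .stop_invalid("unknown config option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a flat key-value YAML configuration file
#'
#' @param path YAML file of scalar options (see [pipeline_config()]).
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

.log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full ITH analysis pipeline
#'
#' Orchestrates: read counts -> presence calling and sharing -> coverage
#' masks -> mutational spectrum and CpG test -> sample phylogeny ->
#' binary-distance clustering -> concordance / purity / clone-block
#' statistics, and writes the newick tree, per-edge support and homoplasy
#' tables, spectrum table and test JSON, ordered heatmap matrix, distance
#' matrix, concordance and purity tables, and a single machine-readable
#' JSON summary.  Deterministic given the configuration seed; progress and
#' filter counts are logged to stderr.
#'
#' @param x A manifest path, manifest data.frame, or [read_counts()]
#'   object.
#' @param config A [pipeline_config()] list (or overrides as `...` via
#'   `pipeline_config`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results (`counts`, `presence`
#'   (tree-mask), `presence_heatmap`, `spectrum`, `cpg_test`, `tree`,
#'   `clustering`, `concordance`, `purity`, `purity_test`,
#'   `matched_pair_test`, `clone_blocks`, `summary`).
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]

  counts <- if (inherits(x, "read_counts")) x else read_cohort(x)
  .log_stage("read", nrow(counts$alt), " candidate mutations, ",
             ncol(counts$alt), " samples")

  presence0 <- call_presence(counts, min_alt = config$min_alt,
                             max_germline_alt = config$max_germline_alt)
  lg <- presence0$filter_log
  .log_stage("presence", lg$admitted, " admitted; ",
             length(lg$germline_excluded), " germline-excluded; ",
             length(lg$uncalled), " uncalled")

  heat <- apply_coverage_mask(presence0, counts, min_depth = config$min_depth,
                              mode = config$mask_mode_heatmap)
  treemat <- apply_coverage_mask(presence0, counts,
                                 min_depth = config$min_depth,
                                 mode = config$mask_mode_tree)
  .log_stage("mask", length(heat$filter_log$mask_dropped),
             " regional mutations dropped for the heatmap matrix (depth < ",
             config$min_depth, " in a negative sample)")

  spec_tab <- spectrum_table(presence0)
  cpg <- tryCatch(cpg_enrichment_test(spec_tab),
                  error = function(e) {
                    .log_stage("spectrum", "CpG test skipped: ",
                               conditionMessage(e))
                    NULL
                  })
  write_spectrum_tsv(spec_tab, file.path(out_dir, "spectrum.tsv"))
  if (!is.null(cpg))
    jsonlite::write_json(cpg[c("statistic", "df", "p.value")],
                         file.path(out_dir, "spectrum_test.json"),
                         auto_unbox = TRUE, digits = NA)

  n_samples <- ncol(treemat$state)
  method <- if (n_samples <= config$exhaustive_limit) "exhaustive"
            else "hill_climb"
  if (method == "hill_climb")
    .log_stage("phylo", n_samples, " samples exceed the exhaustive limit (",
               config$exhaustive_limit, "); falling back to hill_climb")
  tree <- best_tree(treemat, method = method,
                    exhaustive_limit = config$exhaustive_limit,
                    restarts = config$restarts, seed = config$seed)
  .log_stage("phylo", "best tree score ", tree$score, "/",
             tree$score + length(tree$homoplasy), " compatible")
  writeLines(to_newick(tree), file.path(out_dir, "tree.nwk"))
  supp <- data.frame(edge_above = c(tree$labels,
                                    rep("internal", tree$n_tip - 1L)),
                     node = seq_along(tree$parent),
                     support = tree$support,
                     is_trunk = tree$parent == 0L)
  write.table(supp, file.path(out_dir, "edge_support.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(mutation = tree$homoplasy),
              file.path(out_dir, "homoplasy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  d <- binary_distance_matrix(heat)
  clustering <- if (anyNA(d)) NULL else average_linkage(d)
  write.table(round(d, 5), file.path(out_dir, "distance.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  leaf_order <- if (!is.null(clustering))
    clustering$labels[clustering$order] else colnames(heat$state)
  ord <- order(factor(heat$sharing, levels = c("shared", "regional")),
               -heat$carrier_n)
  heat_out <- heat$af[ord, leaf_order, drop = FALSE]
  write.table(round(heat_out, 4), file.path(out_dir, "heatmap_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)

  smp <- counts$samples
  has_pairs <- any(smp$role == "biopsy") && any(smp$role == "spheroid")
  concordance <- NULL
  matched_test <- NULL
  purity_test <- NULL
  if (has_pairs) {
    concordance <- concordance_stats(heat, coding_only = config$coding_only)
    write.table(concordance$per_area,
                file.path(out_dir, "concordance_areas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(concordance$per_sample,
                file.path(out_dir, "private_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    matched_test <- tryCatch(matched_pair_distance_test(tree, heat),
                             error = function(e) NULL)
  }

  truncal_ids <- rownames(presence0$state)[
    presence0$carrier_n == ncol(presence0$state)]
  purity <- suppressWarnings(purity_from_af(presence0, truncal_ids))
  write.table(purity, file.path(out_dir, "purity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (has_pairs) {
    pa <- merge(purity, smp, by = "sample")
    bt <- pa[pa$role == "biopsy", ]
    st <- pa[pa$role == "spheroid", ]
    common <- intersect(bt$area, st$area)
    if (length(common) >= 2L) {
      purity_test <- signed_rank_test(
        st$estimate[match(common, st$area)],
        bt$estimate[match(common, bt$area)])
    }
  }

  blocks <- NULL
  lnms <- smp$sample[smp$role == "lnm"]
  tumors <- smp$sample[smp$role == "biopsy"]
  if (length(lnms) >= 1L && length(tumors) >= 2L) {
    patterns <- list(
      nonmetastatic = list(present_all = tumors, absent_all = lnms))
    for (r in tumors)
      patterns[[paste0("metastatic_via_", r)]] <-
        list(present_all = c(lnms, r), absent_all = setdiff(tumors, r))
    blocks <- clone_blocks(treemat, patterns)
    jsonlite::write_json(blocks, file.path(out_dir, "clone_blocks.json"))
  }

  summary <- list(
    seed = config$seed,
    config = config[order(names(config))],
    n_samples = ncol(counts$alt),
    n_candidate_mutations = nrow(counts$alt),
    filters = list(
      admitted = presence0$filter_log$admitted,
      germline_excluded = length(presence0$filter_log$germline_excluded),
      uncalled = length(presence0$filter_log$uncalled),
      mask_dropped = length(heat$filter_log$mask_dropped)),
    sharing = as.list(table(presence0$sharing)),
    tree = list(newick = to_newick(tree), score = tree$score,
                homoplasy = length(tree$homoplasy), method = method),
    cpg_test = if (!is.null(cpg)) cpg[c("statistic", "df", "p.value")],
    concordance = if (!is.null(concordance))
      setNames(as.list(concordance$per_area$concordance),
               concordance$per_area$area),
    mean_private_fraction = if (!is.null(concordance))
      mean(concordance$per_sample$private_fraction),
    purity = setNames(as.list(purity$estimate), purity$sample),
    purity_spheroid_vs_biopsy_p = if (!is.null(purity_test))
      purity_test$p.value,
    matched_vs_cross_p = if (!is.null(matched_test)) matched_test$p.value,
    clone_blocks = if (!is.null(blocks)) lapply(blocks, length))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_presence_tsv(heat, file.path(out_dir, "presence_matrix.tsv"))
  .log_stage("done", "elapsed ",
             round(proc.time()[["elapsed"]] - t0, 2), "s; outputs in ",
             out_dir)

  invisible(list(counts = counts, presence = treemat,
                 presence_heatmap = heat, spectrum = spec_tab,
                 cpg_test = cpg, tree = tree, clustering = clustering,
                 distance = d, concordance = concordance, purity = purity,
                 purity_test = purity_test, matched_pair_test = matched_test,
                 clone_blocks = blocks, summary = summary))
}
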