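panel_meta_columns <- function() {
  c("id", "wave", "timestamp", "response_time_seconds",
    "age", "sex", "ethnicity_minority", "birth_rural", "chronic_condition",
    "mental_history", "family_history", "psychotic_history", "refused")
}

panel_covariate_columns <- function() {
  c("age", "sex", "ethnicity_minority", "birth_rural", "chronic_condition",
    "mental_history", "family_history")
}

#' Read a two-wave panel dataset from CSV
#'
#' Reads one row per participant per wave, checks the expected metadata and
#' item columns, and bounds-checks every item value against its instrument's
#' response scale; out-of-range values are reported with row and column.
#'
#' @param path CSV file path.
#' @param instruments instrument specs defining the item columns and scales.
#' @return the validated panel data.frame.
#' @export
read_panel_csv <- function(path, instruments = default_instruments()) {
  if (!file.exists(path)) fail("read_panel_csv: no such file: %s", path)
  data <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e)
                     fail("read_panel_csv: cannot parse '%s': %s", path,
                          conditionMessage(e)))
  if (nrow(data) == 0) fail("read_panel_csv: '%s' contains no records", path)
  needed <- c(panel_meta_columns(),
              unlist(lapply(instruments, `[[`, "items"), use.names = FALSE))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0)
    fail("read_panel_csv: missing column(s): %s",
         paste(missing_cols, collapse = ", "))
  for (spec in instruments) {
    m <- as.matrix(data[, spec$items, drop = FALSE])
    bad <- which(!is.na(m) & (m < spec$scale_min | m > spec$scale_max),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      fail("read_panel_csv: value %s out of range [%d, %d] at row %d, column '%s'",
           format(m[bad[1, 1], bad[1, 2]]), spec$scale_min, spec$scale_max,
           bad[1, 1], spec$items[bad[1, 2]])
  }
  data
}

#' Write a panel dataset to CSV
#'
#' @param data panel data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a network's weight matrix (and edge list) to CSV
#'
#' The matrix is written at full floating precision (`%.17g`); display
#' rounding belongs in human-readable reports only.
#'
#' @param net a `clpn` object.
#' @param path matrix CSV path; the edge list goes to
#'   `<path stem>_edges.csv`.
#' @param threshold display threshold for the edge list export.
#' @return `path`, invisibly.
#' @export
write_clpn_csv <- function(net, path, threshold = 0) {
  W <- clpn_weight_matrix(net)
  txt <- matrix(sprintf("%.17g", W), nrow(W), ncol(W), dimnames = dimnames(W))
  write.csv(txt, path, quote = FALSE, row.names = TRUE)
  edges <- display_threshold(net, threshold)
  write.csv(edges, sub("\\.csv$", "_edges.csv", path), row.names = FALSE)
  invisible(path)
}

#' Read a weight matrix written by [write_clpn_csv()]
#' @param path matrix CSV path.
#' @return numeric matrix.
#' @export
read_clpn_csv <- function(path) {
  as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed; fans out to stage seeds via [derive_seed()].
#' @param cutoff baseline screening cut-off used to split the cohort.
#' @param min_group_n abort if either group is smaller than this after the
#'   split (default 250, ten participants per node).
#' @param fit a [fit_config()] template (its seed is replaced by derived
#'   stage seeds).
#' @param rules an [exclusion_rules()] object.
#' @param bootstrap_iterations nonparametric bootstrap size (0 disables).
#' @param casedrop_iterations case-drop subsamples per grid level
#'   (0 disables).
#' @param casedrop_grid drop-proportion grid.
#' @param instruments instrument specs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cutoff = 1.57,
                            min_group_n = 250L,
                            fit = fit_config(),
                            rules = exclusion_rules(),
                            bootstrap_iterations = 0L,
                            casedrop_iterations = 0L,
                            casedrop_grid = seq(0.10, 0.75, by = 0.05),
                            instruments = default_instruments()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), cutoff = cutoff,
                 min_group_n = as.integer(min_group_n), fit = fit,
                 rules = rules,
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 casedrop_iterations = as.integer(casedrop_iterations),
                 casedrop_grid = casedrop_grid,
                 instruments = instruments),
            class = "pipeline_config")
}

#' Run the full two-group network pipeline
#'
#' Executes score -> exclude -> follow-up restriction -> baseline cut-off
#' split -> per-group standardization and CLPN fit -> centrality ->
#' (optional) bootstraps -> between-group comparison, writing every artifact
#' plus a machine-readable JSON run manifest (package version, seed, derived
#' stage seeds, per-stage participant counts). Any stage failure aborts with
#' the stage name. Re-running with the same data, config and seed reproduces
#' every numeric output bit-identically.
#'
#' @param data panel data.frame (e.g. from [generate_cohort()] +
#'   [inject_admin_artifacts()], or [read_panel_csv()]).
#' @param config a [pipeline_config()].
#' @return list of class `clpn_pipeline` with elements `flow`, `groups`
#'   (per-group n, network, centrality, optional boot/stability),
#'   `comparison`, `transitions`, `manifest`.
#' @export
run_pipeline <- function(data, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      fail("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  excl <- stage("exclusions", apply_exclusions(data, config$rules))
  kept <- stage("followup", complete_followup(excl$data))
  ids <- sort(unique(kept$id[kept$wave == 1]))

  w1 <- stage("scoring", node_scores(kept, 1, config$instruments))
  w2 <- stage("scoring", node_scores(kept, 2, config$instruments))
  cape1 <- kept[kept$wave == 1, , drop = FALSE]
  cape1 <- cape1[order(cape1$id), , drop = FALSE]
  cape2 <- kept[kept$wave == 2, , drop = FALSE]
  cape2 <- cape2[order(cape2$id), , drop = FALSE]
  score1 <- cape_weighted_score(cape1[, config$instruments$cape$items],
                                config$instruments$cape)
  score2 <- cape_weighted_score(cape2[, config$instruments$cape$items],
                                config$instruments$cape)
  class1 <- classify_ples(score1, config$cutoff)
  class2 <- classify_ples(score2, config$cutoff)
  transitions <- stage("transitions", transition_rates(class1, class2))

  covars <- cape1[, panel_covariate_columns(), drop = FALSE]
  split_idx <- stage("split", {
    pos <- which(class1 == "positive"); neg <- which(class1 == "negative")
    if (length(pos) < config$min_group_n || length(neg) < config$min_group_n)
      fail("group below the configured minimum (positive %d, negative %d, minimum %d)",
           length(pos), length(neg), config$min_group_n)
    list(positive = pos, negative = neg)
  })

  groups <- list()
  for (gname in names(split_idx)) {
    idx <- split_idx[[gname]]
    g1 <- w1$scores[idx, , drop = FALSE]
    g2 <- w2$scores[idx, , drop = FALSE]
    gcov <- covars[idx, , drop = FALSE]
    cfg <- config$fit
    cfg$seed <- derive_seed(config$seed, paste0("fit:", gname))
    net <- stage(paste0("fit:", gname), fit_clpn(g1, g2, gcov, cfg))
    cent <- centrality_table(net)
    res <- list(n = length(idx), network = net, centrality = cent)
    if (config$bootstrap_iterations > 0)
      res$boot <- stage(paste0("bootstrap:", gname),
        bootstrap_edge_cis(g1, g2, gcov, cfg,
                           iterations = config$bootstrap_iterations,
                           seed = derive_seed(config$seed,
                                              paste0("boot:", gname))))
    if (config$casedrop_iterations > 0)
      res$stability <- stage(paste0("casedrop:", gname),
        case_drop_bootstrap(g1, g2, gcov, cfg,
                            grid = config$casedrop_grid,
                            iterations = config$casedrop_iterations,
                            seed = derive_seed(config$seed,
                                               paste0("casedrop:", gname))))
    groups[[gname]] <- res

    write_clpn_csv(net, file.path(config$out_dir,
                                  sprintf("network_%s.csv", gname)))
    write.csv(cent, file.path(config$out_dir,
                              sprintf("centrality_%s.csv", gname)),
              row.names = FALSE)
    write_clpn_graphml(net, file.path(config$out_dir,
                                      sprintf("network_%s.graphml", gname)))
    if (!is.null(res$stability))
      write.csv(stability_curves(res$stability),
                file.path(config$out_dir,
                          sprintf("stability_%s.csv", gname)),
                row.names = FALSE)
  }

  comparison <- stage("comparison",
                      compare_networks(groups$positive$network,
                                       groups$negative$network))

  manifest <- list(
    package = "clpnet",
    version = as.character(utils::packageVersion("clpnet")),
    seed = config$seed,
    cutoff = config$cutoff,
    stage_seeds = list(
      fit_positive = derive_seed(config$seed, "fit:positive"),
      fit_negative = derive_seed(config$seed, "fit:negative"),
      boot_positive = derive_seed(config$seed, "boot:positive"),
      boot_negative = derive_seed(config$seed, "boot:negative"),
      casedrop_positive = derive_seed(config$seed, "casedrop:positive"),
      casedrop_negative = derive_seed(config$seed, "casedrop:negative")),
    counts = list(
      input_baseline_records = sum(data$wave == 1),
      valid_baseline = excl$flow$remaining[nrow(excl$flow)],
      lost_to_followup = attr(kept, "lost_to_followup"),
      analyzed = length(ids),
      positive = groups$positive$n,
      negative = groups$negative$n),
    flow = excl$flow,
    bootstrap_iterations = config$bootstrap_iterations,
    casedrop_iterations = config$casedrop_iterations)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    list(matrix_correlation = comparison$matrix_correlation,
         replication = comparison$replication[c("proportion", "replicated",
                                                "total")],
         centrality_correlations = lapply(comparison$centrality_correlations,
                                          function(x) x[c("r", "p")]),
         transitions = list(persistence = transitions$persistence,
                            incidence = transitions$incidence,
                            counts = as.list(transitions$counts))),
    file.path(config$out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(flow = excl$flow,
                            lost_to_followup = attr(kept, "lost_to_followup"),
                            analyzed = length(ids)),
                       file.path(config$out_dir, "flow.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  structure(list(flow = excl$flow, groups = groups, comparison = comparison,
                 transitions = transitions, manifest = manifest),
            class = "clpn_pipeline")
}

#' @export
print.clpn_pipeline <- function(x, ...) {
  cat(sprintf("<clpn_pipeline> analyzed %d participants (positive %d / negative %d)\n",
              x$manifest$counts$analyzed, x$manifest$counts$positive,
              x$manifest$counts$negative))
  print(x$comparison)
  invisible(x)
}
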