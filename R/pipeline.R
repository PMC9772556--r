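#' Run configuration for the integrated pipeline
#'
#' Collects the analysis thresholds, the seed, and the output directory,
#' validating each threshold against its documented range. Defaults are the
#' values used throughout the VPA-model study design: lectin fold-change
#' threshold 1.2, DEGG adjusted-p cutoff 0.05, DEGG fold filter 1.5,
#' network confidence cutoff 0.4, MCL inflation 2.0.
#'
#' @param lectin_fc Lectin fold-change call threshold (>= 1).
#' @param degg_alpha Adjusted-p cutoff for DEGGs (in (0, 1]).
#' @param fold DEGG fold filter (>= 1).
#' @param network_cutoff Network confidence cutoff (in \[0, 1\]).
#' @param inflation MCL inflation (> 1).
#' @param seed Integer seed used for any randomness.
#' @param out_dir Optional output directory; created if missing.
#' @return Named list of class `glyco_config`.
#' @export
glyco_config <- function(lectin_fc = 1.2, degg_alpha = 0.05, fold = 1.5,
                         network_cutoff = 0.4, inflation = 2.0,
                         seed = 1L, out_dir = NULL) {
  if (!is.numeric(lectin_fc) || lectin_fc < 1) {
    stop("config error: lectin_fc must be >= 1")
  }
  if (!is.numeric(degg_alpha) || degg_alpha <= 0 || degg_alpha > 1) {
    stop("config error: degg_alpha must lie in (0, 1]")
  }
  if (!is.numeric(fold) || fold < 1) stop("config error: fold must be >= 1")
  if (!is.numeric(network_cutoff) || network_cutoff < 0 || network_cutoff > 1) {
    stop("config error: network_cutoff must lie in [0, 1]")
  }
  if (!is.numeric(inflation) || inflation <= 1) {
    stop("config error: inflation must exceed 1")
  }
  cfg <- list(lectin_fc = lectin_fc, degg_alpha = degg_alpha, fold = fold,
              network_cutoff = network_cutoff, inflation = inflation,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "glyco_config"
  cfg
}

config_echo <- function(config) {
  config[c("lectin_fc", "degg_alpha", "fold", "network_cutoff",
           "inflation", "seed")]
}

write_summary_json <- function(summary, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, paste0(name, "_summary.json"))
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Lectin-microarray stage
#'
#' Accepts either spot-level measurements (full chain: background filter,
#' block normalization, slide/sample/group aggregation) or an NFI summary
#' table with `nfi_control`/`nfi_case` columns, then computes signed fold
#' changes and calls significant lectins.
#'
#' @param input Path to a TSV, or a data.frame: spot layout (see
#'   [read_spot_tsv()]) or NFI summary (`lectin`, `nfi_control`,
#'   `nfi_case`).
#' @param config A [glyco_config()].
#' @param control,case Group labels for the spot-level route.
#' @return List with `fc_table` (with calls) and `summary` (counts,
#'   thresholds, config echo). Writes `lectin_fc.tsv` and
#'   `lectin_summary.json` when `config$out_dir` is set.
#' @export
run_lectin <- function(input, config = glyco_config(),
                       control = "control", case = "case") {
  df <- if (is.character(input)) {
    if (!file.exists(input)) stop("missing input file: ", input)
    utils::read.delim(input, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  } else input
  if (all(c("nfi_control", "nfi_case") %in% names(df))) {
    fc_table <- df[, intersect(c("lectin", "nfi_control", "nfi_case", "fc"),
                               names(df))]
    if (!("fc" %in% names(fc_table))) {
      fc_table$fc <- signed_fold_change(fc_table$nfi_control,
                                        fc_table$nfi_case)
    }
  } else {
    validate_spots(df)
    profiles <- spot_profiles(df)
    agg <- aggregate_sample(profiles)
    fc_table <- lectin_fold_changes(agg$group_nfi, control = control,
                                    case = case)
  }
  calls <- call_significant_lectins(fc_table, threshold = config$lectin_fc)
  summary <- list(stage = "lectin",
                  n_lectins = nrow(calls),
                  n_significant = attr(calls, "n_significant"),
                  n_up = sum(calls$call == "up"),
                  n_down = sum(calls$call == "down"),
                  config = config_echo(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fold_change_tsv(calls, file.path(config$out_dir, "lectin_fc.tsv"))
    write_summary_json(summary, config, "lectin")
  }
  list(fc_table = calls, summary = summary)
}

#' DEGG identification stage
#'
#' @param de DE results table (path or data.frame; see [read_de_table()]).
#' @param gene_list A `glyco_gene_list`, or `NULL` to use the packaged
#'   curated list via [build_gene_table()].
#' @param config A [glyco_config()].
#' @param readjust Recompute `padj` with [bh_adjust()].
#' @return List with `deggs`, `down`, `up`, and `summary`.
#' @export
run_degg <- function(de, gene_list = NULL, config = glyco_config(),
                     readjust = FALSE) {
  de_df <- if (is.character(de)) {
    if (!file.exists(de)) stop("missing input file: ", de)
    read_de_table(de, readjust = readjust)
  } else {
    if (readjust) de$padj <- bh_adjust(de$pvalue)
    de
  }
  if (is.null(gene_list)) gene_list <- assemble_gene_list(build_gene_table())
  deggs <- intersect_with_gene_list(de_df, gene_list,
                                    alpha = config$degg_alpha)
  split <- filter_by_fold(deggs, fold = config$fold)
  summary <- list(stage = "degg",
                  n_de_input = nrow(de_df),
                  n_deggs = nrow(deggs),
                  n_down_at_fold = nrow(split$down),
                  n_up_at_fold = nrow(split$up),
                  n_unresolved = attr(deggs, "n_unresolved"),
                  group_counts = as.list(attr(deggs, "group_counts")),
                  config = config_echo(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_degg_report(deggs, file.path(config$out_dir, "degg_report.tsv"))
    write_summary_json(summary, config, "degg")
  }
  list(deggs = deggs, down = split$down, up = split$up, summary = summary)
}

#' Integration stage: motif concordance, optional ORA and MCL
#'
#' @param lectin_calls Fold-change table with calls (from [run_lectin()]).
#' @param deggs DEGG table (from [run_degg()]).
#' @param actions Enzyme-action catalog (path or data.frame); defaults to
#'   the packaged catalog.
#' @param catalog Lectin catalog (path or data.frame); defaults to the
#'   packaged catalog.
#' @param network Optional edge list (path or data.frame) for MCL.
#' @param annotation Optional GMT path or named list for ORA over the DEGG
#'   symbols.
#' @param config A [glyco_config()].
#' @return List with `concordance`, optional `partition` and `enrichment`,
#'   and `summary`.
#' @export
run_integrate <- function(lectin_calls, deggs,
                          actions = glycolink_extdata("enzyme_actions.tsv"),
                          catalog = glycolink_extdata("lectin_catalog.tsv"),
                          network = NULL, annotation = NULL,
                          config = glyco_config()) {
  act <- if (is.character(actions)) load_enzyme_actions(actions) else actions
  cat_df <- if (is.character(catalog)) load_lectin_catalog(catalog) else catalog
  conc <- concordance_report(lectin_calls, deggs, act, cat_df,
                             floor = config$lectin_fc)
  out <- list(concordance = conc)
  summary <- list(stage = "integrate",
                  n_motifs = nrow(conc$records),
                  n_evaluable = sum(conc$records$evaluable),
                  n_concordant = sum(conc$records$concordant),
                  concordance_fraction = conc$summary,
                  config = config_echo(config))
  if (!is.null(network)) {
    edges <- if (is.character(network)) read_network_tsv(network) else network
    out$partition <- mcl_cluster(edges, cutoff = config$network_cutoff,
                                 inflation = config$inflation)
    summary$n_clusters <- length(out$partition$clusters)
  }
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) read_gmt(annotation) else annotation
    out$enrichment <- ora_enrichment(unique(deggs$symbol), ann)
    summary$n_enriched_terms <- sum(out$enrichment$padj < 0.05)
  }
  out$summary <- summary
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(conc$records,
                       file.path(config$out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_summary_json(summary, config, "integrate")
  }
  out
}

#' Behavioral stage
#'
#' @param behavior Path to a behavior TSV or a data.frame (see
#'   [read_behavior_tsv()]).
#' @param config A [glyco_config()].
#' @param control,case Group labels.
#' @return List with `report` (per-measure tests) and `summary`.
#' @export
run_behavior <- function(behavior, config = glyco_config(),
                         control = "control", case = "case") {
  df <- if (is.character(behavior)) {
    if (!file.exists(behavior)) stop("missing input file: ", behavior)
    read_behavior_tsv(behavior)
  } else behavior
  report <- behavior_report(df, control = control, case = case)
  summary <- list(stage = "behavior",
                  n_control = sum(df$group == control),
                  n_case = sum(df$group == case),
                  si_mean_control = mean(df$si[df$group == control],
                                         na.rm = TRUE),
                  si_mean_case = mean(df$si[df$group == case], na.rm = TRUE),
                  config = config_echo(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(config$out_dir, "behavior_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_summary_json(summary, config, "behavior")
  }
  list(report = report, summary = summary)
}

#' Generate a full synthetic input bundle
#'
#' Produces seeded lectin slides, a count matrix with planted glycan-gene
#' effects, a behavioral table, and a modular network, together with their
#' ground truth.
#'
#' @param config A [glyco_config()] whose `seed` drives every generator.
#' @param planted_lectin_fc,planted_log2fc Planted effects forwarded to the
#'   generators (defaults give a small worked example).
#' @return List with `lectin`, `counts`, `behavior`, `network` simulation
#'   objects. When `config$out_dir` is set, writes the TSV inputs and a
#'   `truth.json`.
#' @export
run_simulate <- function(config = glyco_config(),
                         planted_lectin_fc = c(ConA = 1.8, GNA = -3.3),
                         planted_log2fc = c(g1 = 1, g2 = -1)) {
  lectin <- simulate_lectin_slides(planted_fc = planted_lectin_fc,
                                   seed = config$seed)
  counts <- simulate_counts(planted = planted_log2fc, seed = config$seed)
  behavior <- simulate_behavior(seed = config$seed)
  network <- simulate_network(seed = config$seed)
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(lectin$spots, file.path(d, "spots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = rownames(counts$counts),
                                  counts$counts, check.names = FALSE),
                       file.path(d, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(behavior, file.path(d, "behavior.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(network$edges, file.path(d, "network.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_truth_json(list(lectin = lectin$truth,
                          counts = counts$truth,
                          network = network$truth,
                          seed = config$seed),
                     file.path(d, "truth.json"))
  }
  list(lectin = lectin, counts = counts, behavior = behavior,
       network = network)
}

#' Run the full integrated pipeline on a synthetic bundle or user inputs
#'
#' With no inputs, simulates a bundle under `config$seed` and runs every
#' stage on it; with explicit inputs, runs the stages the inputs cover.
#'
#' @param config A [glyco_config()].
#' @param spots,de,behavior,network Optional stage inputs (paths or
#'   data.frames). When all are `NULL` a seeded synthetic bundle is used.
#' @param gene_list Optional `glyco_gene_list` (default: packaged list).
#' @return List with per-stage results and a combined `summary`.
#' @export
run_all <- function(config = glyco_config(), spots = NULL, de = NULL,
                    behavior = NULL, network = NULL, gene_list = NULL) {
  if (is.null(gene_list)) gene_list <- assemble_gene_list(build_gene_table())
  simulated <- is.null(spots) && is.null(de) && is.null(behavior)
  if (simulated) {
    glyco_ids <- gene_list$records$gene_id
    planted_genes <- as.character(glyco_ids[seq_len(30)])
    planted <- stats::setNames(rep(c(2, -2), length.out = 30),
                               planted_genes)
    sim_counts <- simulate_counts(n_genes = 2000,
                                  gene_ids = c(planted_genes,
                                               sprintf("x%d", seq_len(2000 - 30))),
                                  planted = planted, seed = config$seed)
    sim_lectin <- simulate_lectin_slides(planted_fc = c(ConA = 1.8,
                                                        GNA = -3.3,
                                                        WGA = -2.6),
                                         seed = config$seed)
    spots <- sim_lectin$spots
    de_res <- nb_de_test(sim_counts$counts, sim_counts$groups)
    de <- data.frame(gene_id = de_res$gene_id, symbol = NA_character_,
                     log2fc = de_res$log2fc, pvalue = de_res$pvalue,
                     padj = de_res$padj, stringsAsFactors = FALSE)
    behavior <- simulate_behavior(seed = config$seed)
  }
  lectin <- run_lectin(spots, config = config)
  degg <- if (!is.null(de)) run_degg(de, gene_list = gene_list,
                                     config = config) else NULL
  integ <- if (!is.null(degg)) {
    run_integrate(lectin$fc_table, degg$deggs, network = network,
                  config = config)
  } else NULL
  behav <- if (!is.null(behavior)) run_behavior(behavior, config = config)
           else NULL
  summary <- list(pipeline = "glycolink",
                  config = config_echo(config),
                  lectin = lectin$summary,
                  degg = if (!is.null(degg)) degg$summary,
                  integrate = if (!is.null(integ)) integ$summary,
                  behavior = if (!is.null(behav)) behav$summary)
  if (!is.null(config$out_dir)) write_summary_json(summary, config, "run_all")
  list(lectin = lectin, degg = degg, integrate = integ, behavior = behav,
       summary = summary)
}
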