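#' Configuration for a full synthetic pipeline run
#'
#' Bundles the synthetic-study design with every stage parameter so one
#' seeded object determines a complete run.
#'
#' @param synth A [synth_config()] describing the simulated study.
#' @param stages Character vector of stages to execute, in fixed order:
#'   `simulate`, `preprocess`, `network`, `correlate`, `preserve`,
#'   `score`, `scan`.
#' @param power Soft-threshold power; `NULL` selects it by
#'   [pick_soft_threshold()] (falling back to the best-fitting candidate
#'   when none meets the criterion).
#' @param min_module_size,deep_split,kme_keep,core_kme Network
#'   parameters; see [build_network()].
#' @param n_perm Preservation permutations; default 100.
#' @param dispersion,library_size Count-simulation parameters.
#' @param pwm A `songnet_pwm` for the promoter-scan stage; default is the
#'   package's synthetic forkhead-like fixture motif.
#' @param n_promoters,motif_rate Promoter-simulation parameters.
#' @param keep_fraction Edge fraction kept for visualization; default 0.02.
#' @param seed Master seed; stage sub-seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            stages = c("simulate", "preprocess", "network",
                                       "correlate", "preserve", "score", "scan"),
                            power = NULL,
                            min_module_size = 100,
                            deep_split = 2,
                            kme_keep = 0.3,
                            core_kme = 0.5,
                            n_perm = 100,
                            dispersion = 0.05,
                            library_size = 5e6,
                            pwm = NULL,
                            n_promoters = 100,
                            motif_rate = 0.5,
                            keep_fraction = 0.02,
                            seed = 1) {
  all_stages <- c("simulate", "preprocess", "network", "correlate",
                  "preserve", "score", "scan")
  stopifnot(all(stages %in% all_stages))
  if (is.null(pwm)) {
    pwm <- read_jaspar(system.file("extdata", "synthetic_foxp2_like.jaspar",
                                   package = "songnet"))
  }
  structure(list(
    synth = synth, stages = all_stages[all_stages %in% stages],
    power = power, min_module_size = min_module_size, deep_split = deep_split,
    kme_keep = kme_keep, core_kme = core_kme, n_perm = n_perm,
    dispersion = dispersion, library_size = library_size, pwm = pwm,
    n_promoters = n_promoters, motif_rate = motif_rate,
    keep_fraction = keep_fraction, seed = as.integer(seed)
  ), class = "pipeline_config")
}

require_stage <- function(run, what, producer) {
  if (is.null(run[[what]])) {
    stop("missing upstream output '", what, "': enable the '", producer,
         "' stage first", call. = FALSE)
  }
  run[[what]]
}

select_power <- function(expr, fit_cut = 0.8) {
  scan <- pick_soft_threshold(expr, fit_cut = fit_cut)
  if (!is.na(scan$selected)) return(scan$selected)
  ok <- !is.na(scan$scan$signed_r2)
  scan$scan$power[ok][which.max(scan$scan$signed_r2[ok])]
}

#' Run the full (or partial) synthetic analysis pipeline
#'
#' Executes the enabled stages in order — simulate the two-condition
#' study, preprocess counts to normalized expression, build the signed
#' network, correlate modules with behavior, assess cross-condition
#' module preservation, score annotation terms and interactions, and
#' scan promoters for the supplied motif — halting with a named error if
#' a stage's inputs are missing. The run is fully determined by the
#' config (including its seed).
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, tabular artifacts are
#'   written there as TSV/FASTA/JSON.
#' @return Object of class `pipeline_run`: stage outputs plus a `report`
#'   list recording the resolved parameters and per-stage summaries.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  run <- list(config = config)
  t0 <- Sys.time()

  if ("simulate" %in% config$stages) {
    sim <- simulate_expression(config$synth)
    run$expr_true <- sim$expr
    run$truth <- sim$truth
    run$traits <- simulate_traits(sim$truth, config$synth)
    run$expr_cond2 <- simulate_condition2(sim$expr, sim$truth, config$synth)
    n_genes <- nrow(sim$expr)
    lengths_seed <- derive_seed(config$synth$seed, 606L)
    run$gene_lengths <- withr::with_seed(lengths_seed, tibble::tibble(
      gene_id = sim$expr$gene_id,
      length = round(stats::rlnorm(n_genes, log(1500), 0.6)) + 200
    ))
    run$counts <- simulate_counts(sim$expr, run$gene_lengths,
                                  library_sizes = config$library_size,
                                  dispersion = config$dispersion,
                                  seed = derive_seed(config$synth$seed, 707L))
    run$annotations <- simulate_annotations(sim$truth,
                                            seed = derive_seed(config$synth$seed, 808L))
    run$interactions <- simulate_interactions(sim$truth,
                                              seed = derive_seed(config$synth$seed, 909L))
  }

  if ("preprocess" %in% config$stages) {
    counts <- require_stage(run, "counts", "simulate")
    run$preprocess <- preprocess_expression(counts, run$gene_lengths)
    run$expr <- run$preprocess$expr
  }

  if ("network" %in% config$stages) {
    expr <- require_stage(run, "expr", "preprocess")
    power <- config$power %||% select_power(expr)
    run$network <- build_network(
      expr, power = power,
      min_module_size = config$min_module_size, deep_split = config$deep_split,
      kme_keep = config$kme_keep, core_kme = config$core_kme)
    run$power <- power
  }

  if ("correlate" %in% config$stages) {
    net <- require_stage(run, "network", "network")
    traits <- require_stage(run, "traits", "simulate")
    expr_net <- run$expr[run$expr$gene_id %in% net$modules$gene_id, ]
    run$gene_significance <- gene_significance(expr_net, traits)
    run$module_trait <- module_trait_correlation(net$eigengenes, traits)
  }

  if ("preserve" %in% config$stages) {
    net <- require_stage(run, "network", "network")
    expr2 <- require_stage(run, "expr_cond2", "simulate")
    common2 <- expr2[expr2$gene_id %in% net$modules$gene_id, ]
    beta_test <- config$power %||% select_power(common2)
    run$preservation <- module_preservation(
      run$expr, expr2, net$modules,
      beta_test = beta_test, beta_ref = run$power,
      n_perm = config$n_perm, seed = derive_seed(config$seed, 1010L))
  }

  if ("score" %in% config$stages) {
    net <- require_stage(run, "network", "network")
    ann <- require_stage(run, "annotations", "simulate")
    inter <- require_stage(run, "interactions", "simulate")
    gs <- require_stage(run, "gene_significance", "correlate")
    trait1 <- names(gs)[2]
    run$term_scores <- score_terms(ann, net, gs = gs, trait = trait1)
    node_stats <- tibble::tibble(
      gene_id = net$modules$gene_id,
      k_in = net$modules$k_in,
      gs = gs[[trait1]][match(net$modules$gene_id, gs$gene_id)]
    )
    # interactions among genes the final network dropped carry no
    # connectivity statistics; exclude them up front
    inter_known <- dplyr::filter(inter, .data$gene_i %in% node_stats$gene_id &
                                   .data$gene_j %in% node_stats$gene_id)
    run$ranked_interactions <- scale_interactions(inter_known, node_stats, metric = 4)
    conf_ok <- dplyr::filter(inter, .data$confidence >= 0.9)
    kin <- stats::setNames(node_stats$k_in, node_stats$gene_id)
    widths <- tibble::tibble(
      gene_i = conf_ok$gene_i, gene_j = conf_ok$gene_j,
      weight = edge_width(conf_ok$confidence,
                          dplyr::coalesce(kin[conf_ok$gene_i], 0),
                          dplyr::coalesce(kin[conf_ok$gene_j], 0))
    )
    run$viz <- sparsify_for_viz(widths, keep_fraction = max(
      config$keep_fraction, 2 / max(nrow(widths), 1)))
  }

  if ("scan" %in% config$stages) {
    prom <- simulate_promoters(config$pwm, n = config$n_promoters,
                               motif_rate = config$motif_rate,
                               seed = derive_seed(config$seed, 1111L))
    run$promoters <- prom
    run$motif_hits <- scan_pwm(prom$sequences, config$pwm)
  }

  run$report <- list(
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("pwm", "synth"))],
    synth = unclass(config$synth)[c("n_samples", "module_sizes",
                                    "n_background_genes", "kme_targets",
                                    "preserved_modules", "noise_sd", "seed")],
    summaries = list(
      preprocess = if (!is.null(run$preprocess)) glance(run$preprocess),
      network = if (!is.null(run$network)) glance(run$network),
      preservation = if (!is.null(run$preservation)) glance(run$preservation)
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(run) <- "pipeline_run"
  if (!is.null(outdir)) write_pipeline_outputs(run, outdir)
  run
}

write_tsv_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$counts)) write_tsv_(run$counts, file.path(outdir, "counts.tsv"))
  if (!is.null(run$expr)) write_tsv_(run$expr, file.path(outdir, "expr.tsv"))
  if (!is.null(run$traits)) write_tsv_(run$traits, file.path(outdir, "traits.tsv"))
  if (!is.null(run$truth)) {
    jsonlite::write_json(list(
      modules = run$truth$modules, preserved = run$truth$preserved,
      trait_couplings = run$truth$trait_couplings
    ), file.path(outdir, "truth.json"))
  }
  if (!is.null(run$annotations)) {
    ann <- run$annotations
    ann$genes <- vapply(ann$genes, paste, character(1), collapse = ",")
    write_tsv_(ann, file.path(outdir, "annotations.tsv"))
  }
  if (!is.null(run$interactions)) {
    write_tsv_(run$interactions, file.path(outdir, "interactions.tsv"))
  }
  if (!is.null(run$network)) {
    write_tsv_(run$network$modules, file.path(outdir, "modules.tsv"))
    write_tsv_(run$network$eigengenes, file.path(outdir, "eigengenes.tsv"))
  }
  if (!is.null(run$module_trait)) {
    write_tsv_(run$module_trait, file.path(outdir, "module_trait.tsv"))
  }
  if (!is.null(run$gene_significance)) {
    write_tsv_(run$gene_significance, file.path(outdir, "gene_significance.tsv"))
  }
  if (!is.null(run$preservation)) {
    write_tsv_(run$preservation$report, file.path(outdir, "preservation.tsv"))
  }
  if (!is.null(run$term_scores)) {
    write_tsv_(run$term_scores, file.path(outdir, "term_scores.tsv"))
  }
  if (!is.null(run$ranked_interactions)) {
    write_tsv_(run$ranked_interactions, file.path(outdir, "ranked_interactions.tsv"))
  }
  if (!is.null(run$viz)) {
    write_gexf(run$viz, file.path(outdir, "network.gexf"),
               labels = run$network$modules)
  }
  if (!is.null(run$promoters)) {
    write_fasta(run$promoters$sequences, file.path(outdir, "promoters.fasta"))
  }
  if (!is.null(run$motif_hits)) {
    write_tsv_(run$motif_hits, file.path(outdir, "motif_hits.tsv"))
  }
  jsonlite::write_json(run$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, "): stages ",
      paste(x$config$stages, collapse = " -> "), "\n", sep = "")
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d genes, %d modules (power %s)\n",
                nrow(x$network$modules),
                length(unique(x$network$modules$module)), format(x$power)))
  }
  if (!is.null(x$preservation)) {
    cat("  preservation Zsummary range: ",
        paste(round(range(x$preservation$report$z_summary), 2), collapse = " .. "),
        "\n", sep = "")
  }
  invisible(x)
}
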