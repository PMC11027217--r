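# End-to-end orchestration: ingestion (real tables or the synthetic
# generator) -> co-administration -> stratified prevalence and gender
# relative risks -> null model -> significance-filtered network ->
# substitution intervention, with a manifest for reproducibility.

#' Pipeline configuration
#'
#' @param output_dir Directory for all stage outputs.
#' @param window A [study_window()].
#' @param synthetic Optional [synthetic_config()]; when supplied the four
#'   input tables are generated rather than read.
#' @param paths Named list of input files (`patients`, `dispensations`,
#'   `ddi`, `classes`) when not synthetic.
#' @param null_config A [null_model_config()].
#' @param fdr FDR threshold for the network edge set.
#' @param min_tau Strength filter applied when exporting the network.
#' @param intervention_target Drug id to substitute, or `NULL` to skip the
#'   intervention stage.
#' @param correction Multiplicity correction for gender relative risks.
#' @param seed Integer seed for the stochastic stages.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(output_dir, window, synthetic = NULL, paths = NULL,
                            null_config = null_model_config(),
                            fdr = 0.05, min_tau = 0,
                            intervention_target = NULL,
                            correction = c("fdr", "bonferroni"), seed = 1L) {
  correction <- match.arg(correction)
  abort_if(is.null(synthetic) && is.null(paths),
           "either a synthetic config or input paths must be given")
  stopifnot(inherits(window, "study_window"))
  structure(list(output_dir = output_dir, window = window,
                 synthetic = synthetic, paths = paths,
                 null_config = null_config, fdr = fdr, min_tau = min_tau,
                 intervention_target = intervention_target,
                 correction = correction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writing each stage's table(s) under the
#' configured output directory together with `manifest.json` recording the
#' configuration hash, seed, package version and per-file row counts and
#' checksums. A stage failure halts the run with the failing stage named;
#' outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  rows <- list()
  emit <- function(x, name) {
    p <- file.path(config$output_dir, name)
    write_table(x, p)
    outputs[[name]] <<- p
    rows[[name]] <<- nrow(x)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ingest <- stage("data_io", {
    if (!is.null(config$synthetic)) {
      pats <- generate_population(config$synthetic)
      disp <- generate_dispensations(pats, config$synthetic)
      ddi <- generate_ddi_reference(config$synthetic)
      classes <- generate_drug_classes(config$synthetic, ddi)
    } else {
      p <- config$paths
      pats <- read_patients(p$patients)
      disp <- read_dispensations(p$dispensations, config$window)
      ddi <- read_ddi_reference(p$ddi)
      classes <- if (!is.null(p$classes)) read_drug_classes(p$classes) else NULL
    }
    list(patients = pats, records = disp, ddi = ddi, classes = classes)
  })
  emit(ingest$patients, "patients.csv")
  emit(ingest$records, "dispensations.csv")
  emit(ingest$ddi, "ddi_reference.csv")
  if (!is.null(ingest$classes)) emit(ingest$classes, "drug_classes.csv")

  coad <- stage("coadministration", {
    runs <- coadmin_runs(ingest$records, ingest$ddi, config$window)
    episodes <- detect_pair_episodes(ingest$records, ingest$ddi, config$window)
    stats <- pair_population_stats(episodes, ingest$records)
    list(runs = runs, episodes = episodes, stats = stats)
  })
  emit(coad$episodes, "pair_episodes.csv")
  emit(coad$stats, "pair_stats.csv")

  prev <- stage("prevalence_risk", {
    pr <- compute_prevalence(coad$runs, ingest$records, ingest$patients)
    rr <- gender_relative_risks(pr, correction = config$correction)
    list(prevalence = pr, rr = rr)
  })
  emit(prev$prevalence, "prevalence.csv")
  emit(prev$rr, "gender_relative_risks.csv")

  nullm <- stage("null_model", {
    cfg <- config$null_config
    cfg$seed <- config$seed
    run_null_model(ingest$records, ingest$patients, ingest$ddi, config$window, cfg)
  })
  emit(nullm$summary, "null_model_summary.csv")
  emit(nullm$per_rep, "null_model_reps.csv")

  net <- stage("ddi_network", {
    sig <- pair_significance(coad$stats, data.table::uniqueN(ingest$records$patient_id),
                             fdr = config$fdr)
    g <- build_network(sig, coad$episodes, ingest$records, ingest$patients,
                       fdr = config$fdr)
    list(sig = sig, graph = g)
  })
  emit(net$sig, "pair_significance.csv")
  gpath <- file.path(config$output_dir, "ddi_network.graphml")
  export_network(net$graph, gpath, "graphml", min_tau = config$min_tau)
  outputs[["ddi_network.graphml"]] <- gpath
  rows[["ddi_network.graphml"]] <- igraph::ecount(net$graph)

  interv <- NULL
  if (!is.null(config$intervention_target) && !is.null(ingest$classes)) {
    interv <- stage("intervention", {
      plan <- plan_substitutions(ingest$records, config$intervention_target,
                                 ingest$classes, ingest$ddi, config$window)
      apply_and_recompute(ingest$records, ingest$patients, ingest$ddi,
                          config$window, plan)
    })
    emit(interv$strata, "intervention_report.csv")
    emit(interv$records_after, "dispensations_substituted.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ddiprev")),
    seed = config$seed,
    window = list(start = as.character(config$window$start),
                  end = as.character(config$window$end),
                  resolution = config$window$resolution),
    config_hash = config_hash(config),
    rows = rows,
    files = lapply(outputs, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ingest = ingest, coadmin = coad, prevalence = prev,
                 null_model = nullm, network = net, intervention = interv,
                 manifest = manifest))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  drop_fn <- function(x) {
    if (is.list(x)) lapply(x, drop_fn) else if (is.function(x)) NULL else x
  }
  writeLines(jsonlite::toJSON(drop_fn(unclass(config)), auto_unbox = TRUE,
                              force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Compare the co-administration profiles of two analysis runs
#'
#' Aligns the drug pairs shared by two populations and reports the Spearman
#' correlation of their per-pair co-administering patient counts, together
#' with the sizes of the drug and pair overlaps.
#'
#' @param stats_a,stats_b [pair_population_stats()] tables, or run
#'   directories produced by [run_pipeline()] (their `pair_stats.csv` is
#'   read).
#' @return List with `n_shared_drugs`, `n_shared_pairs`,
#'   `n_shared_ddi_pairs`, `spearman_rho` (`NA` when no shared pairs) and
#'   the aligned `pairs` table.
#' @export
compare_populations <- function(stats_a, stats_b) {
  load_stats <- function(x) {
    if (is.character(x)) {
      x <- data.table::fread(file.path(x, "pair_stats.csv"))
    }
    data.table::as.data.table(x)
  }
  a <- load_stats(stats_a)
  b <- load_stats(stats_b)
  drugs_a <- unique(c(a$drug_a, a$drug_b))
  drugs_b <- unique(c(b$drug_a, b$drug_b))
  shared <- merge(a[, .(drug_a, drug_b, n_a = n_coadmin_users, is_ddi)],
                  b[, .(drug_a, drug_b, n_b = n_coadmin_users)],
                  by = c("drug_a", "drug_b"))
  if (nrow(shared) == 0L) warning("no shared drug pairs between the runs")
  rho <- if (nrow(shared) >= 2L)
    stats::cor(shared$n_a, shared$n_b, method = "spearman") else NA_real_
  list(n_shared_drugs = length(intersect(drugs_a, drugs_b)),
       n_shared_pairs = nrow(shared),
       n_shared_ddi_pairs = shared[is_ddi == TRUE, .N],
       spearman_rho = rho,
       pairs = shared)
}
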