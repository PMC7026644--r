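#' Run configuration
#'
#' Builds the full configuration of an end-to-end run with every
#' parameter explicit, so the written copy records all defaulted values
#' and a run is reproducible from `(config, seed)` alone. Per-stage
#' seeds are derived deterministically from the master seed.
#'
#' @param seed Master seed.
#' @param wt_fasta Optional path to a wild-type FASTA; when `NULL` the
#'   synthetic benchmark supplies the wild type.
#' @param counts_tsv Optional path to pre-aggregated variant counts
#'   (`subs  n_cleaved  n_total`); when `NULL` the simulate stage
#'   generates them.
#' @param dna_tsv,rna_tsv Optional raw record tables (`barcode
#'   sequence` / `barcode cleaved`), used instead of `counts_tsv`.
#' @param reference Optional reference-structure path (CT, bpseq,
#'   dot-bracket or pair TSV) for the evaluation stage; `"planted"`
#'   evaluates against the synthetic benchmark's planted pairs.
#' @param min_reads,ra_threshold Preprocessing parameters (minimum-read
#'   filter; triple-reduction threshold).
#' @param C,gamma,shift,k_sd,aggregate CODA parameters.
#' @param weight,lone_penalty,n_runs Folding parameters.
#' @param t_initial,cooling_factor,t_final,steps_per_temperature
#'   Annealing schedule.
#' @param n_variants,depth Library scale for the simulate stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, wt_fasta = NULL, counts_tsv = NULL,
                       dna_tsv = NULL, rna_tsv = NULL,
                       reference = "planted",
                       min_reads = 5, ra_threshold = 0.5,
                       C = 2000, gamma = 2.0, shift = 0.2, k_sd = 3,
                       aggregate = "max",
                       weight = 2.0, lone_penalty = 3, n_runs = 100,
                       t_initial = 10, cooling_factor = 0.95,
                       t_final = 0.1, steps_per_temperature = 10000,
                       n_variants = 40000, depth = 50) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config()` fields.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> preprocess -> score -> fold -> eval as
#' one reproducible run, persisting every intermediate table in
#' `out_dir` (append-only: no stage rewrites an earlier stage's output)
#' and a `summary.yaml`. Identical config and seed give identical
#' tables.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @param out_dir Run directory, created if missing.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  summary <- list(seed = config$seed)

  # --- simulate / load ------------------------------------------------
  rz <- NULL
  if (is.null(config$wt_fasta) &&
      (!is.null(config$counts_tsv) || !is.null(config$dna_tsv))) {
    stop("config field 'wt_fasta' is required when supplying ",
         "counts_tsv or dna_tsv/rna_tsv")
  }
  if (is.null(config$wt_fasta)) {
    stage_log("simulate", "building synthetic benchmark")
    rz <- make_default_benchmark(seed = config$seed + 11)
    wt <- rz$wild_type
    write_wildtype(wt, file.path(out_dir, "wt.fa"))
    write_ct(rz$structure, wt, file.path(out_dir, "truth_structure.ct"),
             id = wt$id)
  } else {
    wt <- read_wildtype(config$wt_fasta)
  }

  if (!is.null(config$counts_tsv)) {
    stage_log("preprocess", "reading counts from ", config$counts_tsv)
    variants <- readr::read_tsv(config$counts_tsv,
                                show_col_types = FALSE)
    variants$subs[is.na(variants$subs)] <- ""
  } else if (!is.null(config$dna_tsv)) {
    if (is.null(config$rna_tsv)) stop("dna_tsv given without rna_tsv")
    stage_log("preprocess", "mapping barcodes")
    bmap <- build_barcode_map(
      readr::read_tsv(config$dna_tsv, show_col_types = FALSE), wt)
    variants <- count_cleavage(
      readr::read_tsv(config$rna_tsv, show_col_types = FALSE), bmap)
  } else {
    if (is.null(rz)) stop("no counts_tsv/dna_tsv and no synthetic wild type")
    stage_log("simulate", "simulating library (n = ", config$n_variants,
              ", depth = ", config$depth, ")")
    sim <- simulate_library(
      rz, library_params(n_variants = config$n_variants,
                         depth = config$depth),
      seed = config$seed + 23)
    variants <- sim$variants
    readr::write_tsv(variants, file.path(out_dir, "counts.tsv"))
    readr::write_tsv(sim$truth, file.path(out_dir, "truth_ra.tsv"))
  }

  # --- preprocess -----------------------------------------------------
  act <- compute_ra(variants, wt, min_reads = config$min_reads)
  act <- reduce_triples(act, ra_threshold = config$ra_threshold)
  write_activity(act, file.path(out_dir, "activity.tsv"))
  cov <- coverage(act)
  summary$coverage <- as.list(cov)
  stage_log("preprocess", nrow(act), " activity records; single coverage ",
            round(cov$singles, 3), ", double coverage ",
            round(cov$doubles, 3))

  # --- score ----------------------------------------------------------
  stage_log("score", "fitting independent-mutation model and mixture")
  fit <- coda_fit(act, C = config$C, gamma = config$gamma,
                  shift = config$shift, k_sd = config$k_sd,
                  aggregate = config$aggregate)
  write_scores(fit$scores, file.path(out_dir, "scores.tsv"),
               file.path(out_dir, "scores_position.tsv"))
  summary$mixture <- as.list(glance(fit$mixture))
  stage_log("score", sprintf(
    "mixture: a1 = %.3f, sd1 = %.3f, a2 = %.3f, sd2 = %.3f, P(paired) = %.4f",
    fit$mixture$a1, fit$mixture$sd1, fit$mixture$a2, fit$mixture$sd2,
    fit$mixture$p_paired))

  # --- fold -----------------------------------------------------------
  stage_log("fold", config$n_runs, " annealing runs")
  schedule <- anneal_schedule(
    t_initial = config$t_initial, cooling_factor = config$cooling_factor,
    t_final = config$t_final,
    steps_per_temperature = config$steps_per_temperature)
  fold <- fold_ensemble(wt, model = energy_model(
    lone_penalty = config$lone_penalty),
    ps = fit, weight = config$weight, schedule = schedule,
    n_runs = config$n_runs, seed = config$seed + 37)
  readr::write_tsv(fold$pair_freq, file.path(out_dir, "pair_freq.tsv"))
  write_ct(fold$consensus, wt, file.path(out_dir, "consensus.ct"),
           id = wt$id)
  writeLines(write_dotbracket(fold$consensus, wt$length),
             file.path(out_dir, "consensus.db"))
  summary$n_consensus_pairs <- nrow(fold$consensus)
  stage_log("fold", nrow(fold$consensus), " consensus pairs")

  # --- eval -----------------------------------------------------------
  ref <- NULL
  if (identical(config$reference, "planted") && !is.null(rz)) {
    ref <- rz$structure
  } else if (!is.null(config$reference) &&
             !identical(config$reference, "planted")) {
    ref <- read_reference(config$reference)
  }
  if (!is.null(ref)) {
    cts <- confusion_counts(fold$consensus, ref, wt$length)
    mm <- max_mcc_threshold(fit$scores$per_position, ref, wt$length)
    pr <- pr_curve(fit$scores$per_position, ref, wt$length)
    summary$consensus <- list(
      tp = cts$tp, fp = cts$fp, fn = cts$fn,
      mcc = mcc(cts), sensitivity = sensitivity(cts),
      precision = precision(cts))
    summary$coda_scores <- list(
      auc_pr = pr$auc_pr, max_mcc = mm$mcc,
      sensitivity = mm$sensitivity, precision = mm$precision)
    readr::write_tsv(pr$curve, file.path(out_dir, "pr_curve.tsv"))
    stage_log("eval", sprintf(
      "consensus vs reference: sens = %.3f, prec = %.3f, MCC = %.3f",
      summary$consensus$sensitivity, summary$consensus$precision,
      summary$consensus$mcc))
  }

  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(summary)
}
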