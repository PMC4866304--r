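PIPELINE_STAGES <- c("simulate", "count", "score", "classify", "calibrate",
                     "robustness", "epistasis")

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a shared configuration: `simulate` (doped
#' library and counts from a ground-truth landscape) or `count` (counts from
#' FASTQ files listed in a sample sheet), then `score` (enrichment scores),
#' `classify` (single-mutant classes), optionally `calibrate` (ES to PSI),
#' `robustness` and `epistasis`. Every stage writes its TSV artifact into
#' `outdir` and a `manifest.json` records seeds, thresholds and content
#' digests; deterministic stages are bit-identical on rerun.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure. Recognised keys: `reference` (path/string; default the FAS
#'   design), `simulation` (list of [simulation_config()] arguments),
#'   `sample_sheet` (path or data.frame for [count_reads()]), `calibration`
#'   (path or data.frame of `es`, `psi` pairs), `seed`, `alpha`,
#'   `var_threshold`, `min_input_reads`, `pseudocount`, `hub_quantile`,
#'   `min_effects`. Unknown keys fail fast.
#' @param outdir Output directory, created if needed.
#' @param stages Subset of the stage names, or `"all"`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, stages = "all") {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  known <- c("reference", "simulation", "sample_sheet", "calibration", "seed",
             "alpha", "var_threshold", "min_input_reads", "pseudocount",
             "hub_quantile", "min_effects")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))

  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  var_threshold <- config$var_threshold %||% 0.15
  min_input_reads <- config$min_input_reads %||% 10
  pseudocount <- config$pseudocount %||% 0
  hub_quantile <- config$hub_quantile %||% 0.95
  min_effects <- config$min_effects %||% 20L

  ref <- if (is.null(config$reference)) fas_reference() else
    load_reference(config$reference)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(ref = ref)
  files <- character(0)
  emit <- function(name) files <<- c(files, file.path(outdir, name))

  needs <- function(stage, field, from) {
    if (is.null(res[[field]])) {
      stop("stage '", stage, "' requires outputs of stage '", from,
           "' (not run and not available)")
    }
  }

  if ("simulate" %in% stages) {
    if ("count" %in% stages) stop("choose either 'simulate' or 'count', not both")
    sim_args <- config$simulation %||% list()
    sim_args$ref <- ref
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sc <- do.call(simulation_config, sim_args)
    res$truth <- build_truth(sc)
    res$counts <- simulate_counts(res$truth)
    write_counts(res$counts, file.path(outdir, "counts.tsv")); emit("counts.tsv")
    truth_tab <- data.frame(variant_id = names(res$truth$psi),
                            psi_true = unname(res$truth$psi))
    utils::write.table(truth_tab, file.path(outdir, "truth_psi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("truth_psi.tsv")
  }
  if ("count" %in% stages) {
    if (is.null(config$sample_sheet)) stop("stage 'count' needs a sample_sheet")
    res$counts <- count_reads(config$sample_sheet, ref)
    write_counts(res$counts, file.path(outdir, "counts.tsv")); emit("counts.tsv")
    if (nrow(res$counts$rejected)) {
      utils::write.table(res$counts$rejected,
                         file.path(outdir, "rejected_reads.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("rejected_reads.tsv")
    }
  }
  if ("score" %in% stages) {
    needs("score", "counts", "simulate/count")
    res$scores <- enrichment_scores(frequencies(res$counts),
                                    min_input_reads = min_input_reads,
                                    pseudocount = pseudocount)
    write_scores(res$scores, file.path(outdir, "scores.tsv")); emit("scores.tsv")
  }
  if ("classify" %in% stages) {
    needs("classify", "scores", "score")
    res$classes <- classify_variants(res$scores, alpha = alpha,
                                     var_threshold = var_threshold)
    utils::write.table(as.data.frame(res$classes),
                       file.path(outdir, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("classes.tsv")
  }
  if ("calibrate" %in% stages && !is.null(config$calibration)) {
    pts <- config$calibration
    if (is.character(pts)) {
      pts <- utils::read.table(pts, sep = "\t", header = TRUE)
    }
    if ("psi_measured" %in% names(pts) && !"psi" %in% names(pts)) {
      pts$psi <- pts$psi_measured
    }
    res$calibration <- fit_psi_calibration(pts)
    write_calibration(res$calibration, file.path(outdir, "calibration.txt"))
    emit("calibration.txt")
    if (!is.null(res$scores)) {
      sc <- res$scores[res$scores$quantified, ]
      pp <- predict_psi(res$calibration, sc$es)
      pp <- cbind(variant_id = sc$variant_id, pp)
      utils::write.table(pp, file.path(outdir, "psi_predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("psi_predictions.tsv")
    }
  }
  if ("robustness" %in% stages) {
    needs("robustness", "scores", "score")
    needs("robustness", "classes", "classify")
    neutral <- res$classes$variant_id[res$classes$class == "N"]
    res$effects <- background_effects(res$scores, neutral)
    utils::write.table(res$effects, file.path(outdir, "background_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("background_effects.tsv")
    res$robustness <- compare_robustness(res$effects, res$counts, seed = seed,
                                         min_effects = min_effects)
    utils::write.table(res$robustness$per_background,
                       file.path(outdir, "robustness_backgrounds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("robustness_backgrounds.tsv")
    writeLines(sprintf("%s\t%.17g",
                       c("wt_median_abs", "mw_p_value", "wt_is_most_robust",
                         "target_total", "n_wt_resamples"),
                       c(res$robustness$wt_median_abs, res$robustness$p_value,
                         as.numeric(res$robustness$wt_is_most_robust),
                         res$robustness$target_total,
                         res$robustness$n_wt_resamples)),
               file.path(outdir, "robustness_report.txt"))
    emit("robustness_report.txt")
  }
  if ("epistasis" %in% stages) {
    needs("epistasis", "scores", "score")
    fit <- fit_linear_expectation(res$scores)
    epi <- epistasis_scores(fit)
    res$epistasis <- test_epistasis(epi, classes = res$classes, alpha = alpha)
    res$epistasis_fit <- fit
    res$networks <- network_metrics(res$epistasis, hub_quantile = hub_quantile)
    write_epistasis(res$epistasis, file.path(outdir, "epistasis.tsv"))
    emit("epistasis.tsv")
    utils::write.table(res$networks$degrees,
                       file.path(outdir, "epistasis_degrees.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("epistasis_degrees.tsv")
  }

  manifest <- list(
    package = "dmsplice",
    version = as.character(utils::packageVersion("dmsplice")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    thresholds = list(alpha = alpha, var_threshold = var_threshold,
                      min_input_reads = min_input_reads,
                      pseudocount = pseudocount, hub_quantile = hub_quantile,
                      min_effects = min_effects),
    stages = stages,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
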