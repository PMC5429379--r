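# per-stage seeds derived deterministically from the run seed, so any
# stage can be re-run in isolation with the same randomness
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483646L + 1L
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end pipeline in one validated object.
#'
#' @param input Path to a norms CSV/TSV (see [read_norms()]), or a
#'   \code{norm_table} already in memory.
#' @param outdir Output directory for all artifacts (created if needed).
#' @param screening A [screening_config()].
#' @param k_range,families Mixture model search space (see
#'   [select_model()]).
#' @param selection A [selection_config()].
#' @param run_baselines Also run the k-means index scan and hierarchical
#'   clustering diagnostics? Default \code{FALSE}.
#' @param validate \code{"none"} (default), \code{"splithalf"} or
#'   \code{"jackknife"}.
#' @param validate_reps Repetitions for the chosen validation mode.
#' @param dialect Optional [read_norms()] dialect.
#' @param seed Global integer seed; per-stage seeds are derived from it
#'   deterministically.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input, outdir,
                            screening = screening_config(),
                            k_range = 1:9,
                            families = gmm_families()$name,
                            selection = selection_config(),
                            run_baselines = FALSE,
                            validate = c("none", "splithalf", "jackknife"),
                            validate_reps = 50L,
                            dialect = NULL,
                            seed = 1L) {
  stopifnot(inherits(screening, "screening_config"),
            inherits(selection, "selection_config"))
  structure(list(input = input, outdir = outdir, screening = screening,
                 k_range = k_range, families = families,
                 selection = selection, run_baselines = run_baselines,
                 validate = match.arg(validate),
                 validate_reps = as.integer(validate_reps),
                 dialect = dialect, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [pipeline_config()] (nested \code{screening} and \code{selection}
#' blocks map onto [screening_config()] / [selection_config()]
#' arguments).
#'
#' @param path YAML file path.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(input = y$input, outdir = y$outdir)
  if (!is.null(y$screening)) {
    args$screening <- do.call(screening_config, y$screening)
  }
  if (!is.null(y$selection)) {
    args$selection <- do.call(selection_config, y$selection)
  }
  for (f in c("k_range", "families", "run_baselines", "validate",
              "validate_reps", "dialect", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(args$k_range)) args$k_range <- as.integer(args$k_range)
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full stimulus-selection pipeline
#'
#' Executes, in order: screening (duplicates, dominance resolution, MAD
#' outliers, CI precision), model-based clustering with BIC selection,
#' optional baseline diagnostics (k-means index scan, hierarchical
#' clustering with cophenetic correlation and partition concordance),
#' optional stability validation, and exemplar selection. Every tabular
#' artifact is written to \code{config$outdir} as CSV, and a
#' \code{run_manifest.json} records the configuration, derived seeds, the
#' chosen model and every stage's removal counts, so a run can be audited
#' and replayed exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects (\code{screened},
#'   \code{screening_report}, \code{selection_result} (BIC surface +
#'   best model), \code{classification}, \code{selection},
#'   \code{baselines}, \code{stability}) and \code{artifacts}, the named
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- list()

  table <- .stage("read", {
    if (inherits(config$input, "norm_table")) config$input else
      read_norms(config$input, config$dialect)
  })

  scr <- .stage("screen", run_screening(table, config$screening))
  art$screened <- file.path(config$outdir, "screened.csv")
  write_table(art$screened, scr$table)
  art$screening_report <- file.path(config$outdir, "screening_report.csv")
  write_table(art$screening_report, scr$report)

  X <- .pad_matrix(scr$table)
  sel_model <- .stage("cluster",
                      select_model(X, config$k_range, config$families))
  art$bic_surface <- file.path(config$outdir, "bic_surface.csv")
  write_table(art$bic_surface, sel_model$surface)
  cl <- classify(sel_model$best, X, codes = scr$table$code)
  bands <- usability_bands(cl$uncertainty, config$selection$p_ok,
                           config$selection$p_risky)
  art$classification <- file.path(config$outdir, "classification.csv")
  write_table(art$classification, cl, bands = bands)

  baselines <- NULL
  if (isTRUE(config$run_baselines)) {
    baselines <- .stage("baselines", {
      km_seed <- .stage_seed(config$seed, "baselines")
      km <- kmeans_fit(X, k = sel_model$best$k, seed = km_seed)
      idx <- kmeans_index_scan(X, k_range = 2:8, n_init = 25L,
                               seed = km_seed)
      hc <- hclust_fit(X, linkage = "average", metric = "correlation")
      hp <- cut_dendrogram(hc, k = sel_model$best$k)
      list(kmeans = km, indices = idx, hclust = hc,
           cophenetic_r = cophenetic_correlation(hc),
           vs_kmeans = compare_partitions(cl$cluster, km$labels),
           vs_hclust = compare_partitions(cl$cluster, hp$labels))
    })
    art$indices <- file.path(config$outdir, "kmeans_indices.csv")
    write_table(art$indices, as.data.frame(baselines$indices))
  }

  stability <- NULL
  if (config$validate != "none") {
    stability <- .stage("validate", {
      vseed <- .stage_seed(config$seed, config$validate)
      if (config$validate == "splithalf") {
        split_half(X, codes = scr$table$code, R = config$validate_reps,
                   k_range = config$k_range, families = config$families,
                   seed = vseed)
      } else {
        jackknife(X, codes = scr$table$code, B = config$validate_reps,
                  k_range = config$k_range, families = config$families,
                  seed = vseed)
      }
    })
    art$stability <- file.path(config$outdir, "stability.csv")
    write_table(art$stability, stability)
  }

  sel <- .stage("select", select_representatives(cl, config$selection))
  art$exemplars <- file.path(config$outdir, "exemplars.csv")
  write_table(art$exemplars, sel)

  manifest <- list(
    package_version = as.character(utils::packageVersion("affectselect")),
    seed = config$seed,
    stage_seeds = list(baselines = .stage_seed(config$seed, "baselines"),
                       splithalf = .stage_seed(config$seed, "splithalf"),
                       jackknife = .stage_seed(config$seed, "jackknife")),
    input = if (is.character(config$input)) config$input else "<in-memory>",
    screening = unclass(config$screening),
    k_range = config$k_range,
    families = config$families,
    selection = unclass(config$selection),
    validate = config$validate,
    validate_reps = config$validate_reps,
    chosen_model = list(k = sel_model$best$k,
                        family = sel_model$best$family,
                        bic = sel_model$best$bic,
                        loglik = sel_model$best$loglik),
    screening_counts = list(
      n_input = scr$report$n_input,
      n_rows_merged = scr$report$n_rows_merged,
      n_dropped_missing_dominance = scr$report$n_dropped_missing_dominance,
      n_outliers = scr$report$n_outliers,
      n_wide_ci = scr$report$n_wide_ci,
      n_output = scr$report$n_output),
    removed_codes = list(
      duplicates_merged = scr$report$codes_duplicates,
      missing_dominance = scr$report$codes_dropped_dominance,
      outliers = scr$report$codes_outliers,
      wide_ci = scr$report$codes_wide_ci)
  )
  art$manifest <- file.path(config$outdir, "run_manifest.json")
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(screened = scr$table, screening_report = scr$report,
                 selection_result = sel_model, classification = cl,
                 selection = sel, baselines = baselines,
                 stability = stability, artifacts = art))
}
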