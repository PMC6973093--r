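# End-to-end orchestration: validate -> (simulate | load) -> variable-rates
# chain -> stepping-stone Bayes factor -> shift detection -> trends, with one
# global seed expanded into per-stage substreams so stages are independently
# reproducible.

.digest_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, vr = 2L, bf_m0 = 3L, bf_m1 = 4L, shifts = 5L,
               trends = 6L)
  if (is.null(seed)) NULL else (seed + 1000L * offsets[[stage]]) %% .Machine$integer.max
}

#' Default pipeline configuration
#'
#' Returns the configuration skeleton understood by [run_pipeline()]. Either
#' `input` (paths to a newick tree and a trait CSV) or `simulate` (arguments
#' to [sim_config()]) must be supplied. Chain lengths default to the
#' desk-scale preset of [vr_settings()].
#'
#' @param seed Global seed; expanded into per-stage substreams.
#' @param input List with `tree` and `traits` file paths (optional).
#' @param simulate List of [sim_config()] arguments (optional).
#' @param formula Regression formula (string or formula).
#' @param vr,bf,shifts,trends Stage option lists; `bf$enabled = FALSE` skips
#'   the (expensive) stepping-stone stage.
#' @param out_dir Output directory (`NULL`: nothing written to disk).
#' @return A config list.
#' @export
pipeline_config <- function(seed = 1, input = NULL, simulate = NULL,
                            formula = "testes ~ body",
                            vr = list(), bf = list(enabled = FALSE),
                            shifts = list(min_size = 10),
                            trends = NULL, out_dir = NULL) {
  list(seed = seed, input = input, simulate = simulate,
       formula = formula, vr = vr, bf = bf, shifts = shifts,
       trends = trends, out_dir = out_dir)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring [pipeline_config()].
#' @return A config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: input validation, data
#' (simulation or file loading plus tree/trait matching), the variable-rates
#' chain, optionally the stepping-stone Bayes factor m1 vs m0, branch
#' summaries and heritable-shift detection (with mean-shift diagnosis of
#' detected shifts), the median rate-scaled tree and path-wise rates, and the
#' trends analysis. A failure in any stage stops the run with the manifest
#' recording the failure point. Outputs are written under `out_dir` when set
#' (newick, CSV and JSON).
#'
#' @param config From [pipeline_config()] or [read_pipeline_config()].
#' @return A list: `manifest` (config hash, seeds, stage digests, package
#'   version, timestamps) and `results` (the in-memory stage outputs).
#' @export
run_pipeline <- function(config) {
  manifest <- list(config_hash = .digest_of(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("ratescape")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  results <- list()
  fail <- function(stage, msg) {
    manifest$stages[[stage]] <- list(status = "failed", error = msg)
    stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
  }

  # -- validate ---------------------------------------------------------------
  if (is.null(config$input) && is.null(config$simulate))
    fail("validate", "config must declare either `input` or `simulate`")
  if (!is.null(config$input)) {
    for (f in c(config$input$tree, config$input$traits)) {
      if (is.null(f) || !file.exists(f))
        fail("validate", paste("input file missing:",
                               if (is.null(f)) "(unset)" else f))
    }
  }
  formula <- stats::as.formula(config$formula)

  # -- data -------------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- .stage_seed(config$seed, "simulate")
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(cfg)
    tree <- sim$tree; table <- sim$table
    results$truth <- sim[c("scaled_tree", "true_scalars", "true_pathwise")]
  } else {
    tree <- read_newick(config$input$tree)
    table <- read_trait_table(config$input$traits)
    mp <- match_and_prune(tree, table)
    tree <- mp$tree; table <- mp$table
  }
  results$tree <- tree; results$table <- table
  manifest$stages$data <- list(status = "ok", n_species = nrow(table),
                               digest = .digest_of(list(tree, table)))

  # -- variable-rates chain ---------------------------------------------------
  vr_args <- config$vr
  settings <- do.call(vr_settings, vr_args[names(vr_args) %in%
                                             names(formals(vr_settings))])
  trace <- tryCatch(
    run_chain(formula, table, tree, settings = settings,
              seed = .stage_seed(config$seed, "vr")),
    error = function(e) fail("vr", conditionMessage(e)))
  results$trace <- trace
  manifest$stages$vr <- list(status = "ok", samples = length(trace$sigma2),
                             min_ess = min(trace$ess),
                             digest = .digest_of(trace[c("beta", "sigma2", "r")]))

  # -- Bayes factor -----------------------------------------------------------
  if (isTRUE(config$bf$enabled)) {
    bf_args <- config$bf[setdiff(names(config$bf), "enabled")]
    ss <- function(model, stage) do.call(stepping_stone_run, c(
      list(formula = formula, data = table, tree = tree, model = model,
           seed = .stage_seed(config$seed, stage)), bf_args))
    m0 <- tryCatch(ss("single", "bf_m0"),
                   error = function(e) fail("bf", conditionMessage(e)))
    m1 <- tryCatch(ss("vr", "bf_m1"),
                   error = function(e) fail("bf", conditionMessage(e)))
    bf <- compute_bayes_factor(m1$logml, m0$logml)
    results$bf <- list(m0 = m0, m1 = m1, bf = as.numeric(bf),
                       interpretation = attr(bf, "interpretation"))
    manifest$stages$bf <- list(status = "ok", bf = as.numeric(bf),
                               logml_m1 = m1$logml, logml_m0 = m0$logml)
  }

  # -- shifts, scaled tree, path-wise rates -----------------------------------
  summaries <- summarize_branch_rates(trace)
  min_size <- config$shifts$min_size %||% 10
  shifts <- detect_heritable_shifts(trace, min_size = min_size)
  if (nrow(shifts)) {
    ms <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i)
      flag_mean_shift(shifts[i, ], formula, table, tree, summaries)))
    shifts$mean_shift <- ms$mean_shift
    shifts$mean_p <- ms$mean_p
  }
  med_tree <- median_scaled_tree(trace)
  pw <- pathwise_rates(trace)
  results$summaries <- summaries; results$shifts <- shifts
  results$median_tree <- med_tree; results$pathwise <- pw
  manifest$stages$shifts <- list(
    status = "ok", n_heritable = sum(shifts$kind == "heritable"),
    n_incipient = sum(shifts$kind == "incipient"),
    digest = .digest_of(list(summaries, shifts)))

  # -- trends -----------------------------------------------------------------
  if (!is.null(config$trends)) {
    tr_args <- config$trends
    trends <- tryCatch(
      do.call(run_trends, c(list(table = table, scaled_tree = med_tree,
                                 pathrates = pw), tr_args)),
      error = function(e) fail("trends", conditionMessage(e)))
    results$trends <- trends
    manifest$stages$trends <- list(status = "ok",
                                   model_branch = trends$model_branch)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_newick(tree, file.path(config$out_dir, "tree.nwk"))
    write_newick(med_tree, file.path(config$out_dir, "median_scaled_tree.nwk"))
    utils::write.csv(table, file.path(config$out_dir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "branch_rates.csv"),
                     row.names = FALSE)
    if (nrow(shifts)) {
      flat <- shifts
      flat$tips <- vapply(shifts$tips, paste, "", collapse = ";")
      utils::write.csv(flat, file.path(config$out_dir, "shifts.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(pw$summary, file.path(config$out_dir, "pathwise_rates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(manifest = manifest, results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
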