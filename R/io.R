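trial_columns <- c("participant_id", "group", "structure", "noise_index",
                   "n_ext", "contrast", "correct")

#' Read and write trial tables
#'
#' Trial tables are plain CSV with a header naming the columns
#' `participant_id, group, structure, noise_index, n_ext, contrast, correct`
#' (column order is free; columns are matched by name). Contrasts and
#' external-noise levels are proportions; `correct` is 0/1. Malformed rows
#' are rejected with their row numbers.
#'
#' @param path File path.
#' @return `read_trials()` returns the trial tibble.
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(trial_columns, names(raw))
  if (length(missing) > 0) {
    stop("trial file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[trial_columns]
  raw$structure <- as.integer(raw$structure)
  raw$noise_index <- as.integer(raw$noise_index)
  raw$correct <- as.integer(raw$correct)
  bad <- which(is.na(raw$contrast) | raw$contrast <= 0 |
                 is.na(raw$n_ext) | raw$n_ext < 0 |
                 !(raw$correct %in% c(0L, 1L)) |
                 is.na(raw$structure) | is.na(raw$noise_index))
  if (length(bad) > 0) {
    stop("invalid trial rows (after header): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  raw
}

#' @rdname read_trials
#' @param trials Trial tibble with the documented columns.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    stop("trials are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[trial_columns], path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: group and design
#' specifications, the severity link, per-stage MCMC settings, the fixed
#' template gain and transducer exponent, and a single global seed from
#' which every stochastic stage derives its own sub-seed.
#'
#' @param case_spec,control_spec [group_spec()]s.
#' @param design A [design_spec()].
#' @param link A [severity_link()].
#' @param weibull_mcmc,hier_mcmc [mcmc_config()]s for the two Bayesian
#'   stages.
#' @param beta,gamma Fixed PTM template gain and transducer exponent for the
#'   trial-level stages.
#' @param seed Global integer seed.
#' @param case_coeffs Optional injected group effects for the simulation
#'   stage (see [simulate_study()]).
#' @return A list of class `run_config` (with a content hash in
#'   `$config_hash`).
#' @export
run_config <- function(case_spec = case_group_spec(),
                       control_spec = control_group_spec(),
                       design = design_spec(),
                       link = severity_link(),
                       weibull_mcmc = mcmc_config(chains = 2, burn_in = 500,
                                                  thin = 2,
                                                  draws_per_chain = 500),
                       hier_mcmc = mcmc_config(chains = 2, burn_in = 1000,
                                               thin = 1,
                                               draws_per_chain = 750),
                       beta = 1.25, gamma = 2, seed = 1,
                       case_coeffs = unit_coefficients()) {
  cfg <- list(case_spec = case_spec, control_spec = control_spec,
              design = design, link = link, weibull_mcmc = weibull_mcmc,
              hier_mcmc = hier_mcmc, beta = beta, gamma = gamma,
              seed = as.integer(seed), case_coeffs = case_coeffs)
  cfg$config_hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field not present falls back to the [run_config()] default. Nested
#' blocks mirror the constructor arguments, e.g.
#' `design: {trials_per_level_per_structure: 30}` or
#' `hier_mcmc: {chains: 2, burn_in: 1000, thin: 1, draws_per_chain: 750}`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 resolves a bare `n` key to logical FALSE; put it back
  fix_n <- function(block) {
    if (is.list(block)) names(block)[names(block) == "FALSE"] <- "n"
    block
  }
  y <- lapply(y, fix_n)
  build <- function(ctor, field) {
    if (is.null(y[[field]])) formals(run_config)[[field]] else
      do.call(ctor, y[[field]])
  }
  run_config(
    case_spec = if (is.null(y$case_spec)) case_group_spec() else
      do.call(group_spec, y$case_spec),
    control_spec = if (is.null(y$control_spec)) control_group_spec() else
      do.call(group_spec, y$control_spec),
    design = if (is.null(y$design)) design_spec() else
      do.call(design_spec, y$design),
    link = if (is.null(y$link)) severity_link() else
      do.call(severity_link, y$link),
    weibull_mcmc = if (is.null(y$weibull_mcmc))
      formals(run_config)$weibull_mcmc |> eval() else
        do.call(mcmc_config, y$weibull_mcmc),
    hier_mcmc = if (is.null(y$hier_mcmc))
      formals(run_config)$hier_mcmc |> eval() else
        do.call(mcmc_config, y$hier_mcmc),
    beta = y$beta %||% 1.25, gamma = y$gamma %||% 2,
    seed = y$seed %||% 1)
}

pipeline_stages <- c("simulate", "fit_weibull", "fit_group", "fit_hier",
                     "stats")

#' Run the full equivalent-noise analysis pipeline
#'
#' Executes, in order, any contiguous subset of: `simulate` (synthetic
#' study), `fit_weibull` (per-participant per-level thresholds),
#' `fit_group` (conventional 8-model PTM comparison), `fit_hier`
#' (hierarchical Bayesian fit + credible-interval group tests), and `stats`
#' (severity correlation and regression). Each stage writes CSV artifacts to
#' `out_dir`, stamped with the configuration hash; later stages reload the
#' artifacts of earlier ones, so a later stage requested without its inputs
#' present is a dependency error (as is a hash mismatch on resume).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results of the executed
#'   stages.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = pipeline_stages, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"),
            all(stages %in% pipeline_stages))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  hash_path <- file.path(out_dir, "config_hash.txt")
  if (file.exists(hash_path)) {
    old <- readLines(hash_path, warn = FALSE)[1]
    if (!identical(old, config$config_hash)) {
      stop("output directory holds artifacts from a different ",
           "configuration (hash mismatch)", call. = FALSE)
    }
  } else {
    writeLines(config$config_hash, hash_path)
  }
  need <- function(file, stage) {
    p <- file.path(out_dir, file)
    if (!file.exists(p)) {
      stop("stage '", stage, "' requires '", file,
           "' from an earlier stage; run that stage first", call. = FALSE)
    }
    p
  }
  results <- list()
  t_all <- Sys.time()

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    study <- simulate_study(config$case_spec, config$control_spec,
                            config$link, config$design,
                            seed = derive_seed(config$seed, "simulate"),
                            case_coeffs = config$case_coeffs)
    write_trials(study$trials, file.path(out_dir, "trials.csv"))
    readr::write_csv(study$truth, file.path(out_dir, "truth.csv"))
    readr::write_csv(study$severity, file.path(out_dir, "severity.csv"))
    results$study <- study
    say(sprintf("simulate: %d trials [%.1fs]", nrow(study$trials),
                as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("fit_weibull" %in% stages) {
    t0 <- Sys.time()
    trials <- read_trials(need("trials.csv", "fit_weibull"))
    thr <- fit_weibull_thresholds(trials, config$weibull_mcmc,
                                  seed = derive_seed(config$seed,
                                                     "fit_weibull"))
    readr::write_csv(thr, file.path(out_dir, "thresholds.csv"))
    results$thresholds <- thr
    say(sprintf("fit_weibull: %d cells [%.1fs]",
                nrow(dplyr::distinct(thr, .data$participant_id,
                                     .data$noise_index)),
                as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("fit_group" %in% stages) {
    t0 <- Sys.time()
    thr <- readr::read_csv(need("thresholds.csv", "fit_group"),
                           show_col_types = FALSE)
    tvn <- tvn_table(thr)
    models <- fit_ptm_models(tvn, ref_group = config$control_spec$label,
                             seed = derive_seed(config$seed, "fit_group"))
    best <- select_model(models)
    comp <- dplyr::select(models$comparison, -"fit")
    comp$selected <- comp$model == attr(best, "model")
    readr::write_csv(comp, file.path(out_dir, "model_comparison.csv"))
    readr::write_csv(tvn, file.path(out_dir, "tvn_table.csv"))
    readr::write_csv(generics::tidy(best),
                     file.path(out_dir, "selected_model.csv"))
    results$tvn <- tvn
    results$models <- models
    results$selected <- best
    say(sprintf("fit_group: selected '%s' [%.1fs]", attr(best, "model"),
                as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("fit_hier" %in% stages) {
    t0 <- Sys.time()
    trials <- read_trials(need("trials.csv", "fit_hier"))
    hier <- fit_hierarchical(trials, config$hier_mcmc,
                             seed = derive_seed(config$seed, "fit_hier"),
                             beta = config$beta, gamma = config$gamma)
    readr::write_csv(hier$population_draws,
                     file.path(out_dir, "population_draws.csv"))
    readr::write_csv(hier$individual_map,
                     file.path(out_dir, "individual_map.csv"))
    readr::write_csv(hier$population_map,
                     file.path(out_dir, "population_map.csv"))
    case_lab <- config$case_spec$label
    ctrl_lab <- config$control_spec$label
    gd <- purrr::map_dfr(c("n_add", "n_mul", "w_ext"), function(p) {
      group_difference(hier, p, case = case_lab, control = ctrl_lab)
    })
    readr::write_csv(gd, file.path(out_dir, "group_differences.csv"))
    results$hier <- hier
    results$group_differences <- gd
    say(sprintf("fit_hier: %d chains x %d draws [%.1fs]",
                config$hier_mcmc$chains, config$hier_mcmc$draws_per_chain,
                as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("stats" %in% stages) {
    t0 <- Sys.time()
    imap <- readr::read_csv(need("individual_map.csv", "stats"),
                            show_col_types = FALSE)
    sev <- readr::read_csv(need("severity.csv", "stats"),
                           show_col_types = FALSE)
    dat <- dplyr::inner_join(imap, sev, by = "participant_id")
    cors <- purrr::map_dfr(c("n_add", "w_ext"), function(p) {
      dplyr::mutate(pearson_test(dat[[p]], dat$severity), parameter = p,
                    .before = 1)
    })
    reg <- ols_regression(dat, "severity", c("n_add", "w_ext"))
    readr::write_csv(cors, file.path(out_dir, "severity_correlations.csv"))
    readr::write_csv(reg$coefficients,
                     file.path(out_dir, "severity_regression.csv"))
    results$correlations <- cors
    results$regression <- reg
    say(sprintf("stats: r(n_add, severity) = %.2f [%.1fs]",
                cors$r[cors$parameter == "n_add"],
                as.numeric(Sys.time() - t0, units = "secs")))
  }

  say(sprintf("pipeline done [%.1fs total]",
              as.numeric(Sys.time() - t_all, units = "secs")))
  invisible(results)
}
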