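# Shared YAML configuration and the pipeline task runner. Every
# analysis constant (likelihood-ratio thresholds, therapeutic window
# bounds, LLOQ, fixed ka and additive error, centering age) is visible
# in the configuration with its reference default, never hard-coded at
# the call sites.

#' Pipeline configuration
#'
#' Builds the resolved configuration for [run_task()]: defaults,
#' optionally overlaid with a YAML file and/or a list of overrides
#' (later sources win, merged recursively).
#'
#' @param path Optional YAML file.
#' @param overrides Optional named list of overrides.
#' @return A list of class `"pk_config"` with components `seed`,
#'   `lloq`, `ka`, `sigma2_add`, `thresholds` (`forward`, `backward`),
#'   `window` (`lower`, `upper`, `alert`), `truth` (arguments to
#'   [pk_params()]), `cohort` (arguments to [cohort_config()]),
#'   `simulation` (`doses`, `ages`, `phenotypes`, `n_subjects`),
#'   `bootstrap` (`n`), `npde` (`nsim`).
#' @export
pk_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1L,
    lloq = 3,
    ka = 0.6,
    sigma2_add = 0,
    thresholds = list(forward = 6.63, backward = 10.83),
    window = list(lower = 15, upper = 80, alert = 160),
    truth = list(),          # pk_params() arguments
    cohort = list(),         # cohort_config() arguments
    selection = list(continuous = c("AGE", "WT", "HT"),
                     categorical = c("SEX"),
                     phenotype = TRUE),
    simulation = list(doses = c(5, 10, 15, 20), tau = 24,
                      ages = c(16, 45, 65),
                      phenotypes = c("EM", "IM", "PM"),
                      n_subjects = 1000),
    bootstrap = list(n = 1000),
    npde = list(nsim = 1000))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_lists(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_lists(cfg, overrides)
  structure(cfg, class = "pk_config")
}

merge_lists <- function(base, over) {
  if (!is.list(over)) return(over)
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
      merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}

config_params <- function(cfg) {
  args <- cfg$truth
  args$ka <- args$ka %||% cfg$ka
  args$sigma2_add <- args$sigma2_add %||% cfg$sigma2_add
  do.call(pk_params, args)
}

config_cohort <- function(cfg) {
  args <- cfg$cohort
  args$lloq <- args$lloq %||% cfg$lloq
  do.call(cohort_config, args)
}

#' Run a pipeline task
#'
#' Executes one step of the analysis pipeline and writes its result
#' files plus a run log (resolved configuration and seed) to `dir`.
#' Tasks: `"generate"` (synthetic event-record CSV), `"fit"` (FOCE-I
#' parameter table), `"select"` (stepwise covariate search log and
#' final parameters), `"bootstrap"`, `"npde"`, `"gof"`
#' (goodness-of-fit table), `"simulate"` (regimen x age x phenotype
#' trough table). All randomized tasks are reproducible from
#' `config$seed`.
#'
#' @param task One of the task names above.
#' @param config A [pk_config()].
#' @param dir Output directory (created if missing).
#' @param data A [pk_dataset()] or event-record CSV path; required for
#'   every task except `"generate"` and `"simulate"`.
#' @param fit An optional existing [pkfit()] (otherwise tasks that need
#'   one fit the reference model first).
#' @return The task's result object, invisibly.
#' @export
run_task <- function(task = c("generate", "fit", "select", "bootstrap",
                              "npde", "gof", "simulate"),
                     config = pk_config(), dir = ".", data = NULL,
                     fit = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(config, "pk_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- config_params(config)
  need_data <- !(task %in% c("generate", "simulate"))
  if (need_data) {
    if (is.null(data) && is.null(fit))
      stop("task '", task, "' requires `data` (dataset or CSV path)")
    if (is.character(data)) data <- read_pkdata(data, lloq = config$lloq)
    if (is.null(data)) data <- fit$data
    stopifnot(inherits(data, "pk_dataset"))
  }
  get_fit <- function() {
    if (!is.null(fit)) return(fit)
    pkfit(data, start = params,
          control = pkfit_control(se = task == "fit"))
  }

  result <- switch(task,
    generate = {
      coh <- generate_cohort(config_cohort(config), seed = config$seed)
      ds <- simulate_pkdata(coh, truth = params,
                            config = config_cohort(config),
                            seed = config$seed + 1L)
      write_pkdata(ds, file.path(dir, "dataset.csv"))
      ds
    },
    fit = {
      f <- get_fit()
      tb <- data.frame(parameter = names(coef(f)),
                       estimate = as.numeric(coef(f)),
                       se = as.numeric(f$se),
                       rse_pct = as.numeric(f$rse),
                       fixed = names(coef(f)) %in% f$fix)
      tb <- rbind(tb, data.frame(parameter = "OFV", estimate = f$ofv,
                                 se = NA, rse_pct = NA, fixed = FALSE))
      write.csv(tb, file.path(dir, "parameters.csv"), row.names = FALSE)
      f
    },
    select = {
      cand <- covariate_candidates(
        continuous = config$selection$continuous,
        categorical = config$selection$categorical,
        phenotype = isTRUE(config$selection$phenotype))
      sr <- stepwise_covariates(
        data, candidates = cand,
        threshold_fwd = config$thresholds$forward,
        threshold_bwd = config$thresholds$backward,
        start = params, control = pkfit_control(se = FALSE))
      write_search_log(sr, file.path(dir, "search_log.tsv"))
      write.csv(data.frame(parameter = names(coef(sr$final_fit)),
                           estimate = as.numeric(coef(sr$final_fit))),
                file.path(dir, "selected_parameters.csv"),
                row.names = FALSE)
      sr
    },
    bootstrap = {
      bs <- bootstrap_pkfit(get_fit(), n = config$bootstrap$n,
                            seed = config$seed)
      write.csv(as.data.frame(bs$replicates),
                file.path(dir, "bootstrap_replicates.csv"),
                row.names = FALSE)
      write.csv(bs$summary, file.path(dir, "bootstrap_summary.csv"),
                row.names = FALSE)
      bs
    },
    npde = {
      nd <- npde(get_fit(), nsim = config$npde$nsim, seed = config$seed)
      write.table(data.frame(npde = nd$npde),
                  file.path(dir, "npde.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.csv(data.frame(statistic = c("mean", "variance", "skewness",
                                         "kurtosis", "p_t", "p_fisher",
                                         "p_sw", "p_global"),
                           value = c(nd$mean, nd$variance, nd$skewness,
                                     nd$kurtosis, nd$p_t, nd$p_fisher,
                                     nd$p_sw, nd$p_global)),
                file.path(dir, "npde_stats.csv"), row.names = FALSE)
      nd
    },
    gof = {
      g <- gof_table(get_fit())
      write.table(g, file.path(dir, "gof.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      g
    },
    simulate = {
      regs <- lapply(config$simulation$doses, regimen,
                     tau = config$simulation$tau)
      tb <- trough_table(params, regimens = regs,
                         ages = config$simulation$ages,
                         phenotypes = config$simulation$phenotypes,
                         n_subjects = config$simulation$n_subjects,
                         seed = config$seed,
                         lower = config$window$lower,
                         upper = config$window$upper,
                         alert = config$window$alert)
      write.csv(tb, file.path(dir, "trough_table.csv"),
                row.names = FALSE)
      tb
    })

  log_path <- file.path(dir, paste0(task, "_log.txt"))
  writeLines(c(
    paste0("task: ", task),
    paste0("time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed),
    sprintf("thresholds: forward %g, backward %g",
            config$thresholds$forward, config$thresholds$backward),
    sprintf("window: %g-%g ng/ml, alert %g ng/ml",
            config$window$lower, config$window$upper,
            config$window$alert),
    sprintf("fixed: ka %g, additive error variance %g; LLOQ %g ng/ml",
            config$ka, config$sigma2_add, config$lloq),
    "resolved config:",
    yaml::as.yaml(unclass(config))), log_path)
  invisible(result)
}
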