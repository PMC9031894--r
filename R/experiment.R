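# Experiment plumbing: a flat, human-editable YAML configuration, JSONL
# metrics logging, checkpointing and frozen-weight evaluation. A thin
# command-line wrapper over these functions ships in inst/scripts/.

pkg_version_string <- function() {
  v <- tryCatch(as.character(utils::packageVersion("spikemee")),
                error = function(e) "0.1.0")
  paste0("spikemee-", v)
}

#' Experiment configuration
#'
#' A flat description of one training run: the task, overrides for the
#' training and network settings, the output directory and the seed. Round
#' trips losslessly through YAML via [save_experiment_config()] /
#' [load_experiment_config()].
#'
#' @param task task name (\code{store_recall}, \code{noisy_seq},
#'   \code{navigation}).
#' @param out_dir output directory for artifacts.
#' @param seed integer seed.
#' @param train named list of overrides for [snn_fit()] training arguments
#'   (\code{n_iterations}, \code{batch_size}, \code{mu}, \code{sigma},
#'   \code{lr}, \code{mu_f}, \code{f0}, \code{T_steps},
#'   \code{noise_fraction}).
#' @param network named list of overrides (\code{n_hidden},
#'   \code{sparsity}).
#' @return an object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(task, out_dir = "snn-run", seed = 1,
                              train = list(), network = list()) {
  if (!task %in% c("store_recall", "noisy_seq", "navigation"))
    stop_invalid("unknown task '%s'", task)
  structure(list(task = task, out_dir = out_dir, seed = as.integer(seed),
                 train = train, network = network),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config an \code{"experiment_config"}.
#' @param path file path of the YAML configuration.
#' @export
save_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname experiment_config
#' @export
load_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  experiment_config(x$task, x$out_dir %||% ".", x$seed %||% 1,
                    x$train %||% list(), x$network %||% list())
}

write_jsonl <- function(records, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Run a configured experiment
#'
#' Trains a network per the configuration and writes all artifacts into the
#' output directory: \code{config.yaml} (resolved configuration echo),
#' \code{metrics.jsonl} (one JSON record per training iteration, preceded by
#' a config/version record), \code{checkpoint.rds} (the fitted model) and
#' \code{summary.json}. Identical configuration and seed reproduce identical
#' artifacts.
#'
#' @param config an [experiment_config()] or the path to a saved one.
#' @param verbose print training progress.
#' @return invisibly, a list with the fitted model and the artifact paths.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- load_experiment_config(config)
  if (!inherits(config, "experiment_config"))
    stop_invalid("config must be an experiment_config or a path to one")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop_invalid("cannot create output directory '%s'", config$out_dir)
  save_experiment_config(config, file.path(config$out_dir, "config.yaml"))
  args <- c(list(task = config$task, seed = config$seed, verbose = verbose),
            config$train, config$network)
  fit <- do.call(snn_fit, args)
  header <- list(type = "config", version = pkg_version_string(),
                 task = config$task, seed = config$seed,
                 config = unclass(config))
  rows <- lapply(seq_len(nrow(fit$history)),
                 function(i) c(list(type = "iteration"),
                               as.list(fit$history[i, ])))
  metrics_path <- file.path(config$out_dir, "metrics.jsonl")
  write_jsonl(c(list(header), rows), metrics_path)
  ckpt_path <- file.path(config$out_dir, "checkpoint.rds")
  saveRDS(fit, ckpt_path)
  s <- summary(fit)
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(list(version = pkg_version_string(),
                            config = unclass(config),
                            final_metric = s$final_metric,
                            last10_metric = s$last10_metric,
                            final_loss = s$final_loss,
                            mean_rate_hz = s$mean_rate_hz),
                       summary_path, auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, config = config,
                 paths = list(config = file.path(config$out_dir, "config.yaml"),
                              metrics = metrics_path, checkpoint = ckpt_path,
                              summary = summary_path)))
}

#' Evaluate a saved checkpoint on fresh episodes
#'
#' Loads a fitted model (or accepts one directly) and evaluates it with
#' frozen weights - no rewiring, no updates - on newly generated episodes,
#' reporting the task metric with a binomial confidence interval.
#'
#' @param checkpoint an [snn_fit()] object or the path to a
#'   \code{checkpoint.rds}.
#' @param n_episodes episodes to evaluate; 0 returns an empty record.
#' @param seed generation seed.
#' @param conf_level confidence level of the interval.
#' @return list of class \code{"snn_evaluation"} with the metric, trial
#'   counts and confidence bounds.
#' @export
evaluate_checkpoint <- function(checkpoint, n_episodes = 200, seed = 1,
                                conf_level = 0.95) {
  fit <- if (is.character(checkpoint)) readRDS(checkpoint) else checkpoint
  if (!inherits(fit, "snn_fit")) stop_invalid("checkpoint does not contain a fitted model")
  if (n_episodes == 0)
    return(structure(list(task = fit$task, n = 0L, empty = TRUE),
                     class = "snn_evaluation"))
  pr <- predict(fit, n_episodes = n_episodes, seed = seed)
  if (fit$task == "navigation") {
    # reaches per episode are unbounded counts; Poisson interval
    succ <- pr$reached; total <- n_episodes; metric <- pr$rate
    ci <- stats::poisson.test(succ, total, conf.level = conf_level)$conf.int
  } else {
    total <- length(pr$labels); succ <- round(pr$accuracy * total)
    metric <- pr$accuracy
    ci <- stats::binom.test(succ, total, conf.level = conf_level)$conf.int
  }
  structure(list(task = fit$task, n = total, metric = metric,
                 successes = succ, conf_low = ci[1], conf_high = ci[2],
                 conf_level = conf_level, empty = FALSE,
                 version = pkg_version_string()),
            class = "snn_evaluation")
}

#' @export
print.snn_evaluation <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("Evaluation of '%s': no episodes requested\n", x$task))
  } else {
    cat(sprintf("Evaluation of '%s': metric %.3f (%d/%d), %.0f%% CI [%.3f, %.3f]\n",
                x$task, x$metric, x$successes, x$n, 100 * x$conf_level,
                x$conf_low, x$conf_high))
  }
  invisible(x)
}
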