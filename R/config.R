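# Experiment configuration and the end-to-end runner:
# synthesize -> preprocess -> train (local per site + federated) -> cross-site
# evaluation. Configurations are YAML; every run writes its fully resolved
# configuration beside its outputs so reruns are reproducible from the
# artifact directory alone.

default_experiment_config <- function() {
  list(
    seed = 1L,
    output_dir = "fedlesion_run",
    sites = list(n_train = 60L, n_val = 10L, n_test = 15L, preset = "easy",
                 grid_shape = c(32L, 32L, 16L)),
    model = list(base_width = 8L, depth = 2L, K = 2L, regionnet_hidden = 16L),
    loss = list(alpha = c(1, 1, 1, 1), lambda = c(2, 1, 2, 3),
                dice_epsilon = 1e-6, dice_variant = "as_printed",
                hist_high_variant = "suppress", delta = 1e-6),
    preprocess = list(clip = TRUE, zscore = TRUE, target_spacing = NULL),
    training = list(batch_size = 4L, epochs = 10L, lr = 3e-3,
                    weight_decay = 1e-2, eval_every = 1L, schedule = "cosine"),
    federated = list(rounds = NULL, aggregation = "sample_weighted"),
    eval = list(threshold = 0, metric = "overall"))
}

merge_config <- function(def, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(def))
      stop_fl("unknown config key '%s%s'", path, nm, class = "fl_config_error")
    if (is.null(user[[nm]])) next # explicit null keeps the default
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]])))
      def[[nm]] <- merge_config(def[[nm]], as.list(user[[nm]]), paste0(path, nm, "."))
    else def[[nm]] <- user[[nm]]
  }
  def
}

check_range <- function(value, field, min = NULL, choices = NULL) {
  if (!is.null(min) && (!is.numeric(value) || any(value < min)))
    stop_fl("config field '%s' must be numeric >= %s (got %s)", field, min,
            paste(value, collapse = ","), class = "fl_config_error")
  if (!is.null(choices) && !value %in% choices)
    stop_fl("config field '%s' must be one of %s (got '%s')", field,
            paste(choices, collapse = "/"), value, class = "fl_config_error")
  invisible(value)
}

#' Validate and resolve an experiment configuration
#'
#' Accepts a YAML file path, YAML text, or a (possibly partial) list;
#' unknown keys raise a schema error naming the field path, range violations
#' name the offending field, and every default is made explicit in the
#' resolved result, so re-validating a resolved configuration is a fixed
#' point. An empty input yields the fully-defaulted configuration.
#'
#' @param x Path to a YAML file, a YAML string, a list, or `NULL`.
#' @return Resolved configuration list of class `fl_experiment_config`.
#' @export
validate_config <- function(x = NULL) {
  user <- if (is.null(x)) list()
    else if (inherits(x, "fl_experiment_config")) unclass(x)
    else if (is.list(x)) x
    else if (is.character(x) && length(x) == 1L) {
      y <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
      y %||% list()
    } else stop_fl("cannot interpret config of class %s", class(x)[1L],
                   class = "fl_config_error")
  cfg <- merge_config(default_experiment_config(), user)
  check_range(cfg$seed, "seed", min = 0)
  for (f in c("n_train", "n_val", "n_test"))
    check_range(cfg$sites[[f]], paste0("sites.", f), min = 0)
  check_range(cfg$sites$preset, "sites.preset", choices = c("easy", "hard"))
  check_range(cfg$model$depth, "model.depth", min = 2)
  check_range(cfg$training$epochs, "training.epochs", min = 0)
  check_range(cfg$training$batch_size, "training.batch_size", min = 1)
  if (!is.null(cfg$federated$rounds))
    check_range(cfg$federated$rounds, "federated.rounds", min = 0)
  check_range(cfg$federated$aggregation, "federated.aggregation",
              choices = c("sample_weighted", "uniform"))
  check_range(cfg$eval$metric, "eval.metric",
              choices = c("balanced_accuracy", "mean_iou", "overall"))
  structure(cfg, class = "fl_experiment_config")
}

config_loss_weights <- function(cfg) {
  loss_weights(alpha = cfg$loss$alpha, lambda = cfg$loss$lambda,
               dice_epsilon = cfg$loss$dice_epsilon,
               dice_variant = cfg$loss$dice_variant,
               hist_high_variant = cfg$loss$hist_high_variant,
               delta = cfg$loss$delta)
}

preprocess_bundle <- function(b, cfg) {
  b$exam <- preprocess_exam(b$exam, target_spacing = cfg$preprocess$target_spacing,
                            clip = cfg$preprocess$clip, zscore = cfg$preprocess$zscore)
  b
}

train_config <- function(cfg, log_file = NULL) {
  list(optimizer = list(lr = cfg$training$lr, betas = c(0.9, 0.999), eps = 1e-8,
                        weight_decay = cfg$training$weight_decay,
                        schedule = cfg$training$schedule),
       aggregation = cfg$federated$aggregation,
       loss_weights = config_loss_weights(cfg),
       eval_every = cfg$training$eval_every,
       metric = cfg$eval$metric,
       threshold = cfg$eval$threshold,
       log_file = log_file)
}

# Build the preprocessed two-site benchmark of a configuration.
config_benchmark <- function(cfg) {
  bench <- make_two_site_benchmark(cfg$seed, cfg$sites$n_train, cfg$sites$n_val,
                                   cfg$sites$n_test, cfg$sites$preset,
                                   grid_shape = cfg$sites$grid_shape)
  lapply(bench, function(ds) {
    for (split in c("train", "val", "test"))
      ds[[split]] <- lapply(ds[[split]], preprocess_bundle, cfg = cfg)
    ds
  })
}

config_model <- function(cfg, tag) {
  build_model(model_config(base_width = cfg$model$base_width, depth = cfg$model$depth,
                           K = cfg$model$K, regionnet_hidden = cfg$model$regionnet_hidden,
                           seed = substream_seed(cfg$seed, paste0("model_", tag))))
}

config_client <- function(cfg, ds, tag) {
  make_client(config_model(cfg, tag),
              make_loader(ds$train, cfg$training$batch_size,
                          seed = substream_seed(cfg$seed, paste0("loader_", tag))),
              make_loader(ds$val, cfg$training$batch_size, shuffle = FALSE),
              client_id = tag)
}

#' Run a full two-site experiment
#'
#' Deterministic pipeline: synthesize the two-site benchmark, preprocess,
#' train a local model per site and one federated model (per-site best
#' checkpoints), then evaluate every checkpoint on every site's test split.
#' The artifact directory receives the resolved configuration, the per-site
#' manifests, JSON-lines training logs, the four best checkpoints and the
#' cross-site metric table as CSV.
#'
#' @param config Anything [validate_config()] accepts.
#' @return Invisibly, a list with `dir`, `config`, `cross_site`
#'   (the [cross_site_matrix()] result) and `checkpoints`.
#' @export
run_experiment <- function(config = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "resolved_config.yaml"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_fl("experiment stage '%s' failed: %s", name, conditionMessage(e),
              class = "fl_stage_error")
    })
  }

  bench <- stage("synth", config_benchmark(cfg))
  stage("manifest", {
    write.csv(rbind(bench$siteA$manifest, bench$siteB$manifest),
              file.path(cfg$output_dir, "manifest.csv"), row.names = FALSE)
  })

  checkpoints <- list()
  logs <- file.path(cfg$output_dir, "training_log.jsonl")
  for (site in names(bench)) {
    res <- stage(paste0("train-local-", site), {
      run_local(config_client(cfg, bench[[site]], paste0(site, "_local")),
                cfg$training$epochs, train_config(cfg, logs))
    })
    checkpoints[[paste0(site, "_local")]] <- res$best$model
    save_checkpoint(res$best$model,
                    file.path(cfg$output_dir, "checkpoints", paste0(site, "_local.rds")),
                    meta = list(best_round = res$best$round, metric = res$best$metric))
  }

  fed <- stage("train-fed", {
    clients <- lapply(names(bench), function(site)
      config_client(cfg, bench[[site]], paste0(site, "_fedclient")))
    # all clients start from one shared initialization
    for (i in seq_along(clients)) clients[[i]]$model <- config_model(cfg, "fed")
    rounds <- cfg$federated$rounds %||%
      (cfg$training$epochs * clients[[1L]]$train_loader$batches_per_epoch)
    run_federated(clients, rounds, train_config(cfg, logs))
  })
  for (site in names(bench)) {
    b <- fed$best[[paste0(site, "_fedclient")]]
    checkpoints[[paste0(site, "_fed")]] <- b$model
    save_checkpoint(b$model,
                    file.path(cfg$output_dir, "checkpoints", paste0(site, "_fed.rds")),
                    meta = list(best_round = b$round, metric = b$metric))
  }

  cs <- stage("eval", {
    cross_site_matrix(checkpoints,
                      lapply(bench, `[[`, "test"), cfg$eval$threshold)
  })
  write.csv(cs$table, file.path(cfg$output_dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(cs$deltas))
    write.csv(cs$deltas, file.path(cfg$output_dir, "deltas.csv"), row.names = FALSE)
  invisible(list(dir = cfg$output_dir, config = cfg, cross_site = cs,
                 checkpoints = checkpoints))
}
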