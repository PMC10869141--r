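# Local simulation of federated stochastic gradient descent. Clients compute
# per-batch gradients of the composite objective against the broadcast global
# weights; the server aggregates them (sample-weighted by default, which makes
# one round over a partitioned batch exactly equal to one centralized step)
# and applies a single AdamW update whose momentum state lives only on the
# server. Validation data, metrics and checkpoint choices stay on the client:
# the only object that crosses the client-server boundary is the sharable
# update.

#' Create a data loader over exam bundles
#'
#' A resettable iterator yielding collated batches ([collate_batch()]).
#' Batch order reshuffles every epoch from a named substream of the seed, so
#' schedules are reproducible.
#'
#' @param bundles List of exam bundles.
#' @param batch_size Exams per batch.
#' @param shuffle Reshuffle each epoch?
#' @param seed Seed for the shuffling substream.
#' @return An object of class `fl_loader` with fields `next_batch()`,
#'   `reset()`, `n` (exams) and `batches_per_epoch`.
#' @export
make_loader <- function(bundles, batch_size = 4L, shuffle = TRUE, seed = 0L) {
  force(bundles)
  n <- length(bundles)
  bpe <- max(1L, ceiling(n / batch_size))
  env <- new.env(parent = emptyenv())
  env$epoch <- 0L
  env$pos <- 1L
  env$order <- seq_len(n)
  reshuffle <- function() {
    env$order <- if (shuffle && n > 1L)
      with_seed(substream_seed(seed, "shuffle", env$epoch), sample.int(n))
    else seq_len(n)
  }
  reshuffle()
  loader <- list(
    n = n, batches_per_epoch = bpe, batch_size = batch_size,
    next_batch = function() {
      if (n == 0L) stop_fl("loader has no exams", class = "fl_precondition_error")
      take <- env$order[seq(env$pos, min(env$pos + batch_size - 1L, n))]
      env$pos <- env$pos + batch_size
      if (env$pos > n) {
        env$pos <- 1L
        env$epoch <- env$epoch + 1L
        reshuffle()
      }
      collate_batch(bundles[take])
    },
    reset = function() {
      env$pos <- 1L
      env$epoch <- 0L
      reshuffle()
      invisible(NULL)
    },
    bundles = function() bundles)
  class(loader) <- "fl_loader"
  loader
}

#' Assemble the objects a federated client must provide
#'
#' The client contract: a model implementing the forward/training-step
#' interface, a training loader, a private validation loader, and an id.
#' Model parameter names must be identical across the clients of a federation.
#'
#' @param model An `fl_model`.
#' @param train_loader,val_loader [make_loader()] objects.
#' @param client_id Identifier string.
#' @return An object of class `fl_client`.
#' @export
make_client <- function(model, train_loader, val_loader, client_id) {
  structure(list(model = model, train_loader = train_loader,
                 val_loader = val_loader, client_id = client_id),
            class = "fl_client")
}

#' Client-side gradient computation for one federated round
#'
#' Loads the broadcast global weights into the client model, runs one
#' training step on one batch from the client's loader, and returns the
#' sharable update: the named gradients of the composite loss plus the number
#' of samples. The client model is NOT stepped locally (pure FedSGD).
#'
#' @param client An `fl_client`.
#' @param global_weights Named parameter list broadcast by the server.
#' @param batch Optional explicit batch; defaults to the loader's next batch.
#' @param round_index Round counter recorded in the update.
#' @param loss_weights A [loss_weights()].
#' @return An object of class `fl_sharable`: list with `grads`, `n_samples`,
#'   `client_id`, `round_index`, `breakdown`.
#' @export
client_compute_update <- function(client, global_weights, batch = NULL,
                                  round_index = 0L, loss_weights = fedlesion::loss_weights()) {
  if (!setequal(names(global_weights), names(client$model$params)))
    stop_fl("global weight names do not match client '%s' model parameters",
            client$client_id, class = "fl_federation_schema_error")
  model <- client$model
  model$params <- global_weights[names(model$params)]
  batch <- batch %||% client$train_loader$next_batch()
  ts <- tryCatch(training_step(model, batch, loss_weights), error = function(e)
    stop_fl("failed gradient computation on client '%s': %s", client$client_id,
            conditionMessage(e), class = "fl_poisoned_update_error"))
  if (!all(vapply(ts$grads, function(g) all(is.finite(g)), TRUE)))
    stop_fl("non-finite gradient in update from client '%s'", client$client_id,
            class = "fl_poisoned_update_error")
  structure(list(grads = ts$grads, n_samples = length(batch$image),
                 client_id = client$client_id, round_index = round_index,
                 breakdown = ts$breakdown),
            class = "fl_sharable")
}

#' Aggregate client updates into one gradient
#'
#' Per-parameter average of the client gradients; `"sample_weighted"` weights
#' each client by `n_samples / sum(n_samples)` (with mean-reduced client
#' losses this reproduces the pooled-batch gradient exactly),
#' `"uniform"` weights clients equally. Aggregation is permutation-invariant
#' in client order.
#'
#' @param updates List of `fl_sharable` updates (>= 1).
#' @param mode `"sample_weighted"` or `"uniform"`.
#' @return Named list of aggregated gradients.
#' @export
aggregate_updates <- function(updates, mode = c("sample_weighted", "uniform")) {
  mode <- match.arg(mode)
  if (length(updates) < 1L)
    stop_fl("need at least one update", class = "fl_precondition_error")
  ref <- names(updates[[1L]]$grads)
  for (u in updates) {
    if (!setequal(names(u$grads), ref))
      stop_fl("update from client '%s' has a mismatching parameter name set",
              u$client_id, class = "fl_federation_schema_error")
    if (!all(vapply(u$grads, function(g) all(is.finite(g)), TRUE)))
      stop_fl("non-finite value in update from client '%s'", u$client_id,
              class = "fl_poisoned_update_error")
  }
  wts <- if (mode == "uniform") rep(1, length(updates))
         else vapply(updates, `[[`, 0, "n_samples")
  wts <- wts / sum(wts)
  agg <- updates[[1L]]$grads[ref]
  for (nm in ref) agg[[nm]] <- agg[[nm]] * wts[1L]
  for (i in seq_along(updates)[-1L])
    for (nm in ref) agg[[nm]] <- agg[[nm]] + wts[i] * updates[[i]]$grads[[nm]]
  agg
}

#' Initialize server-side AdamW optimizer state
#'
#' Decoupled weight decay: the update is
#' `w <- w - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * w)`,
#' with bias-corrected first and second moment estimates. The state (first and
#' second moments, step counter) lives only on the server.
#'
#' @param params Named parameter list (shapes are taken from it).
#' @param lr Learning rate.
#' @param betas Length-2 exponential decay rates of the moment estimates.
#' @param eps Denominator stabilizer.
#' @param weight_decay Decoupled weight decay coefficient.
#' @return An object of class `fl_adamw_state`.
#' @export
adamw_init <- function(params, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 1e-2) {
  structure(list(m = lapply(params, function(p) p * 0),
                 v = lapply(params, function(p) p * 0),
                 t = 0L, lr = lr, betas = betas, eps = eps,
                 weight_decay = weight_decay),
            class = "fl_adamw_state")
}

#' One server-side AdamW step on aggregated gradients
#'
#' @param weights Named parameter list (the global model weights).
#' @param grads Named gradient list from [aggregate_updates()].
#' @param state An `fl_adamw_state`.
#' @return List with updated `weights` and `state`.
#' @export
server_step <- function(weights, grads, state) {
  if (!setequal(names(weights), names(grads)))
    stop_fl("gradient names do not match weights", class = "fl_federation_schema_error")
  state$t <- state$t + 1L
  b1 <- state$betas[1L]; b2 <- state$betas[2L]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (!identical(dim(g) %||% length(g), dim(weights[[nm]]) %||% length(weights[[nm]])))
      stop_fl("gradient shape mismatch for parameter '%s'", nm,
              class = "fl_federation_schema_error")
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    weights[[nm]] <- weights[[nm]] -
      state$lr * (mhat / (sqrt(vhat) + state$eps) + state$weight_decay * weights[[nm]])
  }
  list(weights = weights, state = state)
}

# Private validation metrics of one client, computable from the client's own
# data at any supervision granularity: exam-level class-balanced accuracy
# (the exam is positive if any of the site's own lesion contours is predicted
# clinically significant; the exam-level maximum grade is known at every
# site, even where per-lesion grades are not) plus mean lesion IoU. Balanced
# accuracy averages per-class recall over the classes present.
client_validation_metrics <- function(model, val_loader, threshold = 0) {
  bundles <- val_loader$bundles()
  trues <- integer(0); preds <- integer(0); ious <- numeric(0)
  for (b in bundles) {
    masks <- if (!is.null(b$truth)) b$truth$masks
             else b$regions$masks[b$regions$kinds == "lesion"]
    out <- model_forward(model, b$exam, masks)
    tm <- array(0, grid_dim(b$exam))
    for (mm in masks) tm <- pmax(tm, mm)
    ious <- c(ious, lesion_iou(out$seg_map, tm, threshold))
    if (length(b$record$max_grade_group)) {
      trues <- c(trues, binarize_grade(max(b$record$max_grade_group)))
      pred_bins <- if (nrow(out$region_preds))
        max.col(out$region_preds, ties.method = "first") - 1L else integer(0)
      preds <- c(preds, as.integer(any(pred_bins == 1L)))
    }
  }
  bal <- NA_real_
  if (length(trues)) {
    rec <- vapply(sort(unique(trues)), function(k) mean(preds[trues == k] == k), 0)
    bal <- 100 * mean(rec)
  }
  list(balanced_accuracy = bal, mean_iou = mean(ious))
}

fed_config_defaults <- function(config = list()) {
  modifyList(list(
    optimizer = list(lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8, weight_decay = 1e-2,
                     schedule = "constant"),
    aggregation = "sample_weighted",
    loss_weights = loss_weights(),
    eval_every = 1L,
    metric = "balanced_accuracy",
    threshold = 0,
    log_file = NULL,
    verbose = FALSE), config)
}

log_round <- function(cfg, rec) {
  if (!is.null(cfg$log_file))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6), "\n",
        file = cfg$log_file, append = TRUE, sep = "")
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] round %s: %s", rec$stage %||% "train", rec$round_index,
                    paste(sprintf("%s=%.4f", names(rec$loss %||% list()),
                                  unlist(rec$loss %||% list())), collapse = " ")))
}

# Learning-rate multiplier of step t out of `total` steps. "cosine" holds the
# full rate for the first 60% of the run (the classification task can emerge
# late under diluted federated gradients) and then anneals to 0.1, damping the
# late-round oscillation of the multi-task trade-off so late checkpoints are
# uniformly usable.
lr_factor <- function(schedule, t, total) {
  if (identical(schedule, "cosine") && total > 1L) {
    hold <- 0.6 * total
    if (t <= hold) 1
    else 0.1 + 0.9 * 0.5 * (1 + cos(pi * (t - hold) / (total - hold)))
  } else 1
}

init_optimizer <- function(params, optimizer) {
  optimizer$schedule <- NULL
  do.call(adamw_init, c(list(params = params), optimizer))
}

select_metric <- function(metrics, metric) {
  if (metric == "overall") {
    # geometric mean of both tasks' validation performance: a checkpoint must
    # do well at classification AND segmentation, so a noise spike in one
    # (e.g. the coarse exam-level accuracy of a weakly supervised site early
    # in training) cannot dominate the selection
    if (is.na(metrics$balanced_accuracy)) return(100 * metrics$mean_iou)
    return(sqrt(pmax(0, metrics$balanced_accuracy) * pmax(0, 100 * metrics$mean_iou)))
  }
  v <- metrics[[metric]]
  if (is.null(v) || is.na(v)) metrics$mean_iou else v
}

#' Run the federated training simulation
#'
#' Per round: broadcast the global weights, collect one gradient update per
#' client, aggregate, apply one server AdamW step, then let every client
#' evaluate the new weights on its own private validation split (every
#' `eval_every` rounds) and track its own best round. Clients may therefore
#' select different "best" checkpoints; both are returned. A client failure
#' aborts the round (synchronous FedSGD semantics).
#'
#' @param clients List of `fl_client` objects (>= 1) with identical model
#'   parameter name sets.
#' @param rounds Number of federated rounds.
#' @param config Optional list overriding the defaults: `optimizer` (lr,
#'   betas, eps, weight_decay), `aggregation`, `loss_weights`, `eval_every`,
#'   `metric` (`"balanced_accuracy"` or `"mean_iou"` for checkpoint
#'   selection), `threshold`, `log_file` (JSON-lines), `verbose`.
#' @return List with `round_logs` (one record per round), `best` (per client:
#'   `round`, `metric`, `model`), and `final` (the last global model).
#' @export
run_federated <- function(clients, rounds, config = list()) {
  stopifnot(length(clients) >= 1L)
  cfg <- fed_config_defaults(config)
  global <- clients[[1L]]$model
  opt <- init_optimizer(global$params, cfg$optimizer)
  base_lr <- opt$lr
  best <- lapply(clients, function(cl) list(round = 0L, metric = -Inf, model = NULL))
  names(best) <- vapply(clients, `[[`, "", "client_id")
  round_logs <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    updates <- lapply(clients, function(cl)
      client_compute_update(cl, global$params, round_index = r,
                            loss_weights = cfg$loss_weights))
    agg <- aggregate_updates(updates, cfg$aggregation)
    opt$lr <- base_lr * lr_factor(cfg$optimizer$schedule, r, rounds)
    st <- server_step(global$params, agg, opt)
    global$params <- st$weights
    opt <- st$state
    losses <- lapply(updates, function(u) u$breakdown$total)
    names(losses) <- names(best)
    rec <- list(stage = "federated", round_index = r, loss = losses)
    if (r %% cfg$eval_every == 0L || r == rounds) {
      for (i in seq_along(clients)) {
        met <- client_validation_metrics(global, clients[[i]]$val_loader, cfg$threshold)
        sel <- select_metric(met, cfg$metric)
        # ties prefer the later (more trained) round
        if (is.finite(sel) && sel >= best[[i]]$metric)
          best[[i]] <- list(round = r, metric = sel, model = global)
        rec[[paste0("val_", names(best)[i])]] <- met
      }
    }
    round_logs[[r]] <- rec
    log_round(cfg, rec)
  }
  for (i in seq_along(best)) if (is.null(best[[i]]$model)) best[[i]]$model <- global
  list(round_logs = round_logs, best = best, final = global)
}

#' Conventional single-site training loop (the "-local" baselines)
#'
#' Same model, objective, optimizer and checkpoint-selection rule as the
#' federated loop, but gradients are applied locally after every batch.
#' With 0 epochs the initialization is returned as best.
#'
#' @param client An `fl_client`.
#' @param epochs Number of passes over the client's training data.
#' @param config As in [run_federated()].
#' @return List with `epoch_logs`, `best` (`round` holds the best epoch) and
#'   `final` model.
#' @export
run_local <- function(client, epochs, config = list()) {
  cfg <- fed_config_defaults(config)
  model <- client$model
  opt <- init_optimizer(model$params, cfg$optimizer)
  base_lr <- opt$lr
  total_steps <- max(1L, epochs * client$train_loader$batches_per_epoch)
  step_i <- 0L
  best <- list(round = 0L, metric = -Inf, model = model)
  met0 <- client_validation_metrics(model, client$val_loader, cfg$threshold)
  sel0 <- select_metric(met0, cfg$metric)
  if (is.finite(sel0)) best$metric <- sel0
  epoch_logs <- vector("list", epochs)
  client$train_loader$reset()
  for (e in seq_len(epochs)) {
    tot <- 0
    for (s in seq_len(client$train_loader$batches_per_epoch)) {
      ts <- training_step(model, client$train_loader$next_batch(), cfg$loss_weights)
      step_i <- step_i + 1L
      opt$lr <- base_lr * lr_factor(cfg$optimizer$schedule, step_i, total_steps)
      st <- server_step(model$params, ts$grads, opt)
      model$params <- st$weights
      opt <- st$state
      tot <- tot + ts$breakdown$total
    }
    met <- client_validation_metrics(model, client$val_loader, cfg$threshold)
    sel <- select_metric(met, cfg$metric)
    if (is.finite(sel) && sel >= best$metric) # ties prefer the later epoch
      best <- list(round = e, metric = sel, model = model)
    rec <- list(stage = "local", client_id = client$client_id, round_index = e,
                loss = list(total = tot / client$train_loader$batches_per_epoch),
                val = met)
    epoch_logs[[e]] <- rec
    log_round(cfg, rec)
  }
  list(epoch_logs = epoch_logs, best = best, final = model)
}
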