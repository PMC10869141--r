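# Federated simulation: client updates, aggregation, the server AdamW
# optimizer, and the equivalence/privacy guarantees of the FedSGD pattern.

fed_bundle <- function(i, d = c(8L, 8L, 4L)) {
  ex <- tiny_exam(i, d = d)
  list(exam = ex,
       regions = region_set(list(mask_of(d, 3 * i + 1, 14)), "lesion"),
       record = supervision_record(1L, if (i %% 2) 3L else 0L),
       labels = groundtruth_labels(mask_of(d, 3 * i + 1, 14),
                                   onehot_rows(as.integer(i %% 2))))
}

fed_client <- function(id, bundles, model, batch_size = length(bundles)) {
  make_client(model, make_loader(bundles, batch_size, shuffle = FALSE),
              make_loader(bundles[1], 1, shuffle = FALSE), id)
}

test_that("client updates carry the full parameter name set and are deterministic", {
  m <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 1))
  cl <- fed_client("c1", lapply(1:2, fed_bundle), m)
  batch <- collate_batch(lapply(1:2, fed_bundle))
  u1 <- client_compute_update(cl, m$params, batch = batch, round_index = 1L)
  u2 <- client_compute_update(cl, m$params, batch = batch, round_index = 1L)
  expect_setequal(names(u1$grads), names(m$params))
  expect_identical(u1$grads, u2$grads)
  expect_identical(u1$n_samples, 2L)
  expect_identical(u1$client_id, "c1")

  # non-finite inputs surface as a poisoned update naming the client
  bad <- fed_bundle(1)
  bad$exam$image[1, 1, 1, 1] <- Inf
  err <- tryCatch(client_compute_update(cl, m$params, batch = collate_batch(list(bad))),
                  error = function(e) e)
  expect_s3_class(err, "fl_poisoned_update_error")
  expect_match(conditionMessage(err), "c1")

  # mismatching global names are rejected
  wrong <- m$params
  names(wrong)[1] <- "bogus"
  expect_error(client_compute_update(cl, wrong), class = "fl_federation_schema_error")
})

test_that("aggregation averages, weights by samples, and ignores client order", {
  m <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 2))
  cl <- fed_client("c", lapply(1:2, fed_bundle), m)
  u1 <- client_compute_update(cl, m$params, batch = collate_batch(list(fed_bundle(1))))
  u2 <- client_compute_update(cl, m$params, batch = collate_batch(lapply(2:4, fed_bundle)))
  agg_same <- aggregate_updates(list(u1, u1))
  for (nm in names(u1$grads)) expect_equal(agg_same[[nm]], u1$grads[[nm]])
  # n = 1 vs n = 3: (1*g1 + 3*g2)/4
  agg <- aggregate_updates(list(u1, u2), "sample_weighted")
  for (nm in names(u1$grads))
    expect_equal(agg[[nm]], (u1$grads[[nm]] + 3 * u2$grads[[nm]]) / 4, tolerance = 1e-12)
  agg_u <- aggregate_updates(list(u1, u2), "uniform")
  for (nm in names(u1$grads))
    expect_equal(agg_u[[nm]], (u1$grads[[nm]] + u2$grads[[nm]]) / 2, tolerance = 1e-12)
  # permutation invariance
  agg_p <- aggregate_updates(list(u2, u1), "sample_weighted")
  for (nm in names(u1$grads)) expect_equal(agg_p[[nm]], agg[[nm]])

  u_bad <- u2
  u_bad$grads[[3]][1] <- NaN
  expect_error(aggregate_updates(list(u1, u_bad)), class = "fl_poisoned_update_error")
  u_ren <- u2
  names(u_ren$grads)[1] <- "bogus"
  expect_error(aggregate_updates(list(u1, u_ren)), class = "fl_federation_schema_error")
})

test_that("server AdamW matches its closed forms and reference recurrence", {
  w <- list(a = c(1, -2), b = matrix(c(0.5, 0, -0.5, 1), 2))
  st <- adamw_init(w, lr = 0.01, weight_decay = 0.1)
  # zero gradient: pure decoupled weight-decay shrinkage
  z <- lapply(w, function(p) p * 0)
  s1 <- server_step(w, z, st)
  for (nm in names(w)) expect_equal(s1$weights[[nm]], w[[nm]] * (1 - 0.01 * 0.1))

  # first step with decay 0: update = -lr * g / (|g| + eps) after bias correction
  g <- list(a = c(0.3, -0.7), b = matrix(c(1, -1, 2, -2), 2))
  st0 <- adamw_init(w, lr = 0.05, weight_decay = 0)
  s2 <- server_step(w, g, st0)
  for (nm in names(w)) {
    mhat <- g[[nm]]          # m/(1-b1) with m = (1-b1) g
    vhat <- g[[nm]]^2
    expect_equal(s2$weights[[nm]], w[[nm]] - 0.05 * mhat / (sqrt(vhat) + 1e-8),
                 tolerance = 1e-12)
  }

  # two successive identical gradients against a hand-rolled recurrence
  lr <- 0.02; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; wd <- 0.01
  st2 <- adamw_init(w, lr = lr, betas = c(b1, b2), eps = eps, weight_decay = wd)
  r1 <- server_step(w, g, st2)
  r2 <- server_step(r1$weights, g, r1$state)
  for (nm in names(w)) {
    m1 <- (1 - b1) * g[[nm]]; v1 <- (1 - b2) * g[[nm]]^2
    w1 <- w[[nm]] - lr * ((m1 / (1 - b1)) / (sqrt(v1 / (1 - b2)) + eps) + wd * w[[nm]])
    m2 <- b1 * m1 + (1 - b1) * g[[nm]]; v2 <- b2 * v1 + (1 - b2) * g[[nm]]^2
    w2 <- w1 - lr * ((m2 / (1 - b1^2)) / (sqrt(v2 / (1 - b2^2)) + eps) + wd * w1)
    expect_equal(r1$weights[[nm]], w1, tolerance = 1e-12)
    expect_equal(r2$weights[[nm]], w2, tolerance = 1e-12)
  }
  expect_error(server_step(w, list(a = 1, b = 2), st), class = "fl_federation_schema_error")
})

test_that("one federated round over any partition equals one centralized step", {
  pool <- lapply(1:6, fed_bundle)
  m <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 5))
  opt <- list(lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8, weight_decay = 1e-2)

  # centralized oracle: one AdamW step on the pooled batch
  ts <- training_step(m, collate_batch(pool))
  st <- do.call(adamw_init, c(list(params = m$params), opt))
  central <- server_step(m$params, ts$grads, st)$weights

  for (parts in list(list(1:3, 4:6), list(1, 2:3, 4:6), list(1, 2, 3, 4, 5, 6))) {
    clients <- lapply(seq_along(parts), function(i)
      fed_client(paste0("c", i), pool[parts[[i]]], m))
    updates <- lapply(clients, function(cl)
      client_compute_update(cl, m$params, round_index = 1L))
    agg <- aggregate_updates(updates, "sample_weighted")
    st_i <- do.call(adamw_init, c(list(params = m$params), opt))
    fedw <- server_step(m$params, agg, st_i)$weights
    dev <- max(vapply(names(fedw), function(nm)
      max(abs(fedw[[nm]] - central[[nm]]) /
            pmax(1e-8, abs(central[[nm]]))), 0))
    expect_lt(dev, 1e-5)
  }
})

test_that("a single-client federation reduces to centralized training", {
  bundles <- lapply(1:4, fed_bundle)
  m <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 7))
  cfg <- list(eval_every = 2L)
  cl_fed <- fed_client("solo", bundles, m, batch_size = 4L)
  fed <- run_federated(list(cl_fed), rounds = 3L, cfg)
  cl_loc <- fed_client("solo", bundles, m, batch_size = 4L)
  loc <- run_local(cl_loc, epochs = 3L, cfg)
  for (nm in names(m$params))
    expect_equal(fed$final$params[[nm]], loc$final$params[[nm]], tolerance = 1e-12)
})

test_that("federated logs are complete and symmetric clients pick the same round", {
  bundles <- lapply(1:4, fed_bundle)
  m <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 8))
  clients <- list(fed_client("east", bundles, m), fed_client("west", bundles, m))
  fed <- run_federated(clients, rounds = 4L, list(eval_every = 2L))
  expect_length(fed$round_logs, 4L)
  expect_identical(vapply(fed$round_logs, `[[`, 0L, "round_index"), 1:4)
  expect_identical(fed$best$east$round, fed$best$west$round)
  expect_identical(fed$best$east$model$params, fed$best$west$model$params)
})

test_that("only sharable updates cross the client-server boundary", {
  bundles <- lapply(1:2, fed_bundle)
  m <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 9))
  cl <- fed_client("private", bundles, m)
  u <- client_compute_update(cl, m$params, round_index = 1L)
  # the sharable exposes gradients and bookkeeping only: no images, masks,
  # labels or validation metrics
  expect_setequal(names(u), c("grads", "n_samples", "client_id", "round_index", "breakdown"))
  expect_s3_class(u, "fl_sharable")
  # the server-side path accepts sharables alone; its formals name no client
  expect_false(any(grepl("client|loader|val", names(formals(aggregate_updates)))))
  expect_false(any(grepl("client|loader|val", names(formals(server_step)))))
})

test_that("local training tracks the best epoch and is reproducible", {
  bundles <- lapply(1:4, fed_bundle)
  m <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 10))
  cl0 <- fed_client("c", bundles, m)
  r0 <- run_local(cl0, epochs = 0L, list())
  expect_identical(r0$best$round, 0L)
  expect_identical(r0$best$model$params, m$params)

  r5a <- run_local(fed_client("c", bundles, m), epochs = 5L, list())
  r5b <- run_local(fed_client("c", bundles, m), epochs = 5L, list())
  expect_identical(r5a$best$round, r5b$best$round)
  loss <- vapply(r5a$epoch_logs, function(e) e$loss$total, 0)
  expect_lt(loss[5], loss[1]) # smoothed downward trend on the smoke fixture
})
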