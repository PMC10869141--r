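# Closed forms, dispatch semantics and gradients of the multi-task objective.

test_that("soft region histograms average the per-voxel class probabilities", {
  d <- c(5L, 4L, 2L)
  gg <- array(0, c(2, d))
  gg[1, , , ] <- 0.7
  gg[2, , , ] <- 0.3
  m <- mask_of(d, 3, 10)
  expect_equal(soft_region_histogram(gg, m), c(0.7, 0.3))

  # 6 one-hot class-0 voxels and 4 one-hot class-1 voxels -> [0.6, 0.4]
  gg2 <- array(0, c(2, d))
  gg2[1, , , ][1:6] <- 1
  gg2[2, , , ][7:10] <- 1
  gg2[1, , , ][11:prod(d)] <- 1
  expect_equal(soft_region_histogram(gg2, mask_of(d, 1, 10)), c(0.6, 0.4))

  # one-voxel region is the identity
  gg3 <- array(c(0.25, 0.75), c(2, 1, 1, 1))
  expect_equal(soft_region_histogram(gg3, array(1, c(1, 1, 1))), c(0.25, 0.75))

  expect_error(soft_region_histogram(gg, array(0, d)), class = "fl_empty_region_error")
})

test_that("dice loss matches the printed closed form in both variants", {
  d <- c(4L, 2L, 2L)
  y <- mask_of(d, 1, 8)
  w <- loss_weights(dice_epsilon = 1e-9)
  # identical masks, no factor 2: 1 - 8/16 = 0.5
  expect_equal(dice_loss(y, y, w), 0.5, tolerance = 1e-8)
  expect_equal(dice_loss(y, y, loss_weights(dice_variant = "standard", dice_epsilon = 1e-9)),
               0, tolerance = 1e-7)
  # disjoint masks: 1 in both variants
  y2 <- mask_of(d, 9, 8)
  expect_equal(dice_loss(y, y2, w), 1)
  expect_equal(dice_loss(y, y2, loss_weights(dice_variant = "standard")), 1)
  # |y| = 4, |yhat| = 6, overlap 3, eps = 1e-6: 1 - 3/(10 + 1e-6)
  ya <- mask_of(d, 1, 4)
  yb <- mask_of(d, 2, 6)
  expect_equal(dice_loss(ya, yb, loss_weights(dice_epsilon = 1e-6)),
               1 - 3 / (10 + 1e-6), tolerance = 1e-12)
})

test_that("segmentation loss = dice + BCE through the tanh-to-probability map", {
  d <- c(2L, 2L, 2L)
  # all-ones target, prediction 0 on the tanh scale (p = 0.5)
  y <- array(1, d)
  yhat <- array(0, d)
  v <- segmentation_loss(y, yhat, loss_weights(dice_epsilon = 1e-6))
  dice <- 1 - 8 * 0.5 / (8 + 4 + 1e-6)
  expect_equal(v, dice + log(2), tolerance = 1e-9)
  # perfect negative prediction: BCE about -log(1 - delta) i.e. about 0;
  # the printed dice form with an empty target evaluates to exactly 1
  v0 <- segmentation_loss(array(0, d), array(-1, d), loss_weights())
  expect_equal(v0, 1, tolerance = 1e-5)
  expect_error(segmentation_loss(y, array(1.5, d)), class = "fl_activation_range_error")
})

test_that("segmentation loss is minimized by the perfect prediction", {
  set.seed(3)
  d <- c(3L, 3L, 2L)
  y <- array(rbinom(prod(d), 1, 0.4), d)
  w <- loss_weights()
  best <- segmentation_loss(y, 2 * y - 1, w)
  # grid of constant predictions plus random fields never beats 2y - 1
  for (cst in seq(-0.95, 0.95, by = 0.19))
    expect_gte(segmentation_loss(y, array(cst, d), w), best)
  for (i in 1:20)
    expect_gte(segmentation_loss(y, tanh(array(rnorm(prod(d)), d)), w), best)
})

test_that("voxel-wise grading loss dispatches on strong lesion regions", {
  fx <- tiny_supervision(1)
  K <- 2L
  # uniform softmax: ln 2 regardless of the label
  gg <- array(0.5, c(K, fx$d))
  v <- ggmap_loss(gg, fx$regions, fx$record, fx$labels)
  expect_equal(as.numeric(v), log(2), tolerance = 1e-9)
  expect_equal(attr(v, "active_count"), 1L) # only the signal-1 lesion

  # empty active set: 0 with count 0
  rec0 <- supervision_record(c(2L, 2L, 0L), fx$record$max_grade_group)
  v0 <- ggmap_loss(gg, fx$regions, rec0, fx$labels)
  expect_identical(as.numeric(v0), 0)
  expect_identical(attr(v0, "active_count"), 0L)

  # perfect one-hot prediction scores about 0
  ggp <- array(0, c(K, fx$d))
  lbl <- which(fx$labels$region_onehot[1, ] == 1)
  ggp[lbl, , , ] <- 1
  ggp[-lbl, , , ] <- 0
  expect_lt(as.numeric(ggmap_loss(ggp, fx$regions, fx$record, fx$labels)), 1e-5)
})

test_that("strong histogram loss is the categorical cross-entropy of active rows", {
  fx <- tiny_supervision(1)
  h <- rbind(c(0.5, 0.5), c(0.9, 0.1), c(0.2, 0.8))
  # region 1 labelled class 1 (grade 3 -> positive): -log 0.5
  expect_equal(as.numeric(hist_strong_loss(h, fx$record, fx$labels)), log(2))
  # one-hot histogram at the labelled class: about 0
  h2 <- rbind(c(0, 1), c(1, 0), c(1, 0))
  expect_lt(as.numeric(hist_strong_loss(h2, fx$record, fx$labels)), 1e-5)
  rec0 <- supervision_record(c(0L, 2L, 0L), fx$record$max_grade_group)
  expect_identical(as.numeric(hist_strong_loss(h, rec0, fx$labels)), 0)
})

test_that("histogram suppression penalizes mass above the labelled grade bin", {
  rec <- supervision_record(c(2L, 2L, 2L), c(0L, 3L, 1L))
  h <- rbind(c(0.8, 0.2), c(0.3, 0.7), c(1, 0))
  w <- loss_weights()
  # region 1: negative label, suppressed bin has 0.2 -> -log(0.8);
  # region 2: labelled at the top bin -> 0; region 3: zero mass -> 0
  expect_equal(as.numeric(hist_high_loss(h, rec, w)), -log(0.8) / 3, tolerance = 1e-9)
  one <- supervision_record(2L, 0L)
  expect_equal(as.numeric(hist_high_loss(h[1, , drop = FALSE], one, w)),
               -log(0.8), tolerance = 1e-9)
  expect_equal(as.numeric(hist_high_loss(h[2, , drop = FALSE],
                                         supervision_record(2L, 3L), w)), 0)
  expect_equal(as.numeric(hist_high_loss(h[3, , drop = FALSE],
                                         supervision_record(2L, 0L), w)), 0)
  # the literal printed form is identically zero and warns
  wp <- loss_weights(hist_high_variant = "as_printed")
  expect_warning(vp <- hist_high_loss(h, rec, wp), "identically zero")
  expect_identical(as.numeric(vp), 0)
})

test_that("region classifier loss covers signal 1 and 2, excludes signal 0", {
  fx <- tiny_supervision(1)
  z <- rbind(c(0.25, 0.75), c(0.25, 0.75), c(0.5, 0.5))
  # region 1 label class 1: -log 0.75; region 2 label class 0: -log 0.25
  expect_equal(as.numeric(region_classifier_loss(z, fx$record, fx$labels)),
               (-log(0.75) - log(0.25)) / 2, tolerance = 1e-9)
  # single region labelled class 0 with z = [0.25, 0.75]: -log 0.25
  expect_equal(as.numeric(region_classifier_loss(
    z[2, , drop = FALSE], supervision_record(2L, 0L),
    groundtruth_labels(array(0, fx$d), onehot_rows(0L)))), -log(0.25), tolerance = 1e-9)
  # removing an ignored region leaves the loss unchanged
  keep <- 1:2
  v_all <- region_classifier_loss(z, fx$record, fx$labels)
  v_sub <- region_classifier_loss(
    z[keep, ], supervision_record(fx$record$signal[keep], fx$record$max_grade_group[keep]),
    groundtruth_labels(fx$labels$seg_mask, fx$labels$region_onehot[keep, ]))
  expect_equal(as.numeric(v_all), as.numeric(v_sub))
})

test_that("composite loss equals the weighted sum of its parts", {
  fx <- tiny_supervision(2)
  model <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 2))
  out <- tiny_outputs(model, fx)
  w <- loss_weights(alpha = c(1, 0.5, 2, 1), lambda = c(0.7, 1, 1, 3))
  bd <- composite_loss(out, fx$regions, fx$record, fx$labels, w)
  seg <- segmentation_loss(fx$labels$seg_mask, out$seg_map, w)
  gg <- ggmap_loss(out$gg_map, fx$regions, fx$record, fx$labels, w)
  hs <- hist_strong_loss(out$region_histograms, fx$record, fx$labels, w)
  hh <- hist_high_loss(out$region_histograms, fx$record, w)
  rc <- region_classifier_loss(out$region_preds, fx$record, fx$labels, w)
  expect_equal(bd$total,
               0.7 * as.numeric(rc) + 0.5 * (as.numeric(hs) + as.numeric(hh)) +
                 2 * as.numeric(gg) + 3 * seg, tolerance = 1e-9)
  expect_equal(bd$segmentation, as.numeric(seg))
  expect_equal(bd$ggmap, as.numeric(gg))
  expect_equal(bd$ggmap_hist, as.numeric(hs) + as.numeric(hh))
  expect_equal(bd$region_classifier, as.numeric(rc))
})

test_that("composite loss dynamically populates terms from the supervision pattern", {
  model <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 3))
  d <- c(6L, 6L, 3L)
  # exam with zero regions and empty mask: only segmentation is active, and a
  # confident all-negative prediction leaves just the irreducible dice constant
  out0 <- structure(list(seg_map = array(-1 + 1e-9, d),
                         gg_map = rand_gg_map(5, d = d),
                         region_histograms = matrix(0, 0, 2),
                         region_preds = matrix(0, 0, 2)),
                    class = "fl_model_outputs")
  lab0 <- groundtruth_labels(array(0, d), matrix(0, 0, 2))
  bd0 <- composite_loss(out0, region_set(), supervision_record(), lab0)
  expect_equal(bd0$total, bd0$segmentation)
  expect_true(all(bd0$active == 0))

  # exam-level-max style exam: single weak gland region
  fx <- tiny_supervision(4)
  gl <- region_set(list(array(1, fx$d)), "gland")
  rec <- supervision_record(2L, 1L)
  lab <- groundtruth_labels(fx$labels$seg_mask, onehot_rows(0L))
  out <- tiny_outputs(model, list(regions = gl, record = rec, labels = lab, d = fx$d))
  bd <- composite_loss(out, gl, rec, lab)
  expect_identical(unname(bd$active[c("ggmap", "hist_strong")]), c(0L, 0L))
  expect_identical(unname(bd$active[c("hist_high", "region_classifier")]), c(1L, 1L))
  expect_equal(bd$ggmap, 0)
})

test_that("every histogram row sums to 1 over many random fixtures", {
  worst <- 0
  for (i in 1:1000) {
    d <- c(4L + (i %% 3), 4L, 2L)
    gg <- rand_gg_map(i, d = d, scale = 3)
    m <- mask_of(d, 1 + (i %% 7), 3 + (i %% 11))
    h <- soft_region_histogram(gg, m)
    worst <- max(worst, abs(sum(h) - 1))
    expect_true(all(h >= 0 & h <= 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("composite loss is finite and term-correct for all 27 supervision patterns", {
  model <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 6))
  d <- c(6L, 6L, 3L)
  masks <- list(mask_of(d, 1, 9), mask_of(d, 15, 20), mask_of(d, 40, 30))
  kinds <- c("lesion", "lesion", "sextant")
  gg_vals <- c(3L, 0L, 2L)
  seg <- pmax(masks[[1]], masks[[2]])
  grid <- expand.grid(s1 = 0:2, s2 = 0:2, s3 = 0:2)
  for (i in seq_len(nrow(grid))) {
    sig <- as.integer(grid[i, ])
    regions <- region_set(masks, kinds)
    rec <- supervision_record(sig, gg_vals)
    lab <- groundtruth_labels(seg, onehot_rows(binarize_grade(gg_vals)))
    out <- tiny_outputs(model, list(regions = regions, record = rec, labels = lab, d = d),
                        ex_seed = i)
    bd <- composite_loss(out, regions, rec, lab)
    expect_true(is.finite(bd$total))
    # per-term oracle: recompute each term on the regions its signal selects
    expect_identical(unname(bd$active["ggmap"]), sum(sig == 1L & kinds == "lesion"))
    expect_identical(unname(bd$active["hist_strong"]), sum(sig == 1L))
    expect_identical(unname(bd$active["hist_high"]), sum(sig == 2L))
    expect_identical(unname(bd$active["region_classifier"]), sum(sig > 0L))
    hs <- hist_strong_loss(out$region_histograms, rec, lab)
    hh <- hist_high_loss(out$region_histograms, rec)
    expect_equal(bd$ggmap_hist, as.numeric(hs) + as.numeric(hh), tolerance = 1e-12)
    if (all(sig == 0L)) {
      expect_equal(bd$total, bd$segmentation)
      expect_equal(bd$region_classifier + bd$ggmap_hist + bd$ggmap, 0)
    }
  }
})

test_that("all loss terms are non-negative and hist_high is monotone in suppressed mass", {
  fx <- tiny_supervision(3)
  model <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 9))
  for (i in 1:10) {
    out <- tiny_outputs(model, fx, ex_seed = 100 + i)
    bd <- composite_loss(out, fx$regions, fx$record, fx$labels)
    expect_gte(bd$segmentation, 0)
    expect_gte(bd$ggmap, 0)
    expect_gte(bd$ggmap_hist, 0)
    expect_gte(bd$region_classifier, 0)
  }
  rec <- supervision_record(2L, 0L)
  vals <- seq(0.02, 0.9, by = 0.05)
  losses <- vapply(vals, function(p)
    as.numeric(hist_high_loss(matrix(c(1 - p, p), 1), rec)), 0)
  expect_true(all(diff(losses) > 0))
})

test_that("permuting regions or adding an ignored region changes no loss value", {
  fx <- tiny_supervision(8)
  model <- build_model(model_config(base_width = 4, regionnet_hidden = 4, seed = 10))
  out <- tiny_outputs(model, fx)
  bd <- composite_loss(out, fx$regions, fx$record, fx$labels)

  perm <- c(3L, 1L, 2L)
  regions_p <- region_set(fx$regions$masks[perm], fx$regions$kinds[perm])
  rec_p <- supervision_record(fx$record$signal[perm], fx$record$max_grade_group[perm])
  lab_p <- groundtruth_labels(fx$labels$seg_mask, fx$labels$region_onehot[perm, ])
  out_p <- out
  out_p$region_histograms <- out$region_histograms[perm, ]
  out_p$region_preds <- out$region_preds[perm, ]
  bd_p <- composite_loss(out_p, regions_p, rec_p, lab_p)
  for (t in c("total", "region_classifier", "ggmap_hist", "ggmap", "segmentation"))
    expect_equal(bd_p[[t]], bd[[t]], tolerance = 1e-12)

  # appending a signal-0 region is a no-op
  d <- fx$d
  regions_a <- region_set(c(fx$regions$masks, list(mask_of(d, 60, 9))),
                          c(fx$regions$kinds, "lesion"))
  rec_a <- supervision_record(c(fx$record$signal, 0L),
                              c(fx$record$max_grade_group, 5L))
  lab_a <- groundtruth_labels(fx$labels$seg_mask,
                              rbind(fx$labels$region_onehot, onehot_rows(1L)))
  out_a <- out
  out_a$region_histograms <- rbind(out$region_histograms, c(0.4, 0.6))
  out_a$region_preds <- rbind(out$region_preds, c(0.5, 0.5))
  bd_a <- composite_loss(out_a, regions_a, rec_a, lab_a)
  for (t in c("total", "region_classifier", "ggmap_hist", "ggmap", "segmentation"))
    expect_equal(bd_a[[t]], bd[[t]], tolerance = 1e-12)
})

test_that("analytic gradients of every loss term match central finite differences", {
  fx <- tiny_supervision(5, d = c(4L, 4L, 2L))
  d <- fx$d
  w <- loss_weights()
  set.seed(77)

  # segmentation w.r.t. the tanh-activated map (kept away from the clamp)
  y <- array(rbinom(prod(d), 1, 0.3), d)
  yhat <- tanh(array(rnorm(prod(d)), d)) * 0.95
  sp <- fedlesion:::segmentation_parts(y, yhat, w)
  fd <- fd_grad(function(v) fedlesion:::segmentation_parts(y, array(v, d), w)$value, yhat)
  expect_lt(max_rel_err(sp$grad, fd), 1e-4)

  # voxel-wise grading w.r.t. the softmax map (treated as a free field)
  gg <- rand_gg_map(21, d = d, scale = 1) * 0.9 + 0.05
  gp <- fedlesion:::ggmap_parts(gg, fx$regions, fx$record, fx$labels, w)
  fd <- fd_grad(function(v) fedlesion:::ggmap_parts(array(v, dim(gg)), fx$regions,
                                                    fx$record, fx$labels, w)$value, gg)
  expect_lt(max_rel_err(gp$grad, fd), 1e-4)

  # histogram terms and the region classifier w.r.t. their matrix inputs
  h <- matrix(runif(6, 0.1, 0.9), 3, 2)
  hp <- fedlesion:::hist_strong_parts(h, fx$record, fx$labels, w)
  fd <- fd_grad(function(v) fedlesion:::hist_strong_parts(matrix(v, 3), fx$record,
                                                          fx$labels, w)$value, h)
  expect_lt(max_rel_err(hp$grad, fd), 1e-4)

  hq <- fedlesion:::hist_high_parts(h, fx$record, w)
  fd <- fd_grad(function(v) fedlesion:::hist_high_parts(matrix(v, 3), fx$record, w)$value, h)
  expect_lt(max_rel_err(hq$grad, fd), 1e-4)

  z <- matrix(runif(6, 0.1, 0.9), 3, 2)
  rp <- fedlesion:::region_classifier_parts(z, fx$record, fx$labels, w)
  fd <- fd_grad(function(v) fedlesion:::region_classifier_parts(matrix(v, 3), fx$record,
                                                                fx$labels, w)$value, z)
  expect_lt(max_rel_err(rp$grad, fd), 1e-4)

  # dice alone, both variants
  for (variant in c("as_printed", "standard")) {
    wv <- loss_weights(dice_variant = variant)
    p <- array(runif(prod(d), 0.05, 0.95), d)
    dp <- fedlesion:::dice_parts(y, p, wv)
    fd <- fd_grad(function(v) fedlesion:::dice_parts(y, array(v, d), wv)$value, p)
    expect_lt(max_rel_err(dp$grad, fd), 1e-4)
  }
})
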