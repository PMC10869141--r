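#' Configuration of the lesion detection network
#'
#' A small, size-configurable 3D residual encoder-decoder with two voxel-wise
#' output heads (a tanh lesion segmentation map and a softmax grade-group map)
#' and a region classification head (a two-layer perceptron on the soft region
#' histograms). Each encoder level is a residual block (two convolutions,
#' instance normalization, additive skip); downsampling is a stride-2
#' convolution, upsampling is factor-2 trilinear interpolation followed by a
#' convolution, and encoder features re-enter the decoder through additive
#' skip connections. At the defaults the model has under 30k parameters, so a
#' full training run fits in CPU minutes.
#'
#' @param input_channels Number of image channels (3: T2WI, DWI, ADC).
#' @param base_width Channel width of the first level (doubles per level).
#' @param depth Number of encoder levels (>= 2); grid dimensions must be
#'   divisible by `2^(depth - 1)`.
#' @param K Number of grade classes (2 for the clinically-significant binary task).
#' @param regionnet_hidden Hidden width of the region classification head.
#' @param seed Seed for weight initialization.
#' @return An object of class `fl_model_config`.
#' @export
model_config <- function(input_channels = 3L, base_width = 8L, depth = 2L, K = 2L,
                         regionnet_hidden = 16L, seed = 1L) {
  if (depth < 2L) stop_fl("depth must be >= 2", class = "fl_precondition_error")
  if (K < 2L) stop_fl("K must be >= 2", class = "fl_precondition_error")
  if (base_width < 4L) stop_fl("base_width must be >= 4", class = "fl_precondition_error")
  structure(list(input_channels = as.integer(input_channels),
                 base_width = as.integer(base_width), depth = as.integer(depth),
                 K = as.integer(K), regionnet_hidden = as.integer(regionnet_hidden),
                 seed = as.integer(seed)),
            class = "fl_model_config")
}

#' Build a lesion detection model with freshly initialized weights
#'
#' Weights use He initialization drawn from a dedicated RNG substream of the
#' configured seed, so models are reproducible and independent of any other
#' randomness in a run.
#'
#' @param config A [model_config()].
#' @return An object of class `fl_model` (list of `config` and named `params`).
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "fl_model_config"))
  widths <- config$base_width * 2^(seq_len(config$depth) - 1L)
  p <- list()
  with_seed(substream_seed(config$seed, "model_init"), {
    add_conv <- function(nm, cin, cout, k = 3L) {
      p[[paste0(nm, ".w")]] <<- he_conv(cout, cin, k)
      p[[paste0(nm, ".b")]] <<- numeric(cout)
      p[[paste0(nm, ".g")]] <<- rep(1, cout)
      p[[paste0(nm, ".bt")]] <<- numeric(cout)
    }
    add_conv("stem", config$input_channels, widths[1L])
    for (d in seq_len(config$depth)) {
      add_conv(sprintf("enc%d.c1", d), widths[d], widths[d])
      add_conv(sprintf("enc%d.c2", d), widths[d], widths[d])
      if (d < config$depth) add_conv(sprintf("down%d", d), widths[d], widths[d + 1L])
    }
    for (d in rev(seq_len(config$depth - 1L))) {
      add_conv(sprintf("up%d", d), widths[d + 1L], widths[d])
      add_conv(sprintf("dec%d.c1", d), widths[d], widths[d])
      add_conv(sprintf("dec%d.c2", d), widths[d], widths[d])
    }
    p[["seg.w"]] <- he_conv(1L, widths[1L], 1L)
    p[["seg.b"]] <- numeric(1L)
    p[["gg.w"]] <- he_conv(config$K, widths[1L], 1L)
    p[["gg.b"]] <- numeric(config$K)
    H <- config$regionnet_hidden
    p[["rn.W1"]] <- matrix(rnorm(H * config$K, 0, sqrt(2 / config$K)), H, config$K)
    p[["rn.b1"]] <- numeric(H)
    p[["rn.W2"]] <- matrix(rnorm(config$K * H, 0, sqrt(2 / H)), config$K, H)
    p[["rn.b2"]] <- numeric(config$K)
  })
  structure(list(config = config, params = p), class = "fl_model")
}

#' Number of learnable parameters of a model
#' @param model An `fl_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 0L))

#' @export
print.fl_model <- function(x, ...) {
  cat(sprintf("<fl_model: depth %d, base width %d, K = %d, %d parameters>\n",
              x$config$depth, x$config$base_width, x$config$K, n_params(x)))
  invisible(x)
}

#' Classify regions from their soft class histograms
#'
#' Applies the region classification head (two-layer perceptron + softmax) to
#' a matrix of soft region histograms.
#'
#' @param model An `fl_model`.
#' @param histograms Numeric matrix (R x K), rows summing to 1.
#' @return Numeric matrix (R x K) of softmax rows.
#' @export
region_classify <- function(model, histograms) {
  regionnet_fw(model$params, as.matrix(histograms))$preds
}

regionnet_fw <- function(p, h) {
  if (nrow(h) == 0L) {
    K <- nrow(p[["rn.W2"]])
    return(list(preds = matrix(0, 0, K), u1 = matrix(0, 0, nrow(p[["rn.W1"]])),
                h = h))
  }
  u1 <- sweep(h %*% t(p[["rn.W1"]]), 2L, p[["rn.b1"]], "+")
  a1 <- pmax(u1, 0)
  u2 <- sweep(a1 %*% t(p[["rn.W2"]]), 2L, p[["rn.b2"]], "+")
  list(preds = softmax_rows(u2), u1 = u1, a1 = a1, h = h)
}

# Backward through the region head given gradient w.r.t. the softmax outputs.
regionnet_bw <- function(g_preds, fw, p, grads) {
  if (nrow(fw$h) == 0L) {
    grads[["rn.W1"]] <- p[["rn.W1"]] * 0; grads[["rn.b1"]] <- p[["rn.b1"]] * 0
    grads[["rn.W2"]] <- p[["rn.W2"]] * 0; grads[["rn.b2"]] <- p[["rn.b2"]] * 0
    return(list(gh = fw$h, grads = grads))
  }
  z <- fw$preds
  gu2 <- z * (g_preds - rowSums(g_preds * z)) # softmax Jacobian, row-wise
  grads[["rn.W2"]] <- t(gu2) %*% fw$a1
  grads[["rn.b2"]] <- colSums(gu2)
  gu1 <- (gu2 %*% p[["rn.W2"]]) * (fw$u1 > 0)
  grads[["rn.W1"]] <- t(gu1) %*% fw$h
  grads[["rn.b1"]] <- colSums(gu1)
  list(gh = gu1 %*% p[["rn.W1"]], grads = grads)
}

#' Forward pass of the lesion detection model
#'
#' Produces the tanh segmentation map, the softmax grade-group map, the soft
#' class histogram of every region, and the region classification head's
#' softmax predictions. With zero regions the histogram and prediction
#' matrices have zero rows but the voxel-wise maps are still produced.
#'
#' @param model An `fl_model` from [build_model()].
#' @param x Input array `dim = c(input_channels, X, Y, Z)`, or an [exam()].
#' @param regions An [region_set()] (or list of binary masks) on the same grid.
#' @param train Keep the activation caches needed for backpropagation?
#' @return An object of class `fl_model_outputs`: list with `seg_map`
#'   (`X x Y x Z`, in `[-1, 1]`), `gg_map` (`K x X x Y x Z`, channel sums 1),
#'   `region_histograms` and `region_preds` (both R x K). When `train = TRUE`
#'   the cache is attached as attribute `"cache"`.
#' @export
model_forward <- function(model, x, regions = region_set(), train = FALSE) {
  if (inherits(x, "fl_exam")) x <- x$image
  if (inherits(regions, "fl_region_set")) masks <- regions$masks
  else masks <- regions
  cfg <- model$config
  p <- model$params
  d <- dim(x)
  if (length(d) != 4L || d[1L] != cfg$input_channels)
    stop_fl("input must be (%d, X, Y, Z); got dims [%s]", cfg$input_channels,
            paste(d, collapse = ", "), class = "fl_shape_error")
  div <- 2^(cfg$depth - 1L)
  bad <- which(d[-1L] %% div != 0L)
  if (length(bad))
    stop_fl("grid axis %s not divisible by %d (depth %d)",
            paste(c("x", "y", "z")[bad], collapse = ","), div, cfg$depth,
            class = "fl_shape_error")

  cache <- if (train) list() else NULL
  stem <- cbr_fw(x, p, "stem")
  a <- stem$out
  skips <- vector("list", cfg$depth - 1L)
  enc_caches <- vector("list", cfg$depth)
  down_caches <- vector("list", cfg$depth - 1L)
  for (dd in seq_len(cfg$depth)) {
    eb <- resblock_fw(a, p, sprintf("enc%d", dd))
    enc_caches[[dd]] <- eb$cache
    a <- eb$out
    if (dd < cfg$depth) {
      skips[[dd]] <- a
      db <- cbr_fw(a, p, sprintf("down%d", dd), stride = 2L)
      down_caches[[dd]] <- db$cache
      a <- db$out
    }
  }
  up_caches <- vector("list", cfg$depth - 1L)
  dec_caches <- vector("list", cfg$depth - 1L)
  up_inputs <- vector("list", cfg$depth - 1L)
  for (dd in rev(seq_len(cfg$depth - 1L))) {
    up_inputs[[dd]] <- a
    u <- .upsample2_fw(a)
    ub <- cbr_fw(u, p, sprintf("up%d", dd))
    up_caches[[dd]] <- ub$cache
    a <- ub$out + skips[[dd]]
    db <- resblock_fw(a, p, sprintf("dec%d", dd))
    dec_caches[[dd]] <- db$cache
    a <- db$out
  }
  seg_logit <- .conv3d_fw(a, p[["seg.w"]], p[["seg.b"]], 1L)
  gg_logit <- .conv3d_fw(a, p[["gg.w"]], p[["gg.b"]], 1L)
  seg_map <- tanh(array(seg_logit, dim = d[-1L]))
  gg_map <- softmax_channels(gg_logit)

  R <- length(masks)
  region_idx <- lapply(masks, function(m) which(m > 0))
  h <- matrix(0, R, cfg$K)
  if (R > 0) {
    gm <- matrix(gg_map, nrow = cfg$K)
    for (r in seq_len(R)) h[r, ] <- rowMeans(gm[, region_idx[[r]], drop = FALSE])
  }
  rn <- regionnet_fw(p, h)
  out <- structure(list(seg_map = seg_map, gg_map = gg_map,
                        region_histograms = h, region_preds = rn$preds),
                   class = "fl_model_outputs")
  if (train) {
    attr(out, "cache") <- list(stem = stem$cache, enc = enc_caches,
                               down = down_caches, up = up_caches, dec = dec_caches,
                               final = a, seg_map = seg_map, gg_map = gg_map,
                               region_idx = region_idx, rn = rn, d = d)
  }
  out
}

# Backpropagate gradients w.r.t. the activated outputs (as produced by
# composite_parts) into gradients w.r.t. every model parameter.
model_backward <- function(model, cache, g_seg_map, g_gg_map, g_hist, g_preds) {
  cfg <- model$config
  p <- model$params
  grads <- list()

  rb <- regionnet_bw(g_preds, cache$rn, p, grads)
  grads <- rb$grads
  gh_total <- g_hist + rb$gh

  K <- cfg$K
  g_gg <- matrix(g_gg_map, nrow = K)
  for (r in seq_along(cache$region_idx)) {
    idx <- cache$region_idx[[r]]
    g_gg[, idx] <- g_gg[, idx] + gh_total[r, ] / length(idx)
  }
  q <- matrix(cache$gg_map, nrow = K)
  s <- .colSums(g_gg * q, K, ncol(q))
  g_gg_logit <- array(q * (g_gg - rep(s, each = K)), dim = c(K, cache$d[-1L]))

  g_seg_logit <- array(g_seg_map * (1 - cache$seg_map^2), dim = c(1L, cache$d[-1L]))

  sb <- .conv3d_bw(cache$final, p[["seg.w"]], g_seg_logit, 1L)
  gb <- .conv3d_bw(cache$final, p[["gg.w"]], g_gg_logit, 1L)
  grads[["seg.w"]] <- sb$gw; grads[["seg.b"]] <- sb$gb
  grads[["gg.w"]] <- gb$gw; grads[["gg.b"]] <- gb$gb
  ga <- sb$gx + gb$gx

  # Decoder backward. The forward decoder ran levels (depth-1) .. 1, so the
  # reverse order is 1 .. (depth-1); the gradient into each additive skip is
  # remembered and re-joined when the encoder backward reaches that level.
  gskip <- vector("list", cfg$depth - 1L)
  for (dd in seq_len(cfg$depth - 1L)) {
    db <- resblock_bw(ga, cache$dec[[dd]], p, sprintf("dec%d", dd), grads)
    grads <- db$grads
    gskip[[dd]] <- db$gx # gradient into (up output + encoder skip)
    ub <- cbr_bw(db$gx, cache$up[[dd]], p, sprintf("up%d", dd), 1L, grads)
    grads <- ub$grads
    ga <- .upsample2_bw(ub$gx) # gradient w.r.t. the next-deeper level's output
  }

  # Encoder backward, deepest level first.
  for (dd in rev(seq_len(cfg$depth))) {
    eb <- resblock_bw(ga, cache$enc[[dd]], p, sprintf("enc%d", dd), grads)
    grads <- eb$grads
    ga <- eb$gx
    if (dd > 1L) {
      dbw <- cbr_bw(ga, cache$down[[dd - 1L]], p, sprintf("down%d", dd - 1L), 2L, grads)
      grads <- dbw$grads
      ga <- dbw$gx + gskip[[dd - 1L]]
    }
  }
  st <- cbr_bw(ga, cache$stem, p, "stem", 1L, grads)
  st$grads
}

#' Collate exam bundles into a batch dictionary
#'
#' Builds the collated dictionary consumed by [training_step()]: per-exam
#' lists under the keys `image`, `regions`, `record`, `labels` (region counts
#' may be ragged across exams; no padding is used).
#'
#' @param bundles List of exam bundles, each a list with `exam`, `regions`,
#'   `record`, `labels` (e.g. from [generate_exam()]).
#' @return An object of class `fl_batch`.
#' @export
collate_batch <- function(bundles) {
  structure(list(image = lapply(bundles, `[[`, "exam"),
                 regions = lapply(bundles, `[[`, "regions"),
                 record = lapply(bundles, `[[`, "record"),
                 labels = lapply(bundles, `[[`, "labels")),
            class = "fl_batch")
}

#' Unpack a collated batch into typed per-exam views
#'
#' The `image` key is required; `regions`, `record` and `labels` are optional
#' and default to empty region sets, empty supervision and an all-background
#' segmentation mask, so weakly annotated exams never fail.
#'
#' @param batch A collated batch (class `fl_batch` or a plain named list).
#' @return List with `exams`, `regions`, `records`, `labels`, all of equal length.
#' @export
unpack_batch <- function(batch) {
  if (!is.list(batch) || is.null(batch[["image"]]))
    stop_fl("batch is missing required key 'image' (expected keys: image, regions, record, labels)",
            class = "fl_schema_error")
  exams <- batch$image
  n <- length(exams)
  fill <- function(key, default_fn) {
    v <- batch[[key]]
    if (is.null(v)) v <- vector("list", n)
    lapply(seq_len(n), function(i) v[[i]] %||% default_fn(i))
  }
  regions <- fill("regions", function(i) region_set())
  records <- fill("record", function(i) supervision_record())
  labels <- fill("labels", function(i) {
    gd <- if (inherits(exams[[i]], "fl_exam")) grid_dim(exams[[i]]) else dim(exams[[i]])[-1L]
    groundtruth_labels(array(0, gd), matrix(0, 0, 2))
  })
  list(exams = exams, regions = regions, records = records, labels = labels)
}

#' One training step: forward, composite loss, analytic gradients
#'
#' Runs the forward pass on every exam of the batch, evaluates the composite
#' multi-task loss, and backpropagates its exact gradient through the network.
#' Losses and gradients are mean-reduced over the batch.
#'
#' @param model An `fl_model`.
#' @param batch A collated batch ([collate_batch()]) or list of bundles.
#' @param weights A [loss_weights()].
#' @return List with `breakdown` (batch-mean `fl_loss_breakdown`, active
#'   counts summed) and `grads` (named list matching `model$params`).
#' @export
training_step <- function(model, batch, weights = loss_weights()) {
  if (!inherits(batch, "fl_batch") && is.null(batch[["image"]]))
    batch <- collate_batch(batch)
  ub <- unpack_batch(batch)
  n <- length(ub$exams)
  if (n == 0L) stop_fl("empty batch", class = "fl_precondition_error")
  acc <- NULL
  terms <- c("total", "region_classifier", "ggmap_hist", "ggmap", "segmentation")
  sums <- setNames(numeric(length(terms)), terms)
  active <- NULL
  for (i in seq_len(n)) {
    out <- model_forward(model, ub$exams[[i]], ub$regions[[i]], train = TRUE)
    cp <- composite_parts(out, ub$regions[[i]], ub$records[[i]], ub$labels[[i]], weights)
    g <- model_backward(model, attr(out, "cache"),
                        cp$g_seg_map, cp$g_gg_map, cp$g_hist, cp$g_preds)
    if (is.null(acc)) acc <- g
    else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
    for (t in terms) sums[[t]] <- sums[[t]] + cp$breakdown[[t]]
    active <- if (is.null(active)) cp$breakdown$active else active + cp$breakdown$active
  }
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / n
  breakdown <- structure(c(as.list(sums / n), list(active = active)),
                         class = "fl_loss_breakdown")
  list(breakdown = breakdown, grads = acc)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the weights, the [model_config()] and optional training
#' metadata, so any variant is reproducible from its file.
#'
#' @param model An `fl_model`.
#' @param path Destination file.
#' @param meta Optional metadata list (round index, metrics, ...).
#' @return `path`, invisibly (for `save_checkpoint`); an `fl_model` with
#'   attribute `"meta"` (for `load_checkpoint`).
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = unclass(model$config), params = model$params, meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  m <- structure(list(config = do.call(model_config, x$config), params = x$params),
                 class = "fl_model")
  attr(m, "meta") <- x$meta
  m
}
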