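# Shared in-code fixtures: everything is generated programmatically at test
# time; no binary data ships with the package.

# A small exam with a rectangular gland and reproducible random intensities.
tiny_exam <- function(seed = 1, d = c(8L, 8L, 4L), nch = 3L) {
  set.seed(seed)
  img <- array(rnorm(nch * prod(d), mean = 10, sd = 2), c(nch, d))
  gland <- array(0, d)
  gland[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- 1
  exam(img, gland, c(1, 1, 2), exam_id = "ex1", site_id = "s1")
}

# A random channel-softmax grade map of dim (K, X, Y, Z).
rand_gg_map <- function(seed = 1, K = 2L, d = c(6L, 6L, 3L), scale = 1) {
  set.seed(seed)
  fedlesion:::softmax_channels(array(rnorm(K * prod(d), sd = scale), c(K, d)))
}

# Binary mask covering `n` voxels starting at linear offset `from`.
mask_of <- function(d, from, n) {
  m <- array(0, d)
  m[seq(from, length.out = n)] <- 1
  m
}

# A fully-populated supervision fixture: one strong lesion, one weak sextant,
# one ignored region.
tiny_supervision <- function(seed = 1, d = c(6L, 6L, 3L), K = 2L) {
  set.seed(seed)
  n <- prod(d)
  masks <- list(mask_of(d, 1, max(4L, n %/% 10)),
                mask_of(d, n %/% 5, max(4L, n %/% 4)),
                mask_of(d, n %/% 2, max(4L, n %/% 8)))
  regions <- region_set(masks, c("lesion", "sextant", "lesion"))
  record <- supervision_record(c(1L, 2L, 0L), c(3L, 0L, 2L))
  seg <- masks[[1L]]
  labels <- groundtruth_labels(seg, onehot_rows(binarize_grade(record$max_grade_group), K))
  list(regions = regions, record = record, labels = labels, d = d)
}

onehot_rows <- fedlesion:::onehot_rows
`%||%` <- fedlesion:::`%||%`

# Model outputs consistent with a supervision fixture, built from random maps.
tiny_outputs <- function(model, fx, ex_seed = 5) {
  set.seed(ex_seed)
  d <- fx$d
  seg_map <- tanh(array(rnorm(prod(d)), d))
  gg_map <- rand_gg_map(ex_seed + 1, d = d)
  h <- fedlesion:::region_histograms(gg_map, fx$regions)
  preds <- region_classify(model, h)
  structure(list(seg_map = seg_map, gg_map = gg_map,
                 region_histograms = h, region_preds = preds),
            class = "fl_model_outputs")
}

# Central finite-difference gradient of f at x (numeric vector/array).
fd_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(floor, abs(a), abs(b)))
}
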