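# Two-site phantom generator. Emulates the statistical and annotation
# structure of a two-hospital prostate mp-MRI cohort at desk scale: an
# ellipsoidal gland, Gaussian-blob lesions whose DWI/ADC contrast is monotone
# in the true ISUP grade tier, site-specific acquisition nuisances (additive
# channel offsets, a multiplicative coil-like bias field, correlated
# background texture, differing noise levels), and two annotation regimes --
# per-lesion regions plus six sextants with strong/weak supervision signals,
# or a single exam-level maximum grade attached to the whole gland.

#' Configuration of one synthetic site
#'
#' @param site_id Site identifier string.
#' @param grid_shape Integer length-3 voxel grid.
#' @param spacing Voxel spacing in mm.
#' @param contrast_offsets Additive per-channel offsets of the gland baseline
#'   intensity (arbitrary units) emulating scanner/protocol differences.
#'   These are removed by the Z-score step; the structural nuisances below are not.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param bias_field_strength Strength of a multiplicative linear bias field
#'   along the posterior-anterior axis, emulating an endorectal receive coil
#'   (0 disables).
#' @param texture_amp,texture_scale Amplitude and correlation length (voxels)
#'   of smooth background texture emulating anatomy-like structure (0 disables).
#' @param channel_effects Length-3 multipliers of the lesion effect size per
#'   channel `(T2WI, DWI, ADC)`. The T2WI component scales the
#'   grade-independent hypointensity of every MRI-identified lesion (what
#'   makes lesions segmentable); the DWI and ADC components scale the
#'   per-grade-tier hyper-/hypo-intensity (what makes lesions gradable).
#'   Sites can weight DWI vs ADC differently, emulating protocol differences
#'   such as acquisition b-value that change diffusion contrast nonlinearly
#'   across sites.
#' @param lesion_count_range Integer interval for the number of
#'   MRI-identified lesions per exam.
#' @param grade_prevalence Probabilities of the exam maximum-grade categories
#'   (GG0, GG1, GG2, GG3-5); must sum to 1.
#' @param annotation_mode `"lesion_and_sextant"` (per-lesion regions with
#'   signal `signal_for_lesions` plus six sextant regions with signal 2) or
#'   `"exam_level_max"` (one gland region with signal 2 carrying the exam
#'   maximum grade; lesion contours are still used for segmentation labels).
#' @param lesion_region_style `"contour"` (exact lesion mask) or
#'   `"bounding_box"` (union of per-slice 2D bounding boxes).
#' @param signal_for_lesions Supervision signal given to lesion regions in
#'   `lesion_and_sextant` mode (1 = strong, 2 = weak).
#' @param effect_scale Multiplier on the grade-contrast effect size (1 =
#'   the easy benchmark: 1.5 x noise_sigma separation between consecutive
#'   grade tiers; the hard preset shrinks it).
#' @param seed Site seed; per-exam randomness is drawn from named substreams
#'   of it, so adding exams never perturbs earlier ones.
#' @return An object of class `fl_site_config`.
#' @export
site_config <- function(site_id = "site", grid_shape = c(32L, 32L, 16L),
                        spacing = c(1, 1, 2), contrast_offsets = c(0, 0, 0),
                        noise_sigma = 0.2, bias_field_strength = 0,
                        texture_amp = 0, texture_scale = 4,
                        channel_effects = c(1.5, 1, 1),
                        lesion_count_range = c(1L, 2L),
                        grade_prevalence = c(0.25, 0.25, 0.25, 0.25),
                        annotation_mode = c("lesion_and_sextant", "exam_level_max"),
                        lesion_region_style = c("contour", "bounding_box"),
                        signal_for_lesions = 1L, effect_scale = 1,
                        seed = 1L) {
  if (abs(sum(grade_prevalence) - 1) > 1e-9 || length(grade_prevalence) != 4L)
    stop_fl("grade_prevalence must be 4 probabilities summing to 1",
            class = "fl_precondition_error")
  if (noise_sigma < 0) stop_fl("noise_sigma must be >= 0", class = "fl_precondition_error")
  structure(list(site_id = site_id, grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 contrast_offsets = as.numeric(contrast_offsets),
                 noise_sigma = noise_sigma,
                 bias_field_strength = bias_field_strength,
                 texture_amp = texture_amp, texture_scale = texture_scale,
                 channel_effects = as.numeric(channel_effects),
                 lesion_count_range = as.integer(lesion_count_range),
                 grade_prevalence = as.numeric(grade_prevalence),
                 annotation_mode = match.arg(annotation_mode),
                 lesion_region_style = match.arg(lesion_region_style),
                 signal_for_lesions = as.integer(signal_for_lesions),
                 effect_scale = effect_scale, seed = as.integer(seed)),
            class = "fl_site_config")
}

# Squared normalized distance field for an axis-aligned ellipsoid.
ellipse_d2 <- function(dims, center, semi) {
  dx <- ((seq_len(dims[1L]) - center[1L]) / semi[1L])^2
  dy <- ((seq_len(dims[2L]) - center[2L]) / semi[2L])^2
  dz <- ((seq_len(dims[3L]) - center[3L]) / semi[3L])^2
  outer(outer(dx, dy, "+"), dz, "+")
}

# ISUP grade -> contrast tier (GG0, GG1, GG2, GG3-5).
grade_tier <- function(g) pmin(as.integer(g), 3L)

# Six sextants: left/right split at the midsagittal plane of the gland
# bounding box, three axial thirds (base / mid / apex).
sextant_masks <- function(gland) {
  idx <- which(gland > 0, arr.ind = TRUE)
  xr <- range(idx[, 1L]); zr <- range(idx[, 3L])
  xmid <- mean(xr)
  zcuts <- quantile(zr[1L]:zr[2L], c(1 / 3, 2 / 3), type = 7)
  d <- dim(gland)
  xi <- slice.index(gland, 1L); zi <- slice.index(gland, 3L)
  masks <- list()
  k <- 0L
  for (lr in 1:2) for (tz in 1:3) {
    m <- gland
    m[!((if (lr == 1) xi <= xmid else xi > xmid) &
          (if (tz == 1) zi <= zcuts[1L]
           else if (tz == 2) zi > zcuts[1L] & zi <= zcuts[2L]
           else zi > zcuts[2L]))] <- 0
    k <- k + 1L
    masks[[k]] <- m
  }
  names(masks) <- c("sextant_L_base", "sextant_L_mid", "sextant_L_apex",
                    "sextant_R_base", "sextant_R_mid", "sextant_R_apex")
  masks
}

# Union of per-slice 2D bounding boxes of a lesion mask (the bounding-box
# annotation dialect).
bbox_mask <- function(mask) {
  out <- array(0, dim(mask))
  for (z in seq_len(dim(mask)[3L])) {
    sl <- mask[, , z]
    if (!any(sl > 0)) next
    ii <- which(sl > 0, arr.ind = TRUE)
    out[min(ii[, 1L]):max(ii[, 1L]), min(ii[, 2L]):max(ii[, 2L]), z] <- 1
  }
  out
}

# Smooth correlated noise: coarse white noise trilinearly upsampled.
smooth_texture <- function(dims, scale) {
  coarse_dim <- pmax(2L, as.integer(ceiling(dims / scale)) + 1L)
  coarse <- array(rnorm(prod(coarse_dim)), coarse_dim)
  .resample3d(coarse, rep(scale, 3L), rep(1, 3L), as.integer(dims), 0L)
}

#' Generate one synthetic exam bundle
#'
#' Draws an ellipsoidal gland, places 0-N Gaussian-blob lesions inside it,
#' renders the three channels (all lesions are T2-hypointense; DWI
#' hyper-/ADC hypo-intensity scales with the grade tier at `effect_scale *
#' 1.5 * noise_sigma` per tier), applies the site's nuisances and noise, and
#' builds regions, supervision and labels according to the site's annotation
#' mode. All randomness comes from named substreams of
#' `(config$seed, exam_index)`, so bundles are bit-reproducible.
#'
#' @param config A [site_config()].
#' @param exam_index Positive integer index of the exam within the site.
#' @return An object of class `fl_bundle`: list with `exam`, `regions`,
#'   `record`, `labels` and `truth` (true lesion centers, radii, grades,
#'   masks, exam maximum grade).
#' @export
generate_exam <- function(config, exam_index = 1L) {
  cfg <- config
  d <- cfg$grid_shape
  sub <- function(tag) substream_seed(cfg$seed, tag, exam_index)

  gland <- with_seed(sub("gland"), {
    semi <- d * c(0.34, 0.30, 0.36) * runif(3L, 0.92, 1.08)
    center <- d / 2 + runif(3L, -0.5, 0.5)
    (ellipse_d2(d, center, semi) <= 1) * 1
  })

  gr <- with_seed(sub("grade"), {
    category <- sample.int(4L, 1L, prob = cfg$grade_prevalence) - 1L
    max_gg <- switch(category + 1L, 0L, 1L, 2L, sample(3:5, 1L))
    n <- if (diff(cfg$lesion_count_range) == 0L) cfg$lesion_count_range[1L]
         else sample(cfg$lesion_count_range[1L]:cfg$lesion_count_range[2L], 1L)
    if (cfg$lesion_count_range[2L] == 0L) {
      # no lesions can exist, so the exam is necessarily negative
      max_gg <- 0L
      category <- 0L
    } else if (max_gg > 0L && n == 0L) n <- 1L
    grades <- integer(0)
    if (n > 0L) {
      grades <- c(if (max_gg > 0L) max_gg else 0L,
                  if (n > 1L) sample(0:max(max_gg, 0L), n - 1L, replace = TRUE))
      grades <- grades[seq_len(n)]
    }
    list(category = category, max_gg = max_gg, grades = grades)
  })
  n_les <- length(gr$grades)

  les <- with_seed(sub("placement"), {
    centers <- matrix(0, n_les, 3L)
    radii <- matrix(0, n_les, 3L)
    masks <- vector("list", n_les)
    profiles <- vector("list", n_les)
    gl_idx <- which(gland > 0, arr.ind = TRUE)
    for (l in seq_len(n_les)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        ctr <- gl_idx[sample.int(nrow(gl_idx), 1L), ] + runif(3L, -0.5, 0.5)
        r <- c(runif(1L, 2.6, 4.2), runif(1L, 2.6, 4.2), runif(1L, 1.4, 2.2))
        if (l > 1L && any(sqrt(rowSums(sweep(centers[seq_len(l - 1L), , drop = FALSE],
                                             2L, ctr)^2)) < 5)) next
        prof <- exp(-0.5 * ellipse_d2(d, ctr, r))
        m <- (prof >= 0.5) * gland # thresholded at half maximum, clipped to gland
        if (sum(m) < 8) next       # mostly outside the gland or too small
        centers[l, ] <- ctr; radii[l, ] <- r
        masks[[l]] <- m; profiles[[l]] <- prof * gland
        placed <- TRUE
        break
      }
      if (!placed)
        stop_fl("could not place lesion %d inside the gland after bounded retries",
                l, class = "fl_placement_error")
    }
    list(centers = centers, radii = radii, masks = masks, profiles = profiles)
  })

  es <- cfg$effect_scale * 1.5 * cfg$noise_sigma
  base_in <- c(1, 1, 1) + cfg$contrast_offsets # T2WI, DWI, ADC gland baseline
  img <- array(0, dim = c(3L, d))
  ynorm <- (slice.index(gland, 2L) - 0.5) / d[2L]
  bias <- 1 + cfg$bias_field_strength * (ynorm - 0.5)
  tex <- if (cfg$texture_amp > 0)
    with_seed(sub("texture"), lapply(1:3, function(i) smooth_texture(d, cfg$texture_scale)))
  else NULL
  noise <- with_seed(sub("noise"), lapply(1:3, function(i) array(rnorm(prod(d)), d)))
  for (c in 1:3) {
    vol <- array(0.35 * base_in[c], d)
    vol[gland > 0] <- base_in[c]
    for (l in seq_len(n_les)) {
      t <- grade_tier(gr$grades[l])
      ce <- cfg$channel_effects
      # T2: grade-independent visibility; DWI up / ADC down with grade tier
      delta <- switch(c, -ce[1L] * es, ce[2L] * es * t, -ce[3L] * es * t)
      vol <- vol + delta * les$profiles[[l]]
    }
    vol <- vol * bias
    if (!is.null(tex)) vol <- vol + cfg$texture_amp * cfg$noise_sigma * tex[[c]]
    img[c, , , ] <- vol + cfg$noise_sigma * noise[[c]]
  }

  exam_id <- sprintf("%s_ex%03d", cfg$site_id, exam_index)
  ex <- exam(img, gland, cfg$spacing, exam_id = exam_id, site_id = cfg$site_id)
  seg <- array(0, d)
  for (m in les$masks) seg <- pmax(seg, m)

  if (cfg$annotation_mode == "lesion_and_sextant") {
    rmask <- lapply(les$masks, function(m)
      if (cfg$lesion_region_style == "bounding_box") bbox_mask(m) else m)
    sx <- sextant_masks(gland)
    sx_gg <- vapply(sx, function(sm)
      if (n_les == 0L) 0L
      else max(c(0L, gr$grades[vapply(les$masks, function(lm) sum(lm * sm) > 0, TRUE)])),
      0L)
    masks <- c(rmask, unname(sx))
    kinds <- c(rep("lesion", n_les), rep("sextant", 6L))
    ids <- c(sprintf("lesion_%d", seq_len(n_les)), names(sx))
    signal <- c(rep(cfg$signal_for_lesions, n_les), rep(2L, 6L))
    max_gg <- c(gr$grades, sx_gg)
  } else {
    masks <- list(gland)
    kinds <- "gland"
    ids <- "gland"
    signal <- 2L
    max_gg <- gr$max_gg
  }
  regions <- region_set(masks, kinds, ids)
  record <- supervision_record(signal, max_gg)
  labels <- groundtruth_labels(seg, onehot_rows(binarize_grade(max_gg), 2L))

  structure(list(exam = ex, regions = regions, record = record, labels = labels,
                 truth = list(centers = les$centers, radii = les$radii,
                              grades = gr$grades, masks = les$masks,
                              max_gg = gr$max_gg, category = gr$category)),
            class = "fl_bundle")
}

#' Generate a site dataset with disjoint train/validation/test splits
#'
#' Exams are indexed deterministically from the site seed; the first
#' `n_train` indices form the training split, the next `n_val` the validation
#' split, the next `n_test` the test split, so regenerating with the same
#' seed reproduces every split exactly.
#'
#' @param config A [site_config()].
#' @param n_train,n_val,n_test Split sizes (>= 0).
#' @return An object of class `fl_dataset`: list with `train`, `val`, `test`
#'   (lists of bundles), `manifest` (data frame: exam_id, split, site,
#'   max_gg, n_regions) and `config`.
#' @export
generate_site_dataset <- function(config, n_train, n_val, n_test) {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0)
  n <- n_train + n_val + n_test
  bundles <- lapply(seq_len(n), function(i) generate_exam(config, i))
  split <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  manifest <- data.frame(
    exam_id = vapply(bundles, function(b) b$exam$exam_id, ""),
    split = split, site = config$site_id,
    max_gg = vapply(bundles, function(b) b$truth$max_gg, 0L),
    n_regions = vapply(bundles, function(b) n_regions(b$regions), 0L))
  structure(list(train = bundles[split == "train"], val = bundles[split == "val"],
                 test = bundles[split == "test"], manifest = manifest,
                 config = config),
            class = "fl_dataset")
}

#' Tabulate a dataset manifest by maximum grade category and split
#'
#' @param dataset An `fl_dataset` (or its manifest data frame).
#' @return A table of exam counts, maximum-grade category by split.
#' @export
manifest_table <- function(dataset) {
  m <- if (inherits(dataset, "fl_dataset")) dataset$manifest else dataset
  cat_lab <- c("max ISUP 0", "max ISUP 1", "max ISUP 2", "max ISUP 3-5")
  category <- cat_lab[grade_tier(m$max_gg) + 1L]
  table(factor(category, cat_lab), factor(m$split, c("train", "val", "test")))
}

#' Site presets of the two-site benchmark
#'
#' Site A emulates an endorectal-coil acquisition with strong lesion-level
#' supervision: higher noise, a multiplicative posterior-anterior bias field,
#' bounding-box lesion regions (signal 1) plus six sextants (signal 2).
#' Site B emulates an external-coil 3D protocol with weak supervision: lower
#' noise, smooth anatomy-like background texture, contoured lesions used only
#' for segmentation labels, and a single exam-level maximum grade on the
#' gland region (signal 2). Additive channel offsets differ as well; those
#' are removed by preprocessing, while the structural nuisances are not.
#'
#' @param name `"siteA"` or `"siteB"`.
#' @param seed Site seed.
#' @param preset `"easy"` (grade-contrast separation 1.5 x noise sigma per
#'   tier) or `"hard"` (half that).
#' @param grid_shape Voxel grid of the site's exams.
#' @return A [site_config()].
#' @export
site_preset <- function(name = c("siteA", "siteB"), seed = 1L,
                        preset = c("easy", "hard"),
                        grid_shape = c(32L, 32L, 16L)) {
  name <- match.arg(name)
  preset <- match.arg(preset)
  es <- if (preset == "hard") 0.5 else 1
  if (name == "siteA")
    site_config(site_id = "siteA", grid_shape = grid_shape, noise_sigma = 0.25,
                contrast_offsets = c(0.5, -0.3, 0.4),
                bias_field_strength = 0.5, texture_amp = 0,
                channel_effects = c(2, 0.15, 1),
                annotation_mode = "lesion_and_sextant",
                lesion_region_style = "bounding_box",
                signal_for_lesions = 1L, effect_scale = es, seed = seed)
  else
    site_config(site_id = "siteB", grid_shape = grid_shape, noise_sigma = 0.12,
                contrast_offsets = c(-0.4, 0.25, -0.35),
                bias_field_strength = 0, texture_amp = 1.5, texture_scale = 4,
                channel_effects = c(2, 1, 0.15),
                annotation_mode = "exam_level_max",
                lesion_region_style = "contour", effect_scale = es, seed = seed)
}

#' Generate the two-site benchmark
#'
#' A pair of site datasets with shifted contrast statistics and different
#' annotation regimes (see [site_preset()]), the desk-scale stand-in for a
#' two-hospital cohort.
#'
#' @param seed Master seed; each site derives its own substream.
#' @param n_train,n_val,n_test Split sizes per site.
#' @param preset `"easy"` or `"hard"`.
#' @param grid_shape Voxel grid of the exams.
#' @return Named list of two `fl_dataset` objects (`siteA`, `siteB`).
#' @export
make_two_site_benchmark <- function(seed = 1L, n_train = 60L, n_val = 10L,
                                    n_test = 15L, preset = "easy",
                                    grid_shape = c(32L, 32L, 16L)) {
  list(siteA = generate_site_dataset(
         site_preset("siteA", seed = substream_seed(seed, "siteA"), preset = preset,
                     grid_shape = grid_shape),
         n_train, n_val, n_test),
       siteB = generate_site_dataset(
         site_preset("siteB", seed = substream_seed(seed, "siteB"), preset = preset,
                     grid_shape = grid_shape),
         n_train, n_val, n_test))
}

#' Write a site dataset to disk in the standard exam layout
#'
#' Each exam's channels, gland mask, region masks and sidecars are written
#' via [write_exam()] and [write_supervision()] into `<dir>/<split>/`; the
#' manifest is written as `manifest.csv`.
#'
#' @param dataset An `fl_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_site_dataset <- function(dataset, dir) {
  for (split in c("train", "val", "test")) {
    sd <- file.path(dir, split)
    for (b in dataset[[split]]) {
      write_exam(b$exam, sd)
      write_supervision(b$regions, b$record, b$labels, b$exam$spacing, sd,
                        b$exam$exam_id)
    }
  }
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read one split of a site dataset written by [write_site_dataset()]
#'
#' @param dir Dataset directory.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return List of bundles (without the synthetic `truth` element).
#' @export
read_site_dataset <- function(dir, split = "train") {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  ids <- manifest$exam_id[manifest$split == split]
  lapply(ids, function(id) {
    ex <- read_exam(file.path(dir, split), id)
    sup <- read_supervision(file.path(dir, split), id)
    structure(list(exam = ex, regions = sup$regions, record = sup$record,
                   labels = sup$labels, truth = NULL),
              class = "fl_bundle")
  })
}
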