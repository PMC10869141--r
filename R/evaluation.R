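#' Lesion segmentation intersection-over-union
#'
#' Binarizes the tanh prediction at `threshold` (default 0, i.e. 0.5 after
#' rescaling to `[0, 1]`) and returns `|intersection| / |union|` against the
#' ground-truth mask. An exam with no true lesion that is predicted clean
#' scores 1; if exactly one of the masks is empty the IoU is 0.
#'
#' @param pred_seg tanh-activated prediction array.
#' @param true_mask Binary array on the same grid.
#' @param threshold Binarization threshold on the tanh scale.
#' @return Scalar in `[0, 1]`.
#' @export
lesion_iou <- function(pred_seg, true_mask, threshold = 0) {
  if (!identical(dim(pred_seg), dim(true_mask)))
    stop_fl("prediction and mask grids differ", class = "fl_shape_error")
  p <- pred_seg > threshold
  t <- true_mask > 0
  np <- sum(p); nt <- sum(t)
  if (np == 0 && nt == 0) return(1)
  if (np == 0 || nt == 0) return(0)
  sum(p & t) / sum(p | t)
}

#' Region-wise confusion matrix
#'
#' Tallies argmax region predictions against one-hot labels. By default the
#' evaluation is restricted to lesion-kind regions (the headline metric of
#' the binary lesion classification task); pass `kinds = NULL` to use all
#' rows.
#'
#' @param region_preds Numeric matrix (R x K) of softmax rows.
#' @param labels An [groundtruth_labels()] or a one-hot matrix (R x K).
#' @param record Optional [supervision_record()]; regions with signal 0 are
#'   excluded when given.
#' @param kinds Optional character vector of region kinds; only `"lesion"`
#'   rows are kept when given.
#' @return A K x K count matrix (class `fl_confusion`), rows = true class,
#'   columns = predicted class.
#' @export
regionwise_confusion <- function(region_preds, labels, record = NULL, kinds = NULL) {
  onehot <- if (inherits(labels, "fl_labels")) labels$region_onehot else as.matrix(labels)
  K <- ncol(onehot)
  keep <- seq_len(nrow(onehot))
  if (!is.null(kinds)) keep <- keep[kinds[keep] == "lesion"]
  if (!is.null(record)) keep <- keep[record$signal[keep] > 0L]
  if (length(keep) == 0L)
    stop_fl("no eligible regions to evaluate", class = "fl_empty_evaluation_error")
  tr <- max.col(onehot[keep, , drop = FALSE], ties.method = "first")
  pr <- max.col(region_preds[keep, , drop = FALSE], ties.method = "first")
  cm <- matrix(0L, K, K, dimnames = list(true = seq_len(K) - 1L, pred = seq_len(K) - 1L))
  for (i in seq_along(tr)) cm[tr[i], pr[i]] <- cm[tr[i], pr[i]] + 1L
  structure(cm, class = c("fl_confusion", "matrix"))
}

#' Occurrence-normalized (class-balanced) accuracy
#'
#' Normalizes each row of the confusion matrix to per-class recall rates and
#' averages the diagonal, reported in percent. For K = 2 the two diagonal
#' rates are the true negative rate (specificity) and true positive rate
#' (sensitivity), and `percent = 100 * (TNR + TPR) / 2` exactly. Every true
#' class must occur at least once.
#'
#' @param cm A K x K count matrix (rows = true class).
#' @return List with `percent`, `rates` (length-K per-class recall), and for
#'   K = 2 also `tnr` and `tpr`.
#' @export
balanced_accuracy <- function(cm) {
  cm <- unclass(cm)
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop_fl("true class %s never occurs; per-class rate undefined",
            paste(which(rs == 0) - 1L, collapse = ","), class = "fl_undefined_rate_error")
  rates <- diag(cm / rs)
  out <- list(percent = 100 * mean(rates), rates = unname(rates))
  if (nrow(cm) == 2L) {
    out$tnr <- unname(rates[1L])
    out$tpr <- unname(rates[2L])
  }
  out
}

# Evaluation regions of a bundle: the true lesion masks and grades when the
# synthetic truth is carried, otherwise the lesion-kind annotated regions.
eval_regions <- function(bundle) {
  if (!is.null(bundle$truth) && length(bundle$truth$grades) > 0L)
    return(list(masks = bundle$truth$masks,
                bins = binarize_grade(bundle$truth$grades)))
  keep <- which(bundle$regions$kinds == "lesion" & bundle$record$signal > 0L)
  list(masks = bundle$regions$masks[keep],
       bins = binarize_grade(bundle$record$max_grade_group[keep]))
}

true_seg_mask <- function(bundle) {
  if (!is.null(bundle$truth)) {
    m <- array(0, dim(bundle$labels$seg_mask))
    for (mm in bundle$truth$masks) m <- pmax(m, mm)
    m
  } else bundle$labels$seg_mask
}

#' Evaluate a model on a set of exams
#'
#' Computes the mean per-exam lesion IoU and the region-wise class-balanced
#' lesion classification accuracy (with TNR/TPR for K = 2). Classification is
#' evaluated on lesion regions with known labels: the true lesions of
#' synthetic bundles, or the annotated lesion-kind regions otherwise.
#'
#' @param model An `fl_model`.
#' @param bundles List of exam bundles (e.g. a dataset's `test` split).
#' @param threshold Segmentation binarization threshold (tanh scale).
#' @param model_tag,test_site Strings recorded in the report.
#' @return An object of class `fl_eval_report`: list with `mean_iou`,
#'   `balanced_accuracy` (percent), `tnr`, `tpr`, `n_exams`, `n_regions`,
#'   `confusion`, `model_tag`, `test_site`.
#' @export
evaluate_model <- function(model, bundles, threshold = 0, model_tag = "model",
                           test_site = "") {
  ious <- numeric(0)
  preds <- NULL
  bins <- integer(0)
  for (b in bundles) {
    er <- eval_regions(b)
    out <- model_forward(model, b$exam, er$masks)
    ious <- c(ious, lesion_iou(out$seg_map, true_seg_mask(b), threshold))
    if (length(er$bins)) {
      preds <- rbind(preds, out$region_preds)
      bins <- c(bins, er$bins)
    }
  }
  if (length(bins) == 0L)
    stop_fl("no eligible lesion regions in the evaluation set",
            class = "fl_empty_evaluation_error")
  cm <- regionwise_confusion(preds, onehot_rows(bins, ncol(preds)))
  ba <- balanced_accuracy(cm)
  structure(list(mean_iou = mean(ious), balanced_accuracy = ba$percent,
                 tnr = ba$tnr, tpr = ba$tpr, n_exams = length(bundles),
                 n_regions = length(bins), confusion = cm,
                 model_tag = model_tag, test_site = test_site),
            class = "fl_eval_report")
}

#' @export
print.fl_eval_report <- function(x, ...) {
  cat(sprintf("<fl_eval_report %s on %s: IoU %.3f | balanced acc %.1f%% [%.2f, %.2f] | %d exams, %d regions>\n",
              x$model_tag, x$test_site, x$mean_iou, x$balanced_accuracy,
              x$tnr %||% NA, x$tpr %||% NA, x$n_exams, x$n_regions))
  invisible(x)
}

#' Cross-site evaluation grid
#'
#' Evaluates every checkpoint on every site's test set, producing the S x M
#' comparison table of mean IoU and class-balanced accuracy, plus the deltas
#' between federated and local checkpoints on each test site when tags of the
#' form `<site>_local` / `<site>_fed` are present.
#'
#' @param checkpoints Named list of `fl_model` objects (>= 1).
#' @param test_sets Named list (>= 2 sites) of bundle lists.
#' @param threshold Segmentation threshold.
#' @return An object of class `fl_cross_site`: list with `table` (data frame:
#'   model, test_site, mean_iou, balanced_accuracy, tnr, tpr), `reports`
#'   (nested list) and `deltas` (data frame or NULL).
#' @export
cross_site_matrix <- function(checkpoints, test_sets, threshold = 0) {
  if (length(test_sets) < 2L)
    stop_fl("need at least two test sites", class = "fl_precondition_error")
  rows <- list()
  reports <- list()
  for (mt in names(checkpoints)) {
    reports[[mt]] <- list()
    for (ts in names(test_sets)) {
      rep <- evaluate_model(checkpoints[[mt]], test_sets[[ts]], threshold, mt, ts)
      reports[[mt]][[ts]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        model = mt, test_site = ts, mean_iou = rep$mean_iou,
        balanced_accuracy = rep$balanced_accuracy,
        tnr = rep$tnr %||% NA_real_, tpr = rep$tpr %||% NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  deltas <- NULL
  locals <- grep("_local$", names(checkpoints), value = TRUE)
  feds <- grep("_fed$", names(checkpoints), value = TRUE)
  if (length(locals) && length(feds)) {
    dl <- list()
    for (lo in locals) {
      site <- sub("_local$", "", lo)
      fe <- paste0(site, "_fed")
      if (!fe %in% feds) next
      for (ts in names(test_sets)) {
        dl[[length(dl) + 1L]] <- data.frame(
          site_model = site, test_site = ts,
          d_balanced_accuracy = reports[[fe]][[ts]]$balanced_accuracy -
            reports[[lo]][[ts]]$balanced_accuracy,
          d_mean_iou = reports[[fe]][[ts]]$mean_iou - reports[[lo]][[ts]]$mean_iou)
      }
    }
    if (length(dl)) deltas <- do.call(rbind, dl)
  }
  structure(list(table = tab, reports = reports, deltas = deltas),
            class = "fl_cross_site")
}

#' @export
print.fl_cross_site <- function(x, ...) {
  cat("Cross-site evaluation (rows: model, columns: test site)\n")
  sites <- unique(x$table$test_site)
  models <- unique(x$table$model)
  cat(sprintf("%-14s", "Model"),
      sprintf("%-22s", sites), "\n", sep = " ")
  for (m in models) {
    cells <- vapply(sites, function(s) {
      r <- x$table[x$table$model == m & x$table$test_site == s, ]
      sprintf("%.1f%% [%.2f,%.2f] %.3f", r$balanced_accuracy, r$tnr, r$tpr, r$mean_iou)
    }, "")
    cat(sprintf("%-14s", m), sprintf("%-22s", cells), "\n", sep = " ")
  }
  cat("cells: balanced accuracy [TNR, TPR] and mean lesion IoU\n")
  invisible(x)
}
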