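## Evaluation statistics: pixel confusion metrics, rank-based AUC, and
## lesion-size-stratified dataset evaluation.

#' Pixel confusion metrics for a binary segmentation
#'
#' Returns precision, sensitivity (recall), specificity, IoU (Jaccard) and
#' DSC (Dice). Ratios with a zero denominator are defined as 1 ("no
#' opportunity for error"), so an empty mask with an empty prediction
#' scores 1 everywhere.
#'
#' @param P_bin binary predicted mask; `B` binary ground truth.
#' @return named numeric vector
#'   `(precision, sensitivity, specificity, iou, dsc)`.
#' @export
confusion_metrics <- function(P_bin, B) {
  check_same_shape(P_bin, B, "P_bin and B")
  check_binary(P_bin, "P_bin"); check_binary(B, "B")
  tp <- sum(P_bin == 1 & B == 1)
  fp <- sum(P_bin == 1 & B == 0)
  fn <- sum(P_bin == 0 & B == 1)
  tn <- sum(P_bin == 0 & B == 0)
  safe <- function(num, den) if (den == 0) 1 else num / den
  c(precision = safe(tp, tp + fp),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    iou = safe(tp, tp + fp + fn),
    dsc = safe(2 * tp, 2 * tp + fp + fn))
}

#' Area under the ROC curve over pixel scores
#'
#' Computed as the normalized Mann-Whitney rank-sum statistic with midranks
#' for ties, identical to the trapezoidal area under the ROC curve.
#'
#' @param P_prob numeric scores/probabilities; `B` binary ground truth of
#'   the same shape.
#' @return AUC in `[0,1]`, or `NA_real_` when `B` is single-class.
#' @export
auc_score <- function(P_prob, B) {
  check_same_shape(P_prob, B, "P_prob and B")
  check_binary(B, "B")
  n_pos <- sum(B == 1); n_neg <- sum(B == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(as.numeric(P_prob), ties.method = "average")
  (sum(r[B == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a model over a dataset manifest, stratified by lesion size
#'
#' Per-image metrics are macro-averaged within each stratum (`all`,
#' `small`, `large`). AUC is computed per image and averaged; images whose
#' ground truth is single-class are excluded from the AUC average and
#' counted in `n_auc_excluded`. With `average = "pooled"` the confusion
#' counts are pooled over pixels of the stratum instead.
#'
#' @param model a `ppaseg_model`, or a function `f(image)` returning a
#'   probability map (useful as a ground-truth oracle in testing).
#' @param manifest data frame with columns `image_path`, `mask_path`,
#'   `size_class` (and optionally `split`), as written by
#'   [write_fundus_dataset()]; or a list of in-memory samples.
#' @param threshold binarization threshold in `(0,1)`.
#' @param average `"macro"` (per-image, default) or `"pooled"`.
#' @return data frame with one row per stratum: the six metrics,
#'   `n_images`, `n_auc_excluded`.
#' @export
evaluate_model <- function(model, manifest, threshold = 0.5,
                           average = c("macro", "pooled")) {
  average <- match.arg(average)
  if (!(is.numeric(threshold) && threshold > 0 && threshold < 1)) {
    stop("threshold must lie in (0,1)")
  }
  predict_fun <- if (is.function(model)) model else {
    function(img) ppa_unet_forward(model, img)$prob
  }
  samples <- manifest_samples(manifest)
  per <- lapply(samples, function(s) {
    prob <- predict_fun(s$image)
    pbin <- (prob >= threshold) * 1
    cm <- confusion_metrics(pbin, s$mask)
    list(cm = cm, auc = auc_score(prob, s$mask), size_class = s$size_class,
         counts = c(tp = sum(pbin & s$mask), fp = sum(pbin & !s$mask),
                    fn = sum(!pbin & s$mask), tn = sum(!pbin & !s$mask)))
  })
  strata <- list(all = seq_along(per),
                 small = which(vapply(per, function(p) p$size_class,
                                      character(1)) == "small"),
                 large = which(vapply(per, function(p) p$size_class,
                                      character(1)) == "large"))
  rows <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    if (length(idx) == 0) {
      return(data.frame(stratum = nm, precision = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        auc = NA_real_, iou = NA_real_, dsc = NA_real_,
                        n_images = 0L, n_auc_excluded = 0L))
    }
    aucs <- vapply(per[idx], function(p) p$auc, numeric(1))
    if (average == "macro") {
      cms <- t(vapply(per[idx], function(p) p$cm, numeric(5)))
      met <- colMeans(cms)
    } else {
      cts <- colSums(t(vapply(per[idx], function(p) p$counts, numeric(4))))
      safe <- function(num, den) if (den == 0) 1 else num / den
      met <- c(precision = safe(cts["tp"], cts["tp"] + cts["fp"]),
               sensitivity = safe(cts["tp"], cts["tp"] + cts["fn"]),
               specificity = safe(cts["tn"], cts["tn"] + cts["fp"]),
               iou = safe(cts["tp"], cts["tp"] + cts["fp"] + cts["fn"]),
               dsc = safe(2 * cts["tp"],
                          2 * cts["tp"] + cts["fp"] + cts["fn"]))
    }
    data.frame(stratum = nm,
               precision = unname(met["precision"]),
               sensitivity = unname(met["sensitivity"]),
               specificity = unname(met["specificity"]),
               auc = if (all(is.na(aucs))) NA_real_
                     else mean(aucs, na.rm = TRUE),
               iou = unname(met["iou"]),
               dsc = unname(met["dsc"]),
               n_images = length(idx),
               n_auc_excluded = sum(is.na(aucs)))
  })
  do.call(rbind, rows)
}

## Accept a manifest data frame (paths on disk) or a list of in-memory
## samples (each with $image, $mask, $size_class).
manifest_samples <- function(manifest) {
  if (is.data.frame(manifest)) {
    lapply(seq_len(nrow(manifest)), function(i) {
      list(image = read_image_png(manifest$image_path[i]),
           mask = round(read_image_png(manifest$mask_path[i])),
           size_class = as.character(manifest$size_class[i]))
    })
  } else {
    lapply(manifest, function(s) {
      if (is.null(s$size_class)) s$size_class <- classify_lesion_size(s)
      s
    })
  }
}
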