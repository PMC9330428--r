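# Voxel-wise metrics (Dice, specificity, sensitivity, accuracy from
# one-vs-rest confusion counts), per-case success rates, stone inventories
# from 26-connected components, and stone-size-stratified Dice.

#' Voxel-wise confusion counts for one class
#'
#' One-vs-rest binarization of `class_id` in both volumes, then TP/FP/TN/FN
#' by voxel-wise comparison.
#'
#' @param pred,truth [label_volume()]s (or bare integer arrays) of equal
#'   shape.
#' @param class_id class to binarize (1 kidney, 2 stone).
#' @return named list TP/FP/TN/FN (counts summing to the voxel total).
#' @export
confusion_counts <- function(pred, truth, class_id) {
  p <- if (is.list(pred)) pred$voxels else pred
  t <- if (is.list(truth)) truth$voxels else truth
  if (!identical(dim(p), dim(t))) stop("pred and truth shapes differ")
  pb <- p == class_id
  tb <- t == class_id
  tp <- sum(pb & tb)
  fp <- sum(pb & !tb)
  fn <- sum(!pb & tb)
  tn <- length(p) - tp - fp - fn
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN), specificity = TN/(TN+FP), sensitivity =
#' TP/(TP+FN), accuracy = (TP+TN)/total.  Zero-denominator convention: an
#' empty truth with an empty prediction scores 1 (so stone-free cases with
#' correct empty predictions are not penalized).
#'
#' @param c named list TP/FP/TN/FN.
#' @return named list dice/specificity/sensitivity/accuracy, each in \[0,1\].
#' @export
metrics_from_counts <- function(c) {
  safe <- function(num, den) if (den == 0) 1.0 else num / den
  list(dice = safe(2 * c$TP, 2 * c$TP + c$FP + c$FN),
       specificity = safe(c$TN, c$TN + c$FP),
       sensitivity = safe(c$TP, c$TP + c$FN),
       accuracy = safe(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN))
}

#' Classify a stone by physical volume
#'
#' Half-open volume classes: small `[0, 28)` mm3, medium `[28, 315)` mm3,
#' large `[315, Inf)` mm3 (display diameters are equivalent-sphere values;
#' the volume thresholds are authoritative for a voxel-count pipeline).
#'
#' @param volume_mm3 numeric vector of stone volumes.
#' @return character vector `"small"` / `"medium"` / `"large"`.
#' @export
classify_stone_size <- function(volume_mm3) {
  if (any(volume_mm3 < 0)) stop("volumes must be >= 0")
  ifelse(volume_mm3 < 28, "small", ifelse(volume_mm3 < 315, "medium", "large"))
}

#' Inventory of stones in a label volume
#'
#' 26-connected components of label 2; each record carries voxel count,
#' physical volume (voxel count x voxel volume), centroid and size class.
#'
#' @param label a [label_volume()].
#' @return data frame, one row per stone (0 rows when no stone voxels).
#' @export
stone_inventory <- function(label) {
  m <- label$voxels == 2L
  empty <- data.frame(component_id = integer(), voxel_count = integer(),
                      volume_mm3 = numeric(), size_class = character(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric())
  if (!any(m)) return(empty)
  lab <- cpp_label_components(array(as.integer(m), dim(m)))
  ncomp <- max(lab)
  vox_mm3 <- vox_volume_mm3(label)
  rows <- lapply(seq_len(ncomp), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    data.frame(component_id = k, voxel_count = nrow(idx),
               volume_mm3 = nrow(idx) * vox_mm3,
               size_class = classify_stone_size(nrow(idx) * vox_mm3),
               centroid_z = mean(idx[, 1]), centroid_y = mean(idx[, 2]),
               centroid_x = mean(idx[, 3]))
  })
  do.call(rbind, rows)
}

#' Fraction of cases meeting a per-case quality threshold
#'
#' @param values per-case metric values (e.g. Dice).
#' @param threshold success criterion (default 0.5); always reported
#'   alongside the rate, never hard-coded downstream.
#' @return list with `rate`, `threshold`, `n`.
#' @export
success_rate <- function(values, threshold = 0.5) {
  values <- values[!is.na(values)]
  list(rate = if (length(values)) mean(values >= threshold) else NA_real_,
       threshold = threshold, n = length(values))
}

#' Stone-size-stratified Dice
#'
#' Each ground-truth stone (26-connected component of label 2 in `truth`)
#' is greedily matched to the predicted stone component with maximal voxel
#' overlap; its per-stone Dice is `2|P∩T| / (|P| + |T|)` (0 when unmatched).
#' Results are aggregated per size class; empty strata are absent from the
#' output.
#'
#' @param pred,truth [label_volume()]s of equal shape.
#' @return list with `per_stone` (data frame) and `by_class` (data frame of
#'   mean/sd/n per size class).
#' @export
size_stratified_dice <- function(pred, truth) {
  tm <- truth$voxels == 2L
  pm <- pred$voxels == 2L
  vox_mm3 <- vox_volume_mm3(truth)
  empty <- list(per_stone = data.frame(), by_class = data.frame())
  if (!any(tm)) return(empty)
  tl <- cpp_label_components(array(as.integer(tm), dim(tm)))
  pl <- if (any(pm)) cpp_label_components(array(as.integer(pm), dim(pm)))
        else array(0L, dim(pm))
  nt <- max(tl); np <- max(pl)
  tsize <- tabulate(tl[tl > 0L], nbins = nt)
  psize <- if (np > 0) tabulate(pl[pl > 0L], nbins = np) else integer(0)
  # overlap table between truth and predicted components
  both <- tl > 0L & pl > 0L
  ov <- if (any(both))
    as.data.frame(table(t = tl[both], p = pl[both]), stringsAsFactors = FALSE)
  else data.frame(t = character(), p = character(), Freq = integer())
  ov$t <- as.integer(ov$t); ov$p <- as.integer(ov$p)
  ov <- ov[order(-ov$Freq), , drop = FALSE]
  match_p <- rep(NA_integer_, nt)
  used_p <- logical(max(np, 1))
  for (i in seq_len(nrow(ov))) {
    ti <- ov$t[i]; pi <- ov$p[i]
    if (is.na(match_p[ti]) && !used_p[pi]) {
      match_p[ti] <- pi
      used_p[pi] <- TRUE
    }
  }
  per <- lapply(seq_len(nt), function(k) {
    inter <- if (is.na(match_p[k])) 0L else ov$Freq[ov$t == k & ov$p == match_p[k]]
    if (!length(inter)) inter <- 0L
    pk <- if (is.na(match_p[k])) 0L else psize[match_p[k]]
    data.frame(stone = k, volume_mm3 = tsize[k] * vox_mm3,
               size_class = classify_stone_size(tsize[k] * vox_mm3),
               dice = if (pk + tsize[k] > 0) 2 * inter / (pk + tsize[k]) else 1)
  })
  per <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(split(per, per$size_class), function(g)
    data.frame(size_class = g$size_class[1], mean_dice = mean(g$dice),
               sd_dice = if (nrow(g) > 1) sd(g$dice) else NA_real_, n = nrow(g))))
  rownames(agg) <- NULL
  list(per_stone = per, by_class = agg)
}

#' Evaluate a cohort of predictions against truth
#'
#' Per case and class (kidney, stone): Dice, specificity, sensitivity,
#' accuracy; cohort aggregates mean +/- sd; success rates at the configured
#' threshold.
#'
#' @param preds,truths lists of [label_volume()]s, same order.
#' @param success_threshold per-case Dice success criterion.
#' @return list with `per_case` (data frame), `summary` (data frame),
#'   `success` (data frame).
#' @export
evaluate_cohort <- function(preds, truths, success_threshold = 0.5) {
  stopifnot(length(preds) == length(truths))
  rows <- list()
  for (i in seq_along(preds)) {
    for (cls in c(kidney = 1L, stone = 2L)) {
      cname <- names(which(c(kidney = 1L, stone = 2L) == cls))
      cc <- confusion_counts(preds[[i]], truths[[i]], cls)
      m <- metrics_from_counts(cc)
      rows[[length(rows) + 1]] <- data.frame(
        case = i, class = cname, dice = m$dice, specificity = m$specificity,
        sensitivity = m$sensitivity, accuracy = m$accuracy)
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_case, per_case$class), function(g)
    data.frame(class = g$class[1],
               dice_mean = mean(g$dice), dice_sd = sd(g$dice),
               sensitivity_mean = mean(g$sensitivity),
               specificity_mean = mean(g$specificity),
               accuracy_mean = mean(g$accuracy), n = nrow(g))))
  rownames(summary) <- NULL
  success <- do.call(rbind, lapply(split(per_case, per_case$class), function(g) {
    sr <- success_rate(g$dice, success_threshold)
    data.frame(class = g$class[1], success_rate = sr$rate,
               threshold = sr$threshold, n = sr$n)
  }))
  rownames(success) <- NULL
  list(per_case = per_case, summary = summary, success = success)
}
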