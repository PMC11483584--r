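#' Voxel-level detection F-score
#'
#' Precision, recall and F-score of a predicted voxel mask against a
#' ground-truth mask: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F = 2PR/(P+R)`. All three are 0 when their denominator is 0 (in
#' particular, an empty prediction against an empty truth scores F = 0
#' by convention, and is logged).
#'
#' @param predicted_mask,truth_mask logical arrays of equal shape.
#' @return named numeric: `precision`, `recall`, `f`.
#' @export
f_score <- function(predicted_mask, truth_mask) {
  if (!all(dim(predicted_mask) == dim(truth_mask)))
    stop("shape mismatch between predicted and truth masks")
  p <- as.logical(predicted_mask)
  t <- as.logical(truth_mask)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  if (tp + fp + fn == 0)
    tau_log("fscore", "empty prediction and empty truth: F defined as 0")
  c(precision = prec, recall = rec, f = f)
}

#' Annotation ROI for detection-accuracy scoring
#'
#' A cubic region of interest (423 um edge by default, the evaluation
#' ROI size used for expert annotation) with one boolean ground-truth
#' mask per annotator.
#'
#' @param origin_vox (z, y, x) 1-based index of the ROI corner in the
#'   source volume.
#' @param annotator_masks list of >= 1 logical 3D arrays of equal shape.
#' @param edge_um cube edge in micrometres.
#' @param pitch_um voxel pitch; `edge_um / pitch_um` must round to the
#'   mask edge in voxels.
#' @return list of class `annotation_roi`.
#' @export
annotation_roi <- function(origin_vox, annotator_masks, edge_um = 423,
                           pitch_um = 8.3) {
  stopifnot(length(annotator_masks) >= 1L)
  d <- dim(annotator_masks[[1]])
  for (m in annotator_masks)
    if (!all(dim(m) == d)) stop("annotator masks must share the ROI shape")
  edge_vox <- round(edge_um / pitch_um)
  # the edge must sit on the voxel grid to within 0.1% (423 um at the
  # 8.3 um standard pitch is 50.96 voxels, i.e. the 51-voxel cube)
  if (edge_vox < 1 || abs(edge_um / pitch_um - edge_vox) > 1e-3 * edge_vox)
    stop("edge_um does not round to an integer voxel edge at this pitch")
  if (!all(d == edge_vox))
    stop("annotator masks must be ", edge_vox, "^3 (", edge_um, " um at ",
         pitch_um, " um pitch)")
  structure(list(origin_vox = as.integer(origin_vox),
                 annotator_masks = annotator_masks,
                 edge_um = edge_um, pitch_um = pitch_um),
            class = "annotation_roi")
}

#' ROI detection accuracy averaged over annotators
#'
#' Crops the predicted candidate-voxel mask to the annotation ROI,
#' scores it against each annotator's mask independently, and returns
#' the arithmetic mean of the per-annotator F-scores as the unified
#' regional score.
#'
#' @param predicted_mask logical 3D array on the full volume grid, or
#'   already cropped to the ROI shape.
#' @param roi an [annotation_roi].
#' @return list with `f_mean` and `per_annotator` (matrix of precision,
#'   recall, f per annotator).
#' @export
region_f_score <- function(predicted_mask, roi) {
  stopifnot(inherits(roi, "annotation_roi"))
  d_roi <- dim(roi$annotator_masks[[1]])
  if (!all(dim(predicted_mask) == d_roi)) {
    o <- roi$origin_vox
    predicted_mask <- predicted_mask[o[1]:(o[1] + d_roi[1] - 1L),
                                     o[2]:(o[2] + d_roi[2] - 1L),
                                     o[3]:(o[3] + d_roi[3] - 1L)]
  }
  per <- t(vapply(roi$annotator_masks,
                  function(m) f_score(predicted_mask, m), numeric(3)))
  list(f_mean = mean(per[, "f"]), per_annotator = per)
}

#' Standardized uptake value per frame
#'
#' `SUV_t = activity_t / (dose / body_weight)`: tissue radioactivity
#' (kBq/cc) normalised by injected dose (kBq) per body weight (g).
#'
#' @param curve a [tac].
#' @return numeric vector of per-frame SUVs.
#' @export
suv <- function(curve) {
  stopifnot(inherits(curve, "tac"))
  curve$activity_kbq_per_cc / (curve$dose_kbq / curve$body_weight_g)
}

#' Standardized uptake value ratio
#'
#' Per-frame SUVR (target SUV / reference SUV; the reference is the
#' cerebellum, devoid of tau aggregates) and its mean over the frames
#' whose mid-times fall in the closed late window (45-60 min by
#' default). Dose and body weight cancel when target and reference
#' come from the same scan.
#'
#' @param target_tac,reference_tac [tac] objects on the same frame grid.
#' @param window_min closed time window (min) for the scalar summary.
#' @return list with `suvr` (per-frame), `times_min`, `window_min`, and
#'   `scalar` (mean SUVR in the window).
#' @export
suvr <- function(target_tac, reference_tac, window_min = c(45, 60)) {
  stopifnot(inherits(target_tac, "tac"), inherits(reference_tac, "tac"))
  if (!isTRUE(all.equal(target_tac$frame_mid_times_min,
                        reference_tac$frame_mid_times_min)))
    stop("target and reference TACs must share the frame grid")
  s_ref <- suv(reference_tac)
  t <- target_tac$frame_mid_times_min
  in_win <- t >= window_min[1] & t <= window_min[2]
  if (!any(in_win)) stop("no frames in the SUVR window")
  if (any(s_ref[in_win] <= 0))
    stop("reference SUV must be > 0 within the window")
  ratio <- suv(target_tac) / s_ref
  list(suvr = ratio, times_min = t, window_min = window_min,
       scalar = mean(ratio[in_win]))
}
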