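#' Build a detector from precomputed global detections
#'
#' Wraps a slide-global detection table as a patch detector: queried with
#' a patch spec, it returns (in patch-local coordinates) every detection
#' whose center falls inside the patch window. This is how both synthetic
#' detectors and precomputed real-model outputs plug into
#' [run_pipeline()].
#'
#' @param dets Scored circle table in slide-global coordinates.
#' @param model_id Label identifying the model.
#' @return A list of class `detector` with fields `model_id` and
#'   `detect(patch)`.
#' @export
detector_from_detections <- function(dets, model_id) {
  validate_circles(dets, scored = nrow(dets) > 0)
  force(dets)
  structure(
    list(
      model_id = as.character(model_id),
      detect = function(patch) {
        inside <- dets$cx >= patch$x0 & dets$cx < patch$x0 + patch$size &
          dets$cy >= patch$y0 & dets$cy < patch$y0 + patch$size
        to_local(dets[inside, , drop = FALSE], patch)
      }
    ),
    class = "detector"
  )
}

#' Oracle detector that returns the ground truth
#'
#' A noise-free detector serving every ground-truth circle (score 1) —
#' the reference point for end-to-end pipeline identities: with perfect
#' detectors the pipeline must return the ground truth exactly.
#'
#' @param gt Ground-truth circle table (slide-global, unscored).
#' @param model_id Label for the detector.
#' @return A `detector`.
#' @export
perfect_detector <- function(gt, model_id = "perfect") {
  validate_circles(gt)
  d <- gt
  d$score <- rep(1, nrow(d))
  d$model_id <- rep(as.character(model_id), nrow(d))
  detector_from_detections(d, model_id)
}

#' Run the whole-slide detection pipeline
#'
#' The end-to-end orchestration: tile the slide with half-overlap
#' patches, run every detector on every patch, translate patch-local
#' detections back to the slide frame, collapse the duplicates that
#' overlapping patches inevitably produce with per-model hard NMS, and
#' finally fuse the per-model sets with weighted circle fusion.
#'
#' A detector that raises an error on a patch loses that patch only
#' (partial-result semantics); the failures are counted in the
#' `pipeline_summary` attribute of the result.
#'
#' @param slide A [slide_meta()].
#' @param detectors A list of `detector` objects (at least one), e.g.
#'   from [detector_from_detections()].
#' @param patch,stride Tiling geometry, default 512 with half overlap.
#' @param sup_cfg Per-model cross-patch NMS settings
#'   ([suppression_config()]).
#' @param fusion_cfg Ensemble fusion settings ([fusion_config()]).
#' @return A fused-circle table in slide-global coordinates (see
#'   [wcf()]), with attribute `pipeline_summary` recording patch counts
#'   and per-model detection/failure counts.
#' @export
run_pipeline <- function(slide, detectors, patch = 512L,
                         stride = patch / 2,
                         sup_cfg = suppression_config(),
                         fusion_cfg = fusion_config()) {
  if (!is.list(detectors) || length(detectors) == 0L) {
    stop("need at least one detector", call. = FALSE)
  }
  tiles <- make_tiles(slide, patch = patch, stride = stride)

  per_model <- list()
  failures <- integer(length(detectors))
  for (m in seq_along(detectors)) {
    det <- detectors[[m]]
    pooled <- vector("list", nrow(tiles))
    for (t in seq_len(nrow(tiles))) {
      spec <- tiles[t, , drop = FALSE]
      local <- tryCatch(det$detect(spec), error = function(e) e)
      if (inherits(local, "error")) {
        failures[m] <- failures[m] + 1L
        next
      }
      if (nrow(local)) pooled[[t]] <- to_global(local, spec)
    }
    pooled <- do.call(rbind, pooled)
    if (is.null(pooled)) pooled <- empty_circles()
    # one NMS pass over the aggregated global detections removes the
    # copies of a single object seen from several overlapping patches
    if (nrow(pooled)) pooled <- nms(pooled, sup_cfg)
    per_model[[det$model_id]] <- pooled
  }
  if (any(failures > 0)) {
    warning("detector failures on ", sum(failures), " patch run(s); ",
            "affected patches skipped", call. = FALSE)
  }

  fused <- wcf(per_model, fusion_cfg)
  attr(fused, "pipeline_summary") <- list(
    slide = slide$name,
    n_patches = nrow(tiles),
    per_model_detections = vapply(per_model, nrow, integer(1)),
    patch_failures = setNames(failures,
                              vapply(detectors, `[[`, character(1),
                                     "model_id"))
  )
  fused
}
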