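#' Compare fusion methods on synthetic ensemble benchmarks
#'
#' Runs the synthetic five-detector benchmark across a set of seeds and
#' scores four post-processing strategies against the ground truth with
#' circle-IoU average precision: each individual detector (after NMS),
#' pooled-ensemble hard NMS, pooled-ensemble Soft-NMS, and weighted
#' circle fusion at its default consensus/confidence thresholds. This is
#' the package's reproducible analogue of comparing an ensemble against
#' its members on real slides.
#'
#' @param cfg A [sim_config()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds Integer vector of benchmark seeds (default 1:100).
#' @param iou_threshold IoU threshold at which AP is reported
#'   (default 0.5).
#' @param fusion_cfg Fusion settings for the WCF arm.
#' @param sup_cfg Suppression settings for the NMS/Soft-NMS arms.
#' @return A list: `per_seed` (data.frame with one row per seed and one
#'   column per method: `wcf`, `nms_pooled`, `soft_nms_pooled`,
#'   `individual_mean`, plus `individual_1..n`) and `summary` (named
#'   means over seeds).
#' @export
compare_fusion_methods <- function(cfg = sim_config(), seeds = 1:100,
                                   iou_threshold = 0.5,
                                   fusion_cfg = fusion_config(),
                                   sup_cfg = suppression_config()) {
  ecfg <- eval_config(iou_thresholds = iou_threshold)
  ap50 <- function(dets, gt) {
    evaluate_detections(dets, gt, ecfg)$ap_by_threshold[[1]]
  }
  rows <- lapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    bench <- make_ensemble_benchmark(cfg)
    per_model <- lapply(bench$per_model, nms, cfg = sup_cfg)
    ind <- vapply(per_model, ap50, numeric(1), gt = bench$gt)
    pooled <- do.call(rbind, unname(bench$per_model))
    fused <- wcf(per_model, fusion_cfg)
    out <- c(
      wcf = ap50(fused, bench$gt),
      nms_pooled = ap50(nms(pooled, sup_cfg), bench$gt),
      soft_nms_pooled = ap50(soft_nms(pooled, sup_cfg), bench$gt),
      individual_mean = mean(ind)
    )
    c(out, setNames(ind, paste0("individual_", seq_along(ind))))
  })
  per_seed <- as.data.frame(do.call(rbind, rows))
  per_seed$seed <- seeds
  list(per_seed = per_seed,
       summary = colMeans(per_seed[, setdiff(names(per_seed), "seed")]))
}
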