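#' Suppression configuration
#'
#' Parameters for redundancy removal within one detection set.
#'
#' @param iou_threshold Circle-IoU overlap above which a lower-scored
#'   detection is suppressed by hard NMS; in (0, 1), default 0.5.
#' @param sigma Gaussian decay width for Soft-NMS (> 0, default 0.5):
#'   an overlapping detection's score is multiplied by
#'   `exp(-IoU^2 / sigma)`.
#' @param score_floor Minimum score a Soft-NMS-decayed detection may keep
#'   before being dropped (>= 0, default 0.001).
#' @return A list of class `suppression_config`.
#' @export
suppression_config <- function(iou_threshold = 0.5, sigma = 0.5,
                               score_floor = 0.001) {
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1 ||
      iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must be a single value in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a single value > 0", call. = FALSE)
  }
  if (!is.numeric(score_floor) || length(score_floor) != 1 ||
      score_floor < 0) {
    stop("score_floor must be >= 0", call. = FALSE)
  }
  structure(list(iou_threshold = iou_threshold, sigma = sigma,
                 score_floor = score_floor),
            class = "suppression_config")
}

#' Non-maximum suppression on circles
#'
#' Greedy hard NMS: walk the detections in descending-score order (ties
#' broken by center then radius so any input permutation gives the same
#' result) and drop a detection iff its circle IoU with an already-kept
#' detection exceeds `iou_threshold`. Kept circles are returned unmodified
#' in descending-score order — for each group of mutually overlapping
#' detections only the one with the highest confidence survives.
#'
#' @param dets Circle table with a score on every row.
#' @param cfg A [suppression_config()].
#' @return The kept subset of `dets`, descending by score.
#' @export
nms <- function(dets, cfg = suppression_config()) {
  validate_circles(dets, scored = TRUE)
  if (nrow(dets) <= 1L) {
    return(dets[order_by_score(dets), , drop = FALSE])
  }
  d <- dets[order_by_score(dets), , drop = FALSE]
  n <- nrow(d)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    later <- which(alive & seq_len(n) > i)
    if (length(later)) {
      iou <- circle_iou(d$cx[i], d$cy[i], d$r[i],
                        d$cx[later], d$cy[later], d$r[later])
      alive[later[iou > cfg$iou_threshold]] <- FALSE
    }
  }
  d[keep, , drop = FALSE]
}

#' Soft non-maximum suppression on circles
#'
#' Instead of deleting overlapping detections outright, Soft-NMS decays
#' their confidence: iteratively pop the highest-scored remaining
#' detection as kept, then multiply every other remaining detection's
#' score by `exp(-IoU^2 / sigma)` against the popped circle; detections
#' whose score falls below `score_floor` are dropped. Geometry is
#' untouched — only scores change.
#'
#' @inheritParams nms
#' @return The surviving detections with decayed scores, in the order
#'   they were popped (descending surviving score).
#' @export
soft_nms <- function(dets, cfg = suppression_config()) {
  validate_circles(dets, scored = TRUE)
  if (nrow(dets) <= 1L) {
    return(dets[order_by_score(dets), , drop = FALSE])
  }
  d <- dets[order_by_score(dets), , drop = FALSE]
  rownames(d) <- NULL
  remaining <- seq_len(nrow(d))
  scores <- d$score
  kept_idx <- integer(0)
  kept_scores <- numeric(0)
  while (length(remaining)) {
    # deterministic pop: max decayed score, ties by original sort order
    best <- remaining[which.max(scores[remaining])]
    kept_idx <- c(kept_idx, best)
    kept_scores <- c(kept_scores, scores[best])
    remaining <- setdiff(remaining, best)
    if (length(remaining)) {
      iou <- circle_iou(d$cx[best], d$cy[best], d$r[best],
                        d$cx[remaining], d$cy[remaining], d$r[remaining])
      scores[remaining] <- scores[remaining] * exp(-(iou^2) / cfg$sigma)
      remaining <- remaining[scores[remaining] >= cfg$score_floor]
    }
  }
  out <- d[kept_idx, , drop = FALSE]
  out$score <- kept_scores
  rownames(out) <- NULL
  out
}
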