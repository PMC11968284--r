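#' Evaluation configuration
#'
#' @param iou_thresholds Strictly increasing circle-IoU thresholds in
#'   (0, 1); default the standard grid 0.5 to 0.95 in steps of 0.05.
#' @param max_dets Cap on scored detections per slide (top-scored first),
#'   default 500.
#' @param interpolation `"101-point"` (default, the COCO-style sampled
#'   precision-recall summary) or `"all-point"` (exact area under the
#'   interpolated precision envelope; convenient for hand-checked cases).
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(iou_thresholds = seq(0.5, 0.95, by = 0.05),
                        max_dets = 500L,
                        interpolation = c("101-point", "all-point")) {
  th <- as.numeric(iou_thresholds)
  if (length(th) == 0 || any(th <= 0) || any(th >= 1) ||
      is.unsorted(th, strictly = TRUE)) {
    stop("iou_thresholds must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(max_dets) || length(max_dets) != 1 || max_dets < 1) {
    stop("max_dets must be a positive integer", call. = FALSE)
  }
  structure(list(iou_thresholds = th, max_dets = as.integer(max_dets),
                 interpolation = match.arg(interpolation)),
            class = "eval_config")
}

#' Greedy detection-to-ground-truth matching
#'
#' The standard matching protocol under circle IoU: detections are
#' visited in descending-score order; each claims the unmatched ground
#' truth with the highest IoU, provided that IoU reaches `iou_thr`
#' (a true positive), else it is a false positive. Each ground truth can
#' be matched at most once.
#'
#' @param dets Scored circle table.
#' @param gts Ground-truth circle table (scores ignored).
#' @param iou_thr Matching threshold in (0, 1).
#' @return A list: `order` (row indices of `dets` in the visiting
#'   order), `tp` (logical flag per visited detection), `matched_gt`
#'   (ground-truth row index per detection, `NA` for false positives),
#'   and `gt_matched` (logical per ground truth).
#' @export
match_detections <- function(dets, gts, iou_thr) {
  validate_circles(gts)
  validate_circles(dets, scored = nrow(dets) > 0)
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0L) {
    return(list(order = integer(0), tp = logical(0),
                matched_gt = integer(0),
                gt_matched = rep(FALSE, ng)))
  }
  ord <- order_by_score(dets)
  tp <- logical(nd)
  matched_gt <- rep(NA_integer_, nd)
  gt_matched <- rep(FALSE, ng)
  if (ng > 0L) {
    iou <- pairwise_iou(dets[ord, , drop = FALSE], gts)
    for (i in seq_len(nd)) {
      cand <- which(!gt_matched & iou[i, ] >= iou_thr)
      if (length(cand)) {
        best <- cand[which.max(iou[i, cand])]
        tp[i] <- TRUE
        matched_gt[i] <- best
        gt_matched[best] <- TRUE
      }
    }
  }
  list(order = ord, tp = tp, matched_gt = matched_gt,
       gt_matched = gt_matched)
}

#' Average precision from ordered match flags
#'
#' Builds the precision-recall curve from cumulative true/false positive
#' counts (flags must be in descending-score order) and summarizes it:
#' `"all-point"` integrates the precision envelope exactly over recall;
#' `"101-point"` averages the envelope at the 101 recall sample points
#' 0, 0.01, ..., 1.
#'
#' With no ground truth and no detections the quantity is undefined and
#' `NA` is returned (such slides are excluded from aggregation, never
#' scored 1); with detections but no ground truth every flag is a false
#' positive and AP is 0.
#'
#' @param tp Logical vector of true-positive flags in descending-score
#'   order.
#' @param n_gt Number of ground-truth objects.
#' @param interpolation `"101-point"` or `"all-point"`.
#' @return AP in \[0, 1\], or `NA_real_` when undefined.
#' @export
average_precision <- function(tp, n_gt,
                              interpolation = c("101-point", "all-point")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0L) {
    return(if (length(tp) == 0L) NA_real_ else 0)
  }
  if (length(tp) == 0L) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  precision <- ctp / (ctp + cfp)
  recall <- ctp / n_gt
  # non-increasing precision envelope from the right
  envelope <- rev(cummax(rev(precision)))
  if (interpolation == "all-point") {
    dr <- diff(c(0, recall))
    sum(dr * envelope)
  } else {
    grid <- seq(0, 1, by = 0.01)
    # envelope value at the first operating point with recall >= g; 0 past max recall
    idx <- findInterval(grid, recall, left.open = TRUE) + 1L
    p <- numeric(length(grid))
    valid <- idx <= length(envelope)
    p[valid] <- envelope[idx[valid]]
    mean(p)
  }
}

#' Evaluate detections against ground truth
#'
#' Runs greedy matching and average precision at every threshold of the
#' IoU grid and assembles the summary detection metrics: per-threshold
#' AP, `map_50`, `map_75`, `map_50_95` (the mean over the grid), and
#' average recall (mean over thresholds of the fraction of ground truths
#' matched, using at most `max_dets` top-scored detections).
#'
#' @param dets Scored circle table (a plain detection set or [wcf()]
#'   output — the fused `score` column is the confidence).
#' @param gts Ground-truth circle table.
#' @param cfg An [eval_config()].
#' @return A list of class `eval_result`: `ap_by_threshold` (named
#'   numeric), `map_50`, `map_75`, `map_50_95`, `average_recall`,
#'   `n_gt`, `n_dets`. All fields `NA` (with `defined = FALSE`) when
#'   both inputs are empty.
#' @export
evaluate_detections <- function(dets, gts, cfg = eval_config()) {
  validate_circles(gts)
  if (nrow(dets) > cfg$max_dets) {
    d <- dets[order_by_score(dets), , drop = FALSE]
    dets <- d[seq_len(cfg$max_dets), , drop = FALSE]
  }
  th <- cfg$iou_thresholds
  if (nrow(dets) == 0L && nrow(gts) == 0L) {
    ap <- setNames(rep(NA_real_, length(th)), format(th))
    return(structure(list(ap_by_threshold = ap, map_50 = NA_real_,
                          map_75 = NA_real_, map_50_95 = NA_real_,
                          average_recall = NA_real_, n_gt = 0L,
                          n_dets = 0L, defined = FALSE),
                     class = "eval_result"))
  }
  ap <- numeric(length(th))
  recall <- numeric(length(th))
  for (k in seq_along(th)) {
    m <- match_detections(dets, gts, th[k])
    ap[k] <- average_precision(m$tp, nrow(gts), cfg$interpolation)
    recall[k] <- if (nrow(gts) == 0L) NA_real_ else mean(m$gt_matched)
  }
  names(ap) <- format(th)
  at <- function(x) {
    i <- which(abs(th - x) < 1e-9)
    if (length(i)) unname(ap[i]) else NA_real_
  }
  structure(list(
    ap_by_threshold = ap,
    map_50 = at(0.5),
    map_75 = at(0.75),
    map_50_95 = mean(ap),
    average_recall = mean(recall),
    n_gt = nrow(gts),
    n_dets = nrow(dets),
    defined = TRUE
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Detection evaluation (circle IoU)\n")
  cat(sprintf("  ground truth: %d, detections: %d\n", x$n_gt, x$n_dets))
  if (isFALSE(x$defined)) {
    cat("  undefined (no ground truth and no detections)\n")
    return(invisible(x))
  }
  cat(sprintf("  mAP@0.5      %.4f\n", x$map_50))
  cat(sprintf("  mAP@0.75     %.4f\n", x$map_75))
  cat(sprintf("  mAP@0.5:0.95 %.4f\n", x$map_50_95))
  cat(sprintf("  AR           %.4f\n", x$average_recall))
  invisible(x)
}

#' Evaluate per slide and aggregate
#'
#' Detections are pooled per slide; metrics are computed per slide and
#' averaged over slides with at least one ground-truth object
#' (`pooled = FALSE`, default), or all slides are pooled into one
#' instance set (`pooled = TRUE`).
#'
#' @param dets Scored circle table with a `slide` column.
#' @param gts Ground-truth table with a `slide` column.
#' @param cfg An [eval_config()].
#' @param pooled Pool slides instead of averaging per-slide results.
#' @return A list: `per_slide` (named list of `eval_result`) and
#'   `aggregate` (an `eval_result`-like list of averaged fields).
#' @export
evaluate_slides <- function(dets, gts, cfg = eval_config(),
                            pooled = FALSE) {
  if (!("slide" %in% names(gts)) || !("slide" %in% names(dets))) {
    stop("both tables need a `slide` column", call. = FALSE)
  }
  if (pooled) {
    res <- evaluate_detections(dets, gts, cfg)
    return(list(per_slide = list(pooled = res), aggregate = res))
  }
  slides <- sort(unique(c(dets$slide, gts$slide)))
  per_slide <- lapply(slides, function(s) {
    evaluate_detections(dets[dets$slide == s, , drop = FALSE],
                        gts[gts$slide == s, , drop = FALSE], cfg)
  })
  names(per_slide) <- slides
  with_gt <- vapply(per_slide, function(r) r$n_gt > 0, logical(1))
  if (!any(with_gt)) {
    agg <- per_slide[[1]]
  } else {
    use <- per_slide[with_gt]
    avg <- function(f) mean(vapply(use, `[[`, numeric(1), f))
    ap <- rowMeans(vapply(use, `[[`, numeric(length(cfg$iou_thresholds)),
                          "ap_by_threshold"))
    agg <- structure(list(
      ap_by_threshold = ap,
      map_50 = avg("map_50"), map_75 = avg("map_75"),
      map_50_95 = avg("map_50_95"),
      average_recall = avg("average_recall"),
      n_gt = sum(vapply(use, `[[`, integer(1), "n_gt")),
      n_dets = sum(vapply(per_slide, `[[`, integer(1), "n_dets")),
      defined = TRUE), class = "eval_result")
  }
  list(per_slide = per_slide, aggregate = agg)
}

#' Write an evaluation report CSV
#'
#' One row per slide plus an `aggregate` row; columns for each
#' threshold's AP and the summary fields.
#'
#' @param eval A result of [evaluate_slides()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  rows <- c(eval$per_slide, list(aggregate = eval$aggregate))
  th_names <- names(rows[[1]]$ap_by_threshold)
  tab <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    data.frame(slide = nm,
               as.list(setNames(round(r$ap_by_threshold, 6),
                                paste0("ap_", th_names))),
               map_50 = round(r$map_50, 6), map_75 = round(r$map_75, 6),
               map_50_95 = round(r$map_50_95, 6),
               average_recall = round(r$average_recall, 6),
               n_gt = r$n_gt, n_dets = r$n_dets,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
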