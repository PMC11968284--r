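#' Fusion configuration
#'
#' Thresholds and options for the weighted circle fusion (WCF) ensemble.
#' Defaults follow the detection plugin's published operating point: a
#' fused detection needs consensus from at least two models
#' (`t_count = 2`) and a fused confidence of at least 0.9
#' (`t_score = 0.9`).
#'
#' @param t_iou Clustering threshold in (0, 1): a detection joins a
#'   cluster when its circle IoU with the cluster's current fused circle
#'   exceeds `t_iou`. Default 0.5.
#' @param t_count Minimum number of distinct supporting models
#'   (integer >= 1). Default 2.
#' @param t_score Minimum fused (averaged) confidence in \[0, 1\].
#'   Default 0.9.
#' @param drop_below_count If `TRUE` (default) clusters supported by
#'   fewer than `t_count` distinct models are discarded; turn off to keep
#'   them for count-colored review.
#' @param weighting `"score"` (default): member geometry is averaged with
#'   confidence weights; `"uniform"`: plain mean.
#' @param fused_score `"mean"` (default): fused confidence is the
#'   arithmetic mean of member scores; `"weighted"`: score-weighted mean.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(t_iou = 0.5, t_count = 2L, t_score = 0.9,
                          drop_below_count = TRUE,
                          weighting = c("score", "uniform"),
                          fused_score = c("mean", "weighted")) {
  if (!is.numeric(t_iou) || length(t_iou) != 1 || t_iou <= 0 || t_iou >= 1) {
    stop("t_iou must be a single value in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(t_count) || length(t_count) != 1 || t_count < 1 ||
      t_count != round(t_count)) {
    stop("t_count must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(t_score) || length(t_score) != 1 || t_score < 0 ||
      t_score > 1) {
    stop("t_score must be a single value in [0, 1]", call. = FALSE)
  }
  structure(list(t_iou = t_iou, t_count = as.integer(t_count),
                 t_score = t_score,
                 drop_below_count = isTRUE(drop_below_count),
                 weighting = match.arg(weighting),
                 fused_score = match.arg(fused_score)),
            class = "fusion_config")
}

#' Weighted circle fusion across a model ensemble
#'
#' WCF merges the outputs of several detection models into one refined
#' detection set: overlapping circles from different models are clustered
#' and each cluster is collapsed to a single confidence-weighted circle,
#' then clusters are filtered by how many distinct models support them
#' and by the fused confidence.
#'
#' Procedure: (1) pool every model's detections and sort by descending
#' score (deterministic tie-break); (2) assign each detection to the
#' first existing cluster whose *current fused circle* has IoU greater
#' than `t_iou` with it, else open a new cluster; (3) a cluster's fused
#' geometry is the weighted average of its members' `(cx, cy, r)` with
#' member scores as weights (or uniform weights), recomputed as members
#' join; (4) the fused score is the arithmetic mean of member scores;
#' (5) clusters supported by fewer than `t_count` distinct models are
#' dropped (when `drop_below_count`); (6) clusters with fused score below
#' `t_score` are dropped. Survivors are returned by descending fused
#' score.
#'
#' Each model's list is assumed internally deduplicated (NMS applied
#' upstream) and all circles must share one global frame.
#'
#' @param per_model_dets Named list mapping `model_id` to a scored circle
#'   table; a model with zero detections is valid, an empty list is not.
#' @param cfg A [fusion_config()].
#' @return A fused-circle table: columns `cx`, `cy`, `r`, `score` (the
#'   fused confidence), `category`, `model_count` (distinct supporting
#'   models), `n_members`, plus a `members` list-column holding each
#'   cluster's contributing detections.
#' @export
wcf <- function(per_model_dets, cfg = fusion_config()) {
  if (!is.list(per_model_dets) || length(per_model_dets) == 0L) {
    stop("per_model_dets must be a non-empty list of detection tables",
         call. = FALSE)
  }
  ids <- names(per_model_dets)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- paste0("model_", seq_along(per_model_dets))
  }
  pooled <- do.call(rbind, lapply(seq_along(per_model_dets), function(i) {
    d <- per_model_dets[[i]]
    validate_circles(d, scored = nrow(d) > 0)
    if (nrow(d) == 0L) return(NULL)
    d$model_id <- ids[i]
    d[, c("cx", "cy", "r", "score", "model_id", "category")]
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(fused_circles_empty())
  }
  pooled <- pooled[order_by_score(pooled), , drop = FALSE]
  rownames(pooled) <- NULL

  n <- nrow(pooled)
  cluster_of <- integer(n)
  # running fused geometry per cluster, grown as members join
  fcx <- numeric(0); fcy <- numeric(0); fr <- numeric(0)
  wsum <- numeric(0); ssum <- numeric(0); msize <- integer(0)
  wxs <- numeric(0); wys <- numeric(0); wrs <- numeric(0)

  for (i in seq_len(n)) {
    assigned <- 0L
    if (length(fcx)) {
      iou <- circle_iou(pooled$cx[i], pooled$cy[i], pooled$r[i],
                        fcx, fcy, fr)
      hit <- which(iou > cfg$t_iou)
      if (length(hit)) assigned <- hit[1L]  # first existing cluster
    }
    w <- if (cfg$weighting == "score") pooled$score[i] else 1
    if (assigned == 0L) {
      fcx <- c(fcx, pooled$cx[i]); fcy <- c(fcy, pooled$cy[i])
      fr <- c(fr, pooled$r[i])
      wxs <- c(wxs, w * pooled$cx[i]); wys <- c(wys, w * pooled$cy[i])
      wrs <- c(wrs, w * pooled$r[i])
      wsum <- c(wsum, w); ssum <- c(ssum, pooled$score[i])
      msize <- c(msize, 1L)
      assigned <- length(fcx)
    } else {
      k <- assigned
      wxs[k] <- wxs[k] + w * pooled$cx[i]
      wys[k] <- wys[k] + w * pooled$cy[i]
      wrs[k] <- wrs[k] + w * pooled$r[i]
      wsum[k] <- wsum[k] + w
      ssum[k] <- ssum[k] + pooled$score[i]
      msize[k] <- msize[k] + 1L
      fcx[k] <- wxs[k] / wsum[k]
      fcy[k] <- wys[k] / wsum[k]
      fr[k] <- wrs[k] / wsum[k]
    }
    cluster_of[i] <- assigned
  }

  k <- length(fcx)
  members <- split(pooled, factor(cluster_of, levels = seq_len(k)))
  model_count <- vapply(members, function(m) length(unique(m$model_id)),
                        integer(1))
  fused_score <- if (cfg$fused_score == "mean") {
    ssum / msize
  } else {
    vapply(members, function(m) sum(m$score^2) / sum(m$score), numeric(1))
  }
  category <- vapply(members, function(m) m$category[1L], character(1))

  out <- data.frame(cx = fcx, cy = fcy, r = fr, score = fused_score,
                    model_count = as.integer(model_count),
                    n_members = msize, category = category,
                    stringsAsFactors = FALSE)
  out$members <- unname(members)

  keep <- rep(TRUE, k)
  if (cfg$drop_below_count) keep <- keep & out$model_count >= cfg$t_count
  keep <- keep & out$score >= cfg$t_score
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$score, out$cx, out$cy, out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

fused_circles_empty <- function() {
  out <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                    score = numeric(0), model_count = integer(0),
                    n_members = integer(0), category = character(0),
                    stringsAsFactors = FALSE)
  out$members <- list()
  out
}

#' Partition fused circles by supporting-model count
#'
#' Groups fused detections into named categories `"fused_k"` by the
#' number of distinct models that supported each one — the grouping used
#' to color-code results for review, so a reader can focus on
#' low-consensus detections, which are more likely to be wrong.
#'
#' @param fused A fused-circle table from [wcf()].
#' @return A named list mapping `"fused_k"` to the rows with
#'   `model_count == k`; groups are disjoint and their union is the
#'   input. Empty input gives an empty list.
#' @export
categorize_by_count <- function(fused) {
  if (nrow(fused) == 0L) return(setNames(list(), character(0)))
  counts <- sort(unique(fused$model_count))
  out <- lapply(counts, function(k) {
    g <- fused[fused$model_count == k, , drop = FALSE]
    rownames(g) <- NULL
    g
  })
  names(out) <- paste0("fused_", counts)
  out
}
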