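# Independent reference implementations used as oracles. These follow
# the stated procedures literally (explicit loops, no shared code with
# the package internals) so agreement is meaningful.

# random scored circle sets with deliberate overlap structure: a few
# cluster sites, several jittered circles per site, plus scattered
# singletons
random_det_set <- function(n, extent = 2000, r_lo = 5, r_hi = 100) {
  n_sites <- max(1L, round(n / 4))
  sx <- runif(n_sites, 0, extent)
  sy <- runif(n_sites, 0, extent)
  site <- sample.int(n_sites, n, replace = TRUE)
  r <- runif(n, r_lo, r_hi)
  circles(
    cx = sx[site] + rnorm(n, 0, 15),
    cy = sy[site] + rnorm(n, 0, 15),
    r = r,
    score = runif(n),
    model_id = "m"
  )
}

iou_one <- function(a, b) {
  circle_iou(a$cx, a$cy, a$r, b$cx, b$cy, b$r)
}

# brute-force hard NMS: explicit O(n^2) double loop
nms_reference <- function(dets, iou_threshold = 0.5) {
  ord <- order(-dets$score, dets$cx, dets$cy, dets$r)
  d <- dets[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (k in kept) {
      if (iou_one(d[i, ], d[k, ]) > iou_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  d[kept, , drop = FALSE]
}

# loop-following Soft-NMS: pop max, decay, drop below floor
soft_nms_reference <- function(dets, sigma = 0.5, score_floor = 0.001) {
  ord <- order(-dets$score, dets$cx, dets$cy, dets$r)
  d <- dets[ord, , drop = FALSE]
  rownames(d) <- NULL
  s <- d$score
  live <- seq_len(nrow(d))
  out_idx <- integer(0)
  out_score <- numeric(0)
  while (length(live)) {
    best <- live[which.max(s[live])]
    out_idx <- c(out_idx, best)
    out_score <- c(out_score, s[best])
    live <- live[live != best]
    drop <- logical(length(live))
    for (j in seq_along(live)) {
      iou <- iou_one(d[best, ], d[live[j], ])
      s[live[j]] <- s[live[j]] * exp(-iou^2 / sigma)
      if (s[live[j]] < score_floor) drop[j] <- TRUE
    }
    live <- live[!drop]
  }
  res <- d[out_idx, , drop = FALSE]
  res$score <- out_score
  rownames(res) <- NULL
  res
}

# literal step-by-step weighted circle fusion
wcf_reference <- function(per_model, t_iou = 0.5, t_count = 2,
                          t_score = 0.9, drop_below_count = TRUE,
                          weighting = "score") {
  pooled <- NULL
  for (m in names(per_model)) {
    d <- per_model[[m]]
    if (!nrow(d)) next
    d$model_id <- m
    pooled <- rbind(pooled, d[, c("cx", "cy", "r", "score", "model_id")])
  }
  if (is.null(pooled)) return(list(clusters = list(), fused = NULL))
  pooled <- pooled[order(-pooled$score, pooled$cx, pooled$cy, pooled$r), ]
  rownames(pooled) <- NULL
  clusters <- list()  # member row indices into pooled
  fused <- list()     # c(cx, cy, r)
  for (i in seq_len(nrow(pooled))) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      iou <- circle_iou(pooled$cx[i], pooled$cy[i], pooled$r[i],
                        fused[[k]][1], fused[[k]][2], fused[[k]][3])
      if (iou > t_iou) {
        clusters[[k]] <- c(clusters[[k]], i)
        mem <- pooled[clusters[[k]], ]
        w <- if (weighting == "score") mem$score else rep(1, nrow(mem))
        fused[[k]] <- c(sum(w * mem$cx) / sum(w),
                        sum(w * mem$cy) / sum(w),
                        sum(w * mem$r) / sum(w))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- i
      fused[[length(fused) + 1L]] <- c(pooled$cx[i], pooled$cy[i],
                                       pooled$r[i])
    }
  }
  tab <- data.frame(
    cx = vapply(fused, `[`, numeric(1), 1),
    cy = vapply(fused, `[`, numeric(1), 2),
    r = vapply(fused, `[`, numeric(1), 3),
    score = vapply(clusters, function(idx) mean(pooled$score[idx]),
                   numeric(1)),
    model_count = vapply(clusters, function(idx) {
      length(unique(pooled$model_id[idx]))
    }, integer(1))
  )
  keep <- rep(TRUE, nrow(tab))
  if (drop_below_count) keep <- keep & tab$model_count >= t_count
  keep <- keep & tab$score >= t_score
  list(pooled = pooled, clusters = clusters,
       fused = tab[keep, , drop = FALSE])
}

# exhaustive greedy matcher following the stated protocol
match_reference <- function(dets, gts, thr) {
  ord <- order(-dets$score, dets$cx, dets$cy, dets$r)
  d <- dets[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    best <- 0L
    best_iou <- -1
    for (g in seq_len(nrow(gts))) {
      if (taken[g]) next
      iou <- iou_one(d[i, ], gts[g, ])
      if (iou >= thr && iou > best_iou) {
        best <- g
        best_iou <- iou
      }
    }
    if (best > 0L) {
      tp[i] <- TRUE
      taken[best] <- TRUE
    }
  }
  list(tp = tp, gt_matched = taken)
}

# direct 101-point AP: max precision at each sampled recall level
ap101_reference <- function(tp, n_gt) {
  if (n_gt == 0) return(if (length(tp)) 0 else NA_real_)
  ctp <- cumsum(tp)
  prec <- ctp / seq_along(tp)
  rec <- ctp / n_gt
  vals <- vapply(seq(0, 1, by = 0.01), function(g) {
    at <- which(rec >= g)
    if (length(at)) max(prec[seq(min(at), length(prec))]) else 0
  }, numeric(1))
  mean(vals)
}

# 90-degree rotation about a point, image convention
rotate90 <- function(df, a, b) {
  out <- df
  out$cx <- a + (df$cy - b)
  out$cy <- b - (df$cx - a)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small noise-free simulation config for end-to-end identities
noise_free_config <- function(seed = 11L, n_gt = 25L, n_models = 5L) {
  sim_config(width = 2048L, height = 2048L, n_gt = n_gt,
             radius_range = c(30, 80), min_separation = 200,
             n_models = n_models, p_detect = 1, center_jitter_sd = 0,
             radius_jitter_sd = 0, fp_per_megapixel = 0, seed = seed)
}
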