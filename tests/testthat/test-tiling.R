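test_that("make_tiles produces the half-overlap grid with edge anchoring", {
  t9 <- make_tiles(slide_meta(1024, 1024), 512, 256)
  expect_equal(nrow(t9), 9L)
  expect_setequal(unique(t9$x0), c(0L, 256L, 512L))
  expect_setequal(unique(t9$y0), c(0L, 256L, 512L))

  t4 <- make_tiles(slide_meta(700, 700), 512, 256)
  expect_equal(nrow(t4), 4L)
  expect_setequal(unique(t4$x0), c(0L, 188L))

  t1 <- make_tiles(slide_meta(512, 512), 512, 256)
  expect_equal(nrow(t1), 1L)
  expect_equal(c(t1$x0, t1$y0), c(0L, 0L))

  expect_error(make_tiles(slide_meta(300, 300), 512), "smaller than patch")
  expect_error(make_tiles(slide_meta(1024, 1024), 512, 0), "stride")
})

test_that("tiling covers every pixel; interiors are 4-covered at half overlap", {
  # dimensions that are stride multiples: the grid is regular, no
  # edge-anchored extra row/column, so the interior 4-cover is exact
  slide <- slide_meta(1280, 1536)
  tiles <- make_tiles(slide, 512, 256)
  # coverage count on a pixel grid (sampled every pixel on a band, plus
  # corners, is prohibitive; use an exact integer sweep on a coarse
  # lattice aligned to stride boundaries plus off-lattice probes)
  px <- c(0:10, seq(0, slide$width - 1, by = 7), slide$width - 1)
  py <- c(0:10, seq(0, slide$height - 1, by = 7), slide$height - 1)
  cover_x <- vapply(px, function(x) {
    sum(x >= tiles$x0 & x < tiles$x0 + tiles$size & tiles$y0 == 0)
  }, numeric(1))
  expect_true(all(cover_x >= 1))
  # full 2-D coverage and interior 4-cover
  probe <- expand.grid(x = seq(3, slide$width - 4, by = 97),
                       y = seq(3, slide$height - 4, by = 89))
  cover <- mapply(function(x, y) {
    sum(x >= tiles$x0 & x < tiles$x0 + tiles$size &
          y >= tiles$y0 & y < tiles$y0 + tiles$size)
  }, probe$x, probe$y)
  expect_true(all(cover >= 1))
  interior <- probe$x >= 256 & probe$x < slide$width - 256 &
    probe$y >= 256 & probe$y < slide$height - 256
  expect_true(all(cover[interior] == 4))
})

test_that("a small circle well inside the slide fits entirely in some patch", {
  slide <- slide_meta(2048, 2048)
  tiles <- make_tiles(slide, 512, 256)
  set.seed(8)
  for (i in 1:50) {
    r <- runif(1, 10, 127)  # diameter < patch / 2
    cx <- runif(1, r, slide$width - r)
    cy <- runif(1, r, slide$height - r)
    contained <- any(cx - r >= tiles$x0 & cx + r <= tiles$x0 + tiles$size &
                       cy - r >= tiles$y0 & cy + r <= tiles$y0 + tiles$size)
    expect_true(contained)
  }
})

test_that("local/global coordinate mapping is an exact inverse pair", {
  patch <- list(x0 = 512L, y0 = 256L, size = 512L)
  local <- circles(10.5, 20.0, 7, score = 0.5)
  glob <- to_global(local, patch)
  expect_equal(glob$cx, 522.5)
  expect_equal(glob$cy, 276.0)
  expect_equal(glob$r, 7)
  expect_equal(glob$score, 0.5)
  # origin (0,0) is the identity
  expect_equal(to_global(local, list(x0 = 0L, y0 = 0L, size = 512L)),
               local)
  # exact round trip
  back <- to_local(glob, patch)
  expect_identical(back$cx, local$cx)
  expect_identical(back$cy, local$cy)
  # centers outside the window warn but are kept
  expect_warning(out <- to_global(circles(600, 10, 5, score = 0.1), patch),
                 "outside")
  expect_equal(nrow(out), 1L)
})

test_that("the pipeline collapses cross-patch duplicates and finds boundary objects", {
  # one ground-truth circle centered exactly on a patch boundary
  slide <- slide_meta(1024, 1024)
  gt <- circles(512, 512, 40)
  fused <- run_pipeline(slide, list(perfect_detector(gt, "m1"),
                                    perfect_detector(gt, "m2")),
                        fusion_cfg = fusion_config(t_score = 0))
  expect_equal(nrow(fused), 1L)
  expect_equal(fused$cx, 512)
  expect_equal(fused$cy, 512)
  expect_equal(fused$r, 40)
  expect_equal(fused$model_count, 2L)
})

test_that("five identical perfect detectors yield full-consensus ground truth", {
  cfg <- noise_free_config(seed = 21L, n_gt = 20L)
  gt <- generate_ground_truth(cfg)
  dets <- lapply(1:5, function(m) perfect_detector(gt, paste0("m", m)))
  fused <- run_pipeline(slide_meta(cfg$width, cfg$height), dets)
  expect_equal(nrow(fused), nrow(gt))
  expect_true(all(fused$model_count == 5L))
  ord_f <- order(fused$cx, fused$cy)
  ord_g <- order(gt$cx, gt$cy)
  expect_equal(fused$cx[ord_f], gt$cx[ord_g])
  expect_equal(fused$cy[ord_f], gt$cy[ord_g])
  expect_equal(fused$r[ord_f], gt$r[ord_g])
})

test_that("pipeline equals the manual stage composition on a noisy benchmark", {
  cfg <- sim_config(width = 2048L, height = 2048L, n_gt = 30L,
                    min_separation = 200, seed = 99L)
  bench <- make_ensemble_benchmark(cfg)
  detectors <- lapply(names(bench$per_model), function(nm) {
    detector_from_detections(bench$per_model[[nm]], nm)
  })
  fused <- run_pipeline(slide_meta(cfg$width, cfg$height), detectors,
                        fusion_cfg = fusion_config(t_score = 0))
  # manual composition: tile -> detect -> to_global -> per-model NMS -> wcf
  tiles <- make_tiles(slide_meta(cfg$width, cfg$height), 512, 256)
  per_model <- lapply(detectors, function(det) {
    pooled <- do.call(rbind, lapply(seq_len(nrow(tiles)), function(t) {
      to_global(det$detect(tiles[t, ]), tiles[t, ])
    }))
    nms(pooled, suppression_config())
  })
  names(per_model) <- vapply(detectors, `[[`, character(1), "model_id")
  manual <- wcf(per_model, fusion_config(t_score = 0))
  expect_equal(fused[, c("cx", "cy", "r", "score", "model_count")],
               manual[, c("cx", "cy", "r", "score", "model_count")])
})

test_that("a failing detector loses only its own patches", {
  slide <- slide_meta(1024, 1024)
  gt <- circles(c(300, 800), c(300, 800), 40)
  flaky <- structure(list(
    model_id = "flaky",
    detect = function(patch) {
      if (patch$x0 == 0 && patch$y0 == 0) stop("corrupt tile")
      inside <- gt$cx >= patch$x0 & gt$cx < patch$x0 + patch$size &
        gt$cy >= patch$y0 & gt$cy < patch$y0 + patch$size
      d <- gt[inside, , drop = FALSE]
      d$score <- rep(1, nrow(d))
      to_local(d, patch)
    }), class = "detector")
  expect_warning(
    fused <- run_pipeline(slide, list(flaky, perfect_detector(gt, "ok")),
                          fusion_cfg = fusion_config(t_score = 0,
                                                     t_count = 1,
                                                     drop_below_count = FALSE)),
    "failures")
  # both objects still found (the (300,300) one via other covering patches)
  expect_equal(nrow(fused), 2L)
  summary <- attr(fused, "pipeline_summary")
  expect_equal(unname(summary$patch_failures["flaky"]), 1L)
})
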