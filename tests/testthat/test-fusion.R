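test_that("single-model detections are dropped under the consensus default", {
  one <- list(model_1 = circles(100, 100, 30, score = 0.99))
  fused <- wcf(one)  # defaults: t_count 2, drop_below_count on
  expect_equal(nrow(fused), 0L)
  # but retrievable with the consensus filter off
  kept <- wcf(one, fusion_config(t_count = 1, t_score = 0))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$model_count, 1L)
  expect_error(wcf(list()), "non-empty")
})

test_that("fused geometry and score follow the weighted-mean arithmetic", {
  # symmetric pair: equal scores and radii -> midpoint center
  pm <- list(
    a = circles(0, 0, 10, score = 0.8),
    b = circles(4, 0, 10, score = 0.8)
  )
  f <- wcf(pm, fusion_config(t_score = 0))
  expect_equal(nrow(f), 1L)
  expect_equal(f$cx, 2)
  expect_equal(f$cy, 0)
  expect_equal(f$r, 10)
  expect_equal(f$score, 0.8)
  expect_equal(f$model_count, 2L)
  # asymmetric scores: cx = (0*0.6 + 4*0.2) / 0.8 = 1, score = mean = 0.4
  pm <- list(
    a = circles(0, 0, 10, score = 0.6),
    b = circles(4, 0, 10, score = 0.2)
  )
  f <- wcf(pm, fusion_config(t_score = 0))
  expect_equal(f$cx, 1)
  expect_equal(f$score, 0.4)
  # uniform weighting puts the center at the plain midpoint instead
  f_u <- wcf(pm, fusion_config(t_score = 0, weighting = "uniform"))
  expect_equal(f_u$cx, 2)
})

test_that("wcf matches the literal step-by-step reference on random ensembles", {
  set.seed(303)
  for (rep in 1:20) {
    pm <- lapply(1:5, function(m) {
      nms(random_det_set(sample(5:50, 1)))
    })
    names(pm) <- paste0("model_", 1:5)
    for (cfgs in list(list(t_count = 2, t_score = 0.9),
                      list(t_count = 1, t_score = 0))) {
      got <- wcf(pm, fusion_config(t_iou = 0.5, t_count = cfgs$t_count,
                                   t_score = cfgs$t_score))
      want <- wcf_reference(pm, t_iou = 0.5, t_count = cfgs$t_count,
                            t_score = cfgs$t_score)$fused
      want <- want[order(-want$score, want$cx, want$cy, want$r), ,
                   drop = FALSE]
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$cx, want$cx, tolerance = 1e-12)
      expect_equal(got$cy, want$cy, tolerance = 1e-12)
      expect_equal(got$r, want$r, tolerance = 1e-12)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      expect_equal(got$model_count, want$model_count)
    }
  }
})

test_that("with filters off every input detection lands in exactly one cluster", {
  set.seed(404)
  for (rep in 1:10) {
    pm <- lapply(1:4, function(m) nms(random_det_set(30)))
    names(pm) <- paste0("model_", 1:4)
    f <- wcf(pm, fusion_config(t_count = 1, t_score = 0,
                               drop_below_count = FALSE))
    n_in <- sum(vapply(pm, nrow, integer(1)))
    expect_equal(sum(f$n_members), n_in)
    members <- do.call(rbind, f$members)
    key <- function(d) paste(d$cx, d$cy, d$r, d$score, d$model_id)
    expect_setequal(key(members),
                    key(do.call(rbind, lapply(names(pm), function(m) {
                      d <- pm[[m]]; d$model_id <- m; d
                    }))))
    expect_equal(nrow(members), n_in)  # no duplication either
  }
})

test_that("consensus filtering leaves no single-model clusters", {
  set.seed(505)
  for (rep in 1:20) {
    pm <- lapply(1:5, function(m) nms(random_det_set(sample(10:40, 1))))
    names(pm) <- paste0("model_", 1:5)
    f <- wcf(pm, fusion_config(t_count = 2, t_score = 0))
    if (nrow(f)) {
      expect_true(all(f$model_count >= 2))
      single <- vapply(f$members, function(m) {
        length(unique(m$model_id)) == 1L
      }, logical(1))
      expect_false(any(single))
    }
  }
})

test_that("wcf output is invariant to within-model input permutations", {
  set.seed(606)
  pm <- lapply(1:3, function(m) nms(random_det_set(40)))
  names(pm) <- paste0("model_", 1:3)
  f1 <- wcf(pm, fusion_config(t_count = 1, t_score = 0))
  pm_shuffled <- lapply(pm, function(d) d[sample.int(nrow(d)), ])
  f2 <- wcf(pm_shuffled, fusion_config(t_count = 1, t_score = 0))
  expect_equal(f1[, c("cx", "cy", "r", "score", "model_count")],
               f2[, c("cx", "cy", "r", "score", "model_count")])
})

test_that("fused score stays within the member score range", {
  set.seed(707)
  pm <- lapply(1:5, function(m) nms(random_det_set(40)))
  names(pm) <- paste0("model_", 1:5)
  f <- wcf(pm, fusion_config(t_count = 1, t_score = 0))
  for (i in seq_len(nrow(f))) {
    expect_gte(f$score[i], min(f$members[[i]]$score))
    expect_lte(f$score[i], max(f$members[[i]]$score))
  }
})

test_that("categorize_by_count partitions by distinct-model support", {
  f <- wcf(list(a = circles(c(0, 500), c(0, 0), 20, score = 0.95),
                b = circles(c(1, 501), c(0, 0), 20, score = 0.94),
                c = circles(0, 0, 20, score = 0.93)),
           fusion_config(t_score = 0))
  groups <- categorize_by_count(f)
  expect_named(groups, c("fused_2", "fused_3"))
  expect_equal(nrow(groups$fused_3), 1L)
  expect_equal(nrow(groups$fused_2), 1L)
  expect_equal(sum(vapply(groups, nrow, integer(1))), nrow(f))
  expect_equal(length(categorize_by_count(f[0, ])), 0L)
})

test_that("fusion_config enforces threshold domains", {
  expect_error(fusion_config(t_iou = 0), "t_iou")
  expect_error(fusion_config(t_count = 0), "t_count")
  expect_error(fusion_config(t_score = 1.2), "t_score")
  cfg <- fusion_config()
  expect_equal(cfg$t_count, 2L)
  expect_equal(cfg$t_score, 0.9)
})
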