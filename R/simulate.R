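#' Synthetic benchmark configuration
#'
#' Full parameterization of a virtual slide with ground-truth circles
#' and an ensemble of noisy circle detectors. The defaults emulate the
#' operating regime of a five-model glomerulus ensemble on one
#' whole-slide image: on the order of a hundred well-separated
#' glomerulus-sized objects, detectors that find 90% of them with a few
#' pixels of localization jitter, sparse low-confidence false positives,
#' and true-positive confidences concentrated near the top of the scale
#' so the 0.9 fused-confidence gate is meaningful.
#'
#' @param width,height Virtual slide size in pixels (default 4096).
#' @param n_gt Number of ground-truth circles (default 120).
#' @param radius_range Min/max ground-truth radius in pixels
#'   (default `c(30, 90)`; small enough that any object fits well inside
#'   a 512-pixel patch).
#' @param min_separation Minimum center distance between ground-truth
#'   circles in pixels (default 220, so objects never overlap —
#'   mirroring glomerular anatomy).
#' @param n_models Ensemble size (default 5).
#' @param p_detect Per-model probability of detecting each ground-truth
#'   circle (default 0.9).
#' @param center_jitter_sd Isotropic Gaussian localization error of a
#'   detected center, in pixels (default 3).
#' @param radius_jitter_sd Relative radius error: the detected radius is
#'   the true one scaled by `1 + N(0, radius_jitter_sd)` (default 0.05).
#' @param fp_per_megapixel Expected false positives per megapixel per
#'   model (default 2).
#' @param tp_score_params,fp_score_params Beta shape parameters
#'   `c(shape1, shape2)` for true-positive and false-positive
#'   confidences. Defaults: `c(40, 2.5)` for true positives (mean about
#'   0.94, so the 0.9 fused-confidence gate bites) and `c(0.45, 0.85)`
#'   for false positives (mean 0.35, mass piled near 0 but with the
#'   heavy high tail of hard negatives that real detector confidences
#'   show - about 7% of false positives score above 0.9).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(width = 4096L, height = 4096L, n_gt = 120L,
                       radius_range = c(30, 90), min_separation = 220,
                       n_models = 5L, p_detect = 0.9,
                       center_jitter_sd = 3, radius_jitter_sd = 0.05,
                       fp_per_megapixel = 2,
                       tp_score_params = c(40, 2.5),
                       fp_score_params = c(0.45, 0.85),
                       seed = 1L) {
  if (p_detect < 0 || p_detect > 1) {
    stop("p_detect must lie in [0, 1]", call. = FALSE)
  }
  if (length(radius_range) != 2 || radius_range[1] <= 0 ||
      radius_range[2] < radius_range[1]) {
    stop("radius_range must be 0 < min <= max", call. = FALSE)
  }
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (fp_per_megapixel < 0) {
    stop("fp_per_megapixel must be >= 0", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_gt = as.integer(n_gt),
                 radius_range = as.numeric(radius_range),
                 min_separation = as.numeric(min_separation),
                 n_models = as.integer(n_models),
                 p_detect = p_detect,
                 center_jitter_sd = center_jitter_sd,
                 radius_jitter_sd = radius_jitter_sd,
                 fp_per_megapixel = fp_per_megapixel,
                 tp_score_params = as.numeric(tp_score_params),
                 fp_score_params = as.numeric(fp_score_params),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Independent per-model seed: a small integer hash of (seed, stream) so
# adding a model never perturbs other models' streams. Kept < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807 + 12345) %%
    2147483647
}

#' Generate ground-truth circles on a virtual slide
#'
#' Radii uniform in `radius_range`; centers uniform over the slide with
#' every circle fully inside the bounds and all pairwise center
#' distances at least `min_separation`, enforced by bounded rejection
#' sampling. Deterministic at a fixed config seed.
#'
#' @param cfg A [sim_config()].
#' @return An unscored circle table (slide-global frame).
#' @export
generate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 0))
  if (cfg$n_gt == 0L) return(empty_circles())
  rmax <- cfg$radius_range[2]
  cx <- numeric(0); cy <- numeric(0); r <- numeric(0)
  attempts <- 0L
  max_attempts <- 1000L * cfg$n_gt
  while (length(cx) < cfg$n_gt && attempts < max_attempts) {
    attempts <- attempts + 1L
    ri <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
    xi <- stats::runif(1, rmax, cfg$width - rmax)
    yi <- stats::runif(1, rmax, cfg$height - rmax)
    if (!length(cx) ||
        all((cx - xi)^2 + (cy - yi)^2 >= cfg$min_separation^2)) {
      cx <- c(cx, xi); cy <- c(cy, yi); r <- c(r, ri)
    }
  }
  if (length(cx) < cfg$n_gt) {
    stop("could not place ", cfg$n_gt, " circles with min_separation ",
         cfg$min_separation, " on a ", cfg$width, "x", cfg$height,
         " slide; use fewer or smaller circles", call. = FALSE)
  }
  circles(cx, cy, r)
}

#' Simulate one noisy detector over a ground-truth set
#'
#' Each ground-truth circle is detected independently with probability
#' `p_detect`; a detected copy gets isotropic Gaussian center jitter
#' (`center_jitter_sd` pixels), multiplicative radius jitter
#' (`1 + N(0, radius_jitter_sd)`), and a confidence drawn from the
#' true-positive Beta distribution. False positives arrive as a Poisson
#' count at `fp_per_megapixel`, with uniform random geometry and
#' confidences from the false-positive Beta. Each model uses its own
#' hash-derived RNG substream, so results per model are independent and
#' stable under ensemble-size changes.
#'
#' @param gt Ground-truth circle table.
#' @param cfg A [sim_config()].
#' @param model_index Which ensemble member (1-based).
#' @param seed Base seed; default the config seed.
#' @return A scored circle table with `model_id = "model_<index>"`.
#' @export
simulate_detector <- function(gt, cfg, model_index, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_circles(gt)
  set.seed(derive_seed(seed, model_index))
  n <- nrow(gt)
  detected <- if (n) stats::runif(n) < cfg$p_detect else logical(0)
  k <- sum(detected)
  tp <- if (k) {
    circles(
      cx = gt$cx[detected] + stats::rnorm(k, 0, cfg$center_jitter_sd),
      cy = gt$cy[detected] + stats::rnorm(k, 0, cfg$center_jitter_sd),
      r = pmax(1e-6, gt$r[detected] *
                 (1 + stats::rnorm(k, 0, cfg$radius_jitter_sd))),
      score = stats::rbeta(k, cfg$tp_score_params[1],
                           cfg$tp_score_params[2]),
      model_id = paste0("model_", model_index)
    )
  } else {
    empty_circles()
  }
  n_fp <- stats::rpois(1, cfg$fp_per_megapixel *
                         cfg$width * cfg$height / 1e6)
  fp <- if (n_fp) {
    rr <- stats::runif(n_fp, cfg$radius_range[1], cfg$radius_range[2])
    circles(
      cx = stats::runif(n_fp, rr, cfg$width - rr),
      cy = stats::runif(n_fp, rr, cfg$height - rr),
      r = rr,
      score = stats::rbeta(n_fp, cfg$fp_score_params[1],
                           cfg$fp_score_params[2]),
      model_id = paste0("model_", model_index)
    )
  } else {
    empty_circles()
  }
  out <- rbind(tp, fp)
  rownames(out) <- NULL
  out
}

#' Build a full synthetic ensemble benchmark
#'
#' One ground-truth set plus `n_models` simulated detector outputs and a
#' manifest recording every parameter and derived seed; byte-for-byte
#' reproducible at a fixed config.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `benchmark`: `gt`, `per_model` (named list of
#'   detection tables), `manifest`.
#' @export
make_ensemble_benchmark <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  gt <- generate_ground_truth(cfg)
  per_model <- lapply(seq_len(cfg$n_models), function(m) {
    simulate_detector(gt, cfg, m)
  })
  names(per_model) <- paste0("model_", seq_len(cfg$n_models))
  manifest <- c(unclass(cfg),
                list(derived_seeds = vapply(0:cfg$n_models, derive_seed,
                                            numeric(1), seed = cfg$seed),
                     n_gt_placed = nrow(gt),
                     n_detections = vapply(per_model, nrow, integer(1))))
  structure(list(gt = gt, per_model = per_model, manifest = manifest),
            class = "benchmark")
}

#' Write a benchmark bundle to disk
#'
#' Ground truth and per-model detections as interchange CSVs plus a YAML
#' manifest of all parameters and seeds.
#'
#' @param bench A [make_ensemble_benchmark()] result.
#' @param dir Output directory (created if missing).
#' @param slide_name Slide identifier written into the CSVs.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir, slide_name = "synthetic_slide") {
  stopifnot(inherits(bench, "benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- bench$gt
  gt$slide <- rep(slide_name, nrow(gt))
  write_detections_csv(gt, file.path(dir, "ground_truth.csv"))
  for (nm in names(bench$per_model)) {
    d <- bench$per_model[[nm]]
    d$slide <- rep(slide_name, nrow(d))
    write_detections_csv(d, file.path(dir, paste0(nm, ".csv")))
  }
  yaml::write_yaml(bench$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a benchmark bundle from disk
#'
#' @param dir Directory written by [write_benchmark()].
#' @return A `benchmark` list (`gt`, `per_model`, `manifest`).
#' @export
read_benchmark <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  gt <- read_detections_csv(file.path(dir, "ground_truth.csv"))
  files <- sort(list.files(dir, pattern = "^model_[0-9]+\\.csv$",
                           full.names = TRUE))
  per_model <- lapply(files, read_detections_csv)
  names(per_model) <- sub("\\.csv$", "", basename(files))
  structure(list(gt = gt, per_model = per_model, manifest = manifest),
            class = "benchmark")
}
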