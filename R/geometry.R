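#' Area of a circle
#'
#' @param r Numeric vector of radii in pixels (> 0).
#' @return Numeric vector of areas in square pixels (`pi * r^2`).
#' @examples
#' circle_area(1)   # pi
#' circle_area(10)  # 100 * pi
#' @export
circle_area <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("invalid geometry: radius must be finite and > 0", call. = FALSE)
  }
  pi * r^2
}

#' Circle intersection-over-union
#'
#' The overlap area of two circles divided by the area of their union —
#' the rotation-invariant analogue of box IoU used throughout the
#' pipeline (suppression, fusion clustering, and evaluation matching).
#' Vectorized over paired inputs.
#'
#' Three regimes: zero when the center distance `d >= r1 + r2` (disjoint
#' or tangent); the area ratio `min(A1, A2) / max(A1, A2)` when one circle
#' contains the other (`d <= |r1 - r2|`); otherwise the circular-lens
#' intersection area over `A1 + A2 - intersection`. `acos` arguments are
#' clamped to \[-1, 1\] so tangency and near-containment survive floating
#' point.
#'
#' @param cx1,cy1,r1 First circle(s): center and radius in pixels.
#' @param cx2,cy2,r2 Second circle(s), recycled against the first.
#' @return Numeric vector of IoU values in \[0, 1\].
#' @examples
#' circle_iou(0, 0, 1, 0, 0, 1)  # identical -> 1
#' circle_iou(0, 0, 1, 2, 0, 1)  # tangent  -> 0
#' circle_iou(0, 0, 1, 0, 0, 2)  # nested   -> 0.25
#' @export
circle_iou <- function(cx1, cy1, r1, cx2, cy2, r2) {
  if (any(!is.finite(c(r1, r2))) || any(r1 <= 0) || any(r2 <= 0)) {
    stop("invalid geometry: radius must be finite and > 0", call. = FALSE)
  }
  n <- max(length(cx1), length(cx2))
  cx1 <- rep_len(cx1, n); cy1 <- rep_len(cy1, n); r1 <- rep_len(r1, n)
  cx2 <- rep_len(cx2, n); cy2 <- rep_len(cy2, n); r2 <- rep_len(r2, n)

  d <- sqrt((cx1 - cx2)^2 + (cy1 - cy2)^2)
  a1 <- pi * r1^2
  a2 <- pi * r2^2

  out <- numeric(n)

  # exact 1 for coincident equal circles, no roundoff below 1
  same <- d == 0 & r1 == r2
  out[same] <- 1

  contained <- !same & d <= abs(r1 - r2)
  if (any(contained)) {
    out[contained] <- pmin(a1, a2)[contained] / pmax(a1, a2)[contained]
  }

  partial <- !same & !contained & d < (r1 + r2)
  if (any(partial)) {
    # canonical radius order makes the result bit-exact symmetric
    dd <- d[partial]
    ra <- pmin(r1, r2)[partial]
    rb <- pmax(r1, r2)[partial]
    clamp <- function(z) pmin(1, pmax(-1, z))
    alpha <- acos(clamp((dd^2 + ra^2 - rb^2) / (2 * dd * ra)))
    beta <- acos(clamp((dd^2 + rb^2 - ra^2) / (2 * dd * rb)))
    tri <- (-dd + ra + rb) * (dd + ra - rb) * (dd - ra + rb) * (dd + ra + rb)
    inter <- ra^2 * alpha + rb^2 * beta - 0.5 * sqrt(pmax(0, tri))
    out[partial] <- inter / (a1[partial] + a2[partial] - inter)
  }
  # disjoint / tangent rows stay 0
  pmin(1, pmax(0, out))
}

#' Pairwise circle IoU matrix
#'
#' IoU between every circle of `a` and every circle of `b`, with no
#' thresholding. Empty inputs give an empty matrix.
#'
#' @param a,b Circle tables (see [circles()]).
#' @return A `nrow(a)` x `nrow(b)` numeric matrix; entry `(i, j)` is
#'   `circle_iou(a[i], b[j])`.
#' @export
pairwise_iou <- function(a, b) {
  validate_circles(a)
  validate_circles(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) {
    return(matrix(numeric(), nrow = na, ncol = nb))
  }
  i <- rep(seq_len(na), times = nb)
  j <- rep(seq_len(nb), each = na)
  matrix(circle_iou(a$cx[i], a$cy[i], a$r[i], b$cx[j], b$cy[j], b$r[j]),
         nrow = na, ncol = nb)
}

#' Monte-Carlo circle IoU estimate
#'
#' Independent stochastic estimate of the circle IoU used to validate the
#' analytic formula: uniform points are thrown over the intersection of
#' the two circles' bounding boxes to estimate the overlap area, and the
#' union is completed analytically from the two exact disc areas. Shares
#' no code path with [circle_iou()].
#'
#' @param cx1,cy1,r1,cx2,cy2,r2 Scalar circle parameters.
#' @param n Number of uniform samples (default 1e7).
#' @param seed Integer seed for the sampler's private RNG stream.
#' @return A scalar IoU estimate in \[0, 1\].
#' @export
circle_iou_mc <- function(cx1, cy1, r1, cx2, cy2, r2, n = 1e7,
                          seed = 1L) {
  if (r1 <= 0 || r2 <= 0) {
    stop("invalid geometry: radius must be > 0", call. = FALSE)
  }
  mc_circle_iou_cpp(cx1, cy1, r1, cx2, cy2, r2, as.numeric(n),
                    as.integer(seed))
}
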