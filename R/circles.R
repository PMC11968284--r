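#' Build a table of circles
#'
#' Circles are the package's universal currency: a detected or ground-truth
#' object is a center `(cx, cy)` in continuous 0-based pixel coordinates
#' (x rightward, y downward), a strictly positive radius `r`, an optional confidence
#' `score` in \[0, 1\] (absent, i.e. `NA`, for ground truth), an optional
#' `model_id` recording which detector produced it, and a free-text
#' `category` label. The coordinate frame (patch-local vs slide-global) is
#' bookkeeping carried by the containing collection, never by the circle.
#'
#' @param cx,cy Numeric vectors, center coordinates in pixels.
#' @param r Numeric vector of radii in pixels, strictly positive.
#' @param score Numeric vector of confidences in \[0, 1\], or `NA` for
#'   unscored (ground-truth) circles. Recycled to length.
#' @param model_id Character vector of model labels, or `NA`. Recycled.
#' @param category Character class label, default `"glomerulus"`. Recycled.
#' @return A `data.frame` with columns `cx`, `cy`, `r`, `score`,
#'   `model_id`, `category`.
#' @examples
#' circles(cx = c(10, 40), cy = c(10, 40), r = 5, score = c(0.9, 0.8))
#' @export
circles <- function(cx = numeric(), cy = numeric(), r = numeric(),
                    score = NA_real_, model_id = NA_character_,
                    category = "glomerulus") {
  n <- length(cx)
  if ((length(cy) != n && length(cy) != 1L) ||
      (length(r) != n && length(r) != 1L)) {
    stop("`cy` and `r` must match the length of `cx` (or be scalar)",
         call. = FALSE)
  }
  out <- data.frame(
    cx = as.numeric(cx),
    cy = rep_len(as.numeric(cy), n),
    r = rep_len(as.numeric(r), n),
    score = rep_len(as.numeric(score), n),
    model_id = rep_len(as.character(model_id), n),
    category = rep_len(as.character(category), n),
    stringsAsFactors = FALSE
  )
  validate_circles(out)
  out
}

#' Validate a circle table
#'
#' Checks the structural invariants: required columns present, radii
#' strictly positive, scores (where present) within \[0, 1\]. Called by
#' every operation that consumes circles; exposed for use at I/O
#' boundaries.
#'
#' @param x A data.frame of circles (see [circles()]).
#' @param scored If `TRUE`, additionally require a non-missing score on
#'   every row (suppression and fusion need scores).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_circles <- function(x, scored = FALSE) {
  if (!is.data.frame(x)) {
    stop("circle set must be a data.frame", call. = FALSE)
  }
  needed <- c("cx", "cy", "r")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("circle set is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x)) {
    if (any(!is.finite(x$r)) || any(x$r <= 0)) {
      stop("invalid geometry: all radii must be finite and > 0",
           call. = FALSE)
    }
    if (any(!is.finite(x$cx)) || any(!is.finite(x$cy))) {
      stop("invalid geometry: centers must be finite", call. = FALSE)
    }
    if ("score" %in% names(x)) {
      sc <- x$score[!is.na(x$score)]
      if (length(sc) && (any(sc < 0) || any(sc > 1))) {
        stop("scores must lie in [0, 1]", call. = FALSE)
      }
    }
    if (scored) {
      if (!("score" %in% names(x)) || anyNA(x$score)) {
        stop("invalid input: every circle must carry a score",
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

# Deterministic ordering used everywhere a score ranking is needed:
# score descending, ties broken by (cx, cy, r) ascending so that any
# permutation of the input rows yields the same processing order.
order_by_score <- function(x) {
  order(-x$score, x$cx, x$cy, x$r)
}

empty_circles <- function() {
  circles()
}
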