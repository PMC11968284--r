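#' Slide metadata
#'
#' Width/height in pixels and a name identifying a (virtual or real)
#' whole-slide image; the pipeline only ever needs dimensions, never
#' pixel data.
#'
#' @param width,height Positive integer pixel extents.
#' @param name Identifier, default `"slide"`.
#' @return A list of class `slide_meta`.
#' @export
slide_meta <- function(width, height, name = "slide") {
  if (!is.numeric(width) || !is.numeric(height) ||
      length(width) != 1 || length(height) != 1 ||
      width <= 0 || height <= 0 ||
      width != round(width) || height != round(height)) {
    stop("width and height must be positive integers", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 name = as.character(name)),
            class = "slide_meta")
}

# Per-axis patch origins: k * stride while the patch still fits, plus a
# final origin anchored at extent - patch when the last regular patch
# does not reach the edge. Guarantees full coverage of [0, extent).
axis_origins <- function(extent, patch, stride) {
  ks <- 0:floor((extent - patch) / stride)
  origins <- ks * stride
  if (max(origins) + patch < extent) {
    origins <- c(origins, extent - patch)
  }
  as.integer(origins)
}

#' Half-overlap tiling of a slide
#'
#' Covers the slide with square patches laid on a regular grid with the
#' given stride (default half the patch side, i.e. each patch overlaps
#' its neighbours by half its area), with a final row/column anchored at
#' the slide edge so no pixel is missed. Patch windows are half-open
#' `[x0, x0 + size) x [y0, y0 + size)` with integer origins.
#'
#' @param slide A [slide_meta()].
#' @param patch Patch side length in pixels, default 512.
#' @param stride Grid stride in pixels, default `patch / 2`.
#' @return A data.frame of patch specs: `x0`, `y0`, `size`.
#' @examples
#' make_tiles(slide_meta(1024, 1024), 512, 256)  # 3 x 3 = 9 patches
#' @export
make_tiles <- function(slide, patch = 512L, stride = patch / 2) {
  stopifnot(inherits(slide, "slide_meta"))
  patch <- as.integer(patch)
  stride <- as.integer(stride)
  if (patch <= 0 || stride <= 0 || stride > patch) {
    stop("need 0 < stride <= patch", call. = FALSE)
  }
  if (slide$width < patch || slide$height < patch) {
    stop("slide smaller than patch size; pad upstream or use a smaller ",
         "patch", call. = FALSE)
  }
  xs <- axis_origins(slide$width, patch, stride)
  ys <- axis_origins(slide$height, patch, stride)
  grid <- expand.grid(x0 = xs, y0 = ys, KEEP.OUT.ATTRS = FALSE)
  grid$size <- patch
  grid
}

#' Map a patch-local circle to the slide frame
#'
#' Adds the patch origin to the center coordinates; radius, score and
#' model id are untouched. A local center outside the patch window
#' `[0, size)` raises a warning but is kept — detections hanging over a
#' patch edge are legitimate.
#'
#' @param local Circle table in patch-local coordinates.
#' @param patch One row of a [make_tiles()] table (or a list with
#'   `x0`, `y0`, `size`).
#' @return The same circles in slide-global coordinates.
#' @export
to_global <- function(local, patch) {
  validate_circles(local)
  if (nrow(local) == 0L) return(local)
  outside <- local$cx < 0 | local$cx >= patch$size |
    local$cy < 0 | local$cy >= patch$size
  if (any(outside)) {
    warning(sum(outside), " detection center(s) outside the patch ",
            "window; kept", call. = FALSE)
  }
  local$cx <- local$cx + patch$x0
  local$cy <- local$cy + patch$y0
  local
}

#' Map a slide-global circle into a patch frame
#'
#' Exact inverse of [to_global()].
#'
#' @inheritParams to_global
#' @param global Circle table in slide-global coordinates.
#' @export
to_local <- function(global, patch) {
  validate_circles(global)
  global$cx <- global$cx - patch$x0
  global$cy <- global$cy - patch$y0
  global
}
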