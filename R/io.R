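#' Color palette keyed by supporting-model count
#'
#' Distinct RGB colors for the consensus-count categories `fused_1` ...
#' `fused_n`, used as the `classification` color in exported GeoJSON so
#' an annotation viewer renders low-consensus detections (the likeliest
#' errors) in their own color.
#'
#' @param n_models Ensemble size, default 5.
#' @return Named list mapping count `"k"` to an integer RGB triple.
#' @export
count_palette <- function(n_models = 5L) {
  base <- list(
    c(230L, 25L, 75L),   # red
    c(245L, 130L, 48L),  # orange
    c(255L, 225L, 25L),  # yellow
    c(60L, 180L, 75L),   # green
    c(0L, 130L, 200L),   # blue
    c(145L, 30L, 180L),  # purple
    c(70L, 240L, 240L),  # cyan
    c(240L, 50L, 230L)   # magenta
  )
  if (n_models > length(base)) {
    extra <- lapply(seq_len(n_models - length(base)), function(i) {
      as.integer((c(37, 91, 151) * i * 53) %% 256)
    })
    base <- c(base, extra)
  }
  setNames(base[seq_len(n_models)], as.character(seq_len(n_models)))
}

circle_ring <- function(cx, cy, r, n_vertices = 64L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ring <- cbind(cx + r * cos(theta), cy + r * sin(theta))
  rbind(ring, ring[1L, , drop = FALSE])  # closed
}

#' Write fused circles as QuPath-style GeoJSON
#'
#' Emits an RFC 7946 `FeatureCollection`. Each circle becomes a `Polygon`
#' feature whose ring is a closed, counterclockwise regular 64-gon
#' (65 coordinate pairs) approximating the circle — the target annotation
#' dialect has no native circle geometry — while the exact `cx`, `cy`,
#' `r`, `score` and `model_count` are duplicated in the feature
#' properties so a round trip is lossless. Properties also carry
#' `objectType: "annotation"` and a `classification` block naming the
#' consensus category `fused_k` with its palette color.
#'
#' Coordinates are pixels; a microns-per-pixel scale, if known, belongs
#' in downstream metadata and is never silently applied.
#'
#' @param fused Fused-circle table ([wcf()] output, or any circle table
#'   with `score`; missing `model_count` is treated as 1).
#' @param path Output file path.
#' @param palette Palette from [count_palette()].
#' @return `path`, invisibly.
#' @export
write_geojson <- function(fused, path, palette = count_palette()) {
  validate_circles(fused)
  model_count <- if ("model_count" %in% names(fused)) {
    fused$model_count
  } else {
    rep(1L, nrow(fused))
  }
  features <- lapply(seq_len(nrow(fused)), function(i) {
    k <- as.character(model_count[i])
    color <- palette[[k]]
    if (is.null(color)) color <- c(128L, 128L, 128L)
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list({
          ring <- circle_ring(fused$cx[i], fused$cy[i], fused$r[i])
          lapply(seq_len(nrow(ring)), function(v) c(ring[v, 1L], ring[v, 2L]))
        })
      ),
      properties = list(
        objectType = "annotation",
        classification = list(name = paste0("fused_", k),
                              color = as.integer(color)),
        cx = fused$cx[i], cy = fused$cy[i], r = fused$r[i],
        score = if (!is.null(fused$score)) fused$score[i] else NULL,
        model_count = as.integer(model_count[i])
      )
    )
  })
  doc <- list(type = "FeatureCollection", features = features)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write GeoJSON to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  invisible(path)
}

# Least-squares (Kasa) circle fit to ring vertices; used when a feature
# carries only a polygon (e.g. edited externally) and no exact circle
# properties.
fit_circle <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  a <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(a, b)
  cx <- sol[1L]; cy <- sol[2L]
  r <- sqrt(sol[3L] + cx^2 + cy^2)
  c(cx = cx, cy = cy, r = r)
}

#' Read fused circles from GeoJSON
#'
#' Inverse of [write_geojson()]: exact `cx`/`cy`/`r` properties are
#' preferred; a feature carrying only a polygon gets a least-squares
#' circle fit to its ring. A classification name of the form `fused_k`
#' is parsed back into `model_count`. Malformed features are skipped
#' with a warning reporting how many.
#'
#' @param path A GeoJSON `FeatureCollection` file.
#' @return A fused-circle table (`cx`, `cy`, `r`, `score`,
#'   `model_count`, `category`).
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  skipped <- 0L
  rows <- lapply(doc$features, function(f) {
    out <- tryCatch({
      p <- f$properties
      if (!is.null(p$cx) && !is.null(p$cy) && !is.null(p$r)) {
        cx <- as.numeric(p$cx); cy <- as.numeric(p$cy)
        r <- as.numeric(p$r)
      } else {
        ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                      function(v) as.numeric(v[1:2])))
        fit <- fit_circle(ring)
        cx <- fit[["cx"]]; cy <- fit[["cy"]]; r <- fit[["r"]]
      }
      score <- if (!is.null(p$score)) as.numeric(p$score) else NA_real_
      mc <- if (!is.null(p$model_count)) {
        as.integer(p$model_count)
      } else if (!is.null(p$classification$name) &&
                 grepl("^fused_[0-9]+$", p$classification$name)) {
        as.integer(sub("^fused_", "", p$classification$name))
      } else {
        NA_integer_
      }
      data.frame(cx = cx, cy = cy, r = r, score = score,
                 model_count = mc, category = "glomerulus",
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    out
  })
  bad <- vapply(rows, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " malformed feature(s) skipped", call. = FALSE)
  }
  rows <- rows[!bad]
  if (!length(rows)) {
    return(data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                      score = numeric(0), model_count = integer(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

csv_schema <- c("slide", "model_id", "cx", "cy", "r", "score")

#' Write a detection table as CSV
#'
#' Plain interchange format with header
#' `slide,model_id,cx,cy,r,score`; floats are serialized with six
#' decimals. Lossless at that precision; an empty table writes a
#' header-only file.
#'
#' @param dets Circle table; a missing `slide`/`model_id` column is
#'   filled with `"slide"` / `NA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(dets, path) {
  validate_circles(dets)
  tab <- data.frame(
    slide = if ("slide" %in% names(dets)) dets$slide else
      rep("slide", nrow(dets)),
    model_id = if ("model_id" %in% names(dets)) dets$model_id else
      rep(NA_character_, nrow(dets)),
    cx = sprintf("%.6f", dets$cx),
    cy = sprintf("%.6f", dets$cy),
    r = sprintf("%.6f", dets$r),
    score = ifelse(is.na(dets$score), "",
                   sprintf("%.6f", dets$score)),
    stringsAsFactors = FALSE
  )
  if (nrow(dets) == 0L) {
    tab <- tab[0, , drop = FALSE]
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a detection table from CSV
#'
#' @param path CSV with header `slide,model_id,cx,cy,r,score`.
#' @return A circle table with `slide` and `model_id` columns.
#' @export
read_detections_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(csv_schema, names(tab))
  if (length(missing_cols)) {
    stop("detection CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$cx <- as.numeric(tab$cx)
  tab$cy <- as.numeric(tab$cy)
  tab$r <- as.numeric(tab$r)
  tab$score[!is.na(tab$score) & tab$score == ""] <- NA_character_
  tab$score <- as.numeric(tab$score)
  tab$category <- rep("glomerulus", nrow(tab))
  validate_circles(tab)
  tab
}
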