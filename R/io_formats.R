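#' Parse a "YYYY-MM-DD-HH-MM-SS" timestamp token out of a filename
#'
#' Image frames carry their acquisition time in the filename, e.g.
#' `"box3_2025-03-01-12-30-00.jpg"`. The first such token is extracted with a
#' regular expression and parsed as a calendar date-time in UTC.
#'
#' @param filename character vector of filenames (or bare tokens).
#' @return a `POSIXct` vector (UTC), one element per filename.
#' @examples
#' parse_timestamp("box3_2025-03-01-12-30-00.jpg")
#' @export
parse_timestamp <- function(filename) {
  stopifnot(is.character(filename))
  tok <- regmatches(
    filename,
    regexpr("\\d{4}-\\d{2}-\\d{2}-\\d{2}-\\d{2}-\\d{2}", filename)
  )
  bad <- !grepl("\\d{4}-\\d{2}-\\d{2}-\\d{2}-\\d{2}-\\d{2}", filename)
  if (any(bad)) {
    stop("no YYYY-MM-DD-HH-MM-SS timestamp token in: ",
         paste(filename[bad], collapse = ", "))
  }
  ts <- as.POSIXct(strptime(tok, "%Y-%m-%d-%H-%M-%S", tz = "UTC"))
  if (anyNA(ts)) {
    stop("malformed timestamp token in: ",
         paste(filename[is.na(ts)], collapse = ", "))
  }
  ts
}

#' Elapsed time between two timestamps, in fractional hours
#'
#' @param from,to `POSIXct` timestamps (vectors recycle).
#' @return numeric hours, `to - from`.
#' @export
interval_hours <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

#' Format a timestamp back into the filename token
#' @param time `POSIXct`.
#' @return character "YYYY-MM-DD-HH-MM-SS".
#' @export
format_timestamp <- function(time) {
  format(time, "%Y-%m-%d-%H-%M-%S", tz = "UTC")
}

## ---- polygon records ------------------------------------------------------

# Coordinate convention used throughout: 0-based, origin at the top-left
# corner, x rightward, y downward. Pixel (x, y) covers the unit square
# [x, x+1) x [y, y+1); its centre is (x+0.5, y+0.5). A pixel belongs to a
# polygon's raster when its centre lies inside the polygon (even-odd rule).

#' Convert pixel-coordinate polygons to normalized annotation lines
#'
#' Produces the one-instance-per-line segmentation TXT dialect: a class id
#' followed by alternating normalized x, y vertex coordinates (x divided by
#' image width, y by height). Vertices outside the image rectangle are
#' clipped to it with a warning; polygons with fewer than 3 vertices are
#' rejected.
#'
#' @param polygons list of n x 2 numeric matrices (pixel coordinates).
#' @param image_width,image_height image dimensions in pixels.
#' @param class_id single non-negative integer class label (default 0; the
#'   pipeline is single-class, "leaf").
#' @param digits decimal places written per coordinate.
#' @return character vector, one TXT line per polygon.
#' @export
polygons_to_txt_lines <- function(polygons, image_width, image_height,
                                  class_id = 0L, digits = 6L) {
  stopifnot(image_width > 0, image_height > 0)
  if (is.matrix(polygons)) polygons <- list(polygons)
  vapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop("degenerate polygon at index ", i, ": need >= 3 (x, y) vertices")
    }
    if (any(p[, 1] < 0 | p[, 1] > image_width |
            p[, 2] < 0 | p[, 2] > image_height)) {
      warning("polygon ", i, " has out-of-bounds vertices; clipping to image")
      p[, 1] <- pmin(pmax(p[, 1], 0), image_width)
      p[, 2] <- pmin(pmax(p[, 2], 0), image_height)
    }
    xy <- rbind(p[, 1] / image_width, p[, 2] / image_height)
    paste(c(format(as.integer(class_id)),
            sprintf(paste0("%.", digits, "f"), as.vector(xy))),
          collapse = " ")
  }, character(1))
}

#' Parse normalized segmentation TXT lines
#'
#' Inverse of [polygons_to_txt_lines()]: each line is a class id followed by
#' at least six normalized coordinate values (three vertices).
#'
#' @param lines character vector of TXT lines.
#' @return list of polygon records, each `list(class_id, vertices)` with
#'   `vertices` an n x 2 matrix of normalized coordinates in `[0, 1]`.
#' @export
parse_txt_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    f <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    if (length(f) < 7 || length(f) %% 2 == 0) {
      stop("line ", i, ": expected class id + >= 6 coordinate values ",
           "(even count)")
    }
    v <- matrix(f[-1], ncol = 2, byrow = TRUE)
    if (any(v < 0 | v > 1)) {
      stop("line ", i, ": normalized coordinates outside [0, 1]")
    }
    list(class_id = as.integer(f[1]), vertices = v)
  })
}

#' Read / write polygon TXT files
#' @param path file path.
#' @rdname polygon_txt
#' @return `read_polygon_txt()`: a list of polygon records (see
#'   [parse_txt_lines()]).
#' @export
read_polygon_txt <- function(path) parse_txt_lines(readLines(path))

#' @param lines character lines from [polygons_to_txt_lines()].
#' @rdname polygon_txt
#' @export
write_polygon_txt <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Read an ISAT-style per-image polygon annotation document (JSON)
#'
#' ISAT-style documents carry image metadata under `info` (`width`,
#' `height`) and one object per instance under `objects`, each with a
#' `segmentation` list of `[x, y]` pixel-coordinate vertices.
#'
#' @param path path to the JSON document.
#' @return `list(width, height, polygons)` where `polygons` is a list of
#'   n x 2 pixel-coordinate matrices (one per annotated instance).
#' @export
read_isat_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(doc$info$width) || is.null(doc$info$height)) {
    stop("ISAT document missing info$width / info$height: ", path)
  }
  segs <- doc$objects$segmentation
  polys <- lapply(segs, function(s) {
    m <- if (is.matrix(s)) s else do.call(rbind, s)
    storage.mode(m) <- "double"
    m
  })
  list(width = as.integer(doc$info$width),
       height = as.integer(doc$info$height),
       polygons = polys)
}

## ---- rasterization --------------------------------------------------------

#' Rasterize a polygon into a binary mask
#'
#' Scan-line fill under the even-odd rule: a pixel is foreground when its
#' centre `(x + 0.5, y + 0.5)` lies inside the polygon.
#'
#' @param vertices n x 2 matrix of pixel coordinates (0-based, x then y).
#' @param width,height raster dimensions in pixels.
#' @return integer mask matrix (`height` rows, `width` cols), values 0/255.
#' @export
rasterize_polygon <- function(vertices, width, height) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3,
            width >= 1, height >= 1)
  m <- matrix(0L, nrow = height, ncol = width)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  nx <- c(vx[-1], vx[1]); ny <- c(vy[-1], vy[1])
  ymin <- max(0L, floor(min(vy) - 0.5))
  ymax <- min(height - 1L, ceiling(max(vy)))
  if (ymax < ymin) return(m)
  for (y in ymin:ymax) {
    yc <- y + 0.5
    cross <- (vy > yc) != (ny > yc)
    if (!any(cross)) next
    xs <- sort(vx[cross] + (yc - vy[cross]) * (nx[cross] - vx[cross]) /
                 (ny[cross] - vy[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      x0 <- max(0L, ceiling(xs[k] - 0.5))
      x1 <- min(width - 1L, ceiling(xs[k + 1] - 0.5) - 1L)
      if (x1 >= x0) m[y + 1L, (x0 + 1L):(x1 + 1L)] <- 255L
    }
  }
  m
}

#' Assemble a frame observation from polygon records or mask rasters
#'
#' Builds the per-frame container the tracking and phenotyping stages
#' consume: one [instance_mask()] per detected leaf, in input order.
#'
#' @param x either a list of polygon records (as from
#'   [read_polygon_txt()]; normalized coordinates are scaled by the image
#'   size and rasterized with interiors filled), a list of binary mask
#'   matrices, or a character vector of mask raster file paths.
#' @param image_size `c(width, height)` in pixels.
#' @param time optional `POSIXct` frame time (or a filename to parse).
#' @return a `frame_observation`: `list(time, dim = c(height, width),
#'   instances)`.
#' @export
load_instances <- function(x, image_size, time = NULL) {
  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  stopifnot(w > 0, h > 0)
  if (is.character(time)) time <- parse_timestamp(time)
  instances <-
    if (is.character(x)) {
      lapply(x, function(p) {
        m <- read_mask_image(p)
        if (nrow(m) != h || ncol(m) != w) {
          stop("raster ", p, " is ", ncol(m), "x", nrow(m),
               " but declared image size is ", w, "x", h)
        }
        instance_mask(m)
      })
    } else if (length(x) == 0) {
      list()
    } else if (is.list(x[[1]]) && !is.null(x[[1]]$vertices)) {
      lapply(x, function(rec) {
        v <- rec$vertices
        v[, 1] <- v[, 1] * w
        v[, 2] <- v[, 2] * h
        instance_mask(rasterize_polygon(v, w, h))
      })
    } else {
      lapply(x, function(m) {
        if (nrow(m) != h || ncol(m) != w) {
          stop("mask is ", ncol(m), "x", nrow(m),
               " but declared image size is ", w, "x", h)
        }
        instance_mask(m)
      })
    }
  structure(list(time = time, dim = c(h, w), instances = instances),
            class = "frame_observation")
}

#' @export
print.frame_observation <- function(x, ...) {
  cat("frame_observation:", length(x$instances), "instance(s),",
      x$dim[2], "x", x$dim[1], "px",
      if (!is.null(x$time)) paste0("@ ", format_timestamp(x$time)), "\n")
  invisible(x)
}

## ---- raster file IO -------------------------------------------------------

#' Read a mask raster file as a binary matrix
#'
#' Grayscale JPG/PNG are thresholded at mid-range so values land in
#' \{0, 255\}; colour images are averaged to grayscale first.
#'
#' @param path image file path.
#' @return integer matrix (rows = height), values 0/255.
#' @export
read_mask_image <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  m <- matrix(0L, nrow = ncol(img), ncol = nrow(img))
  m[t(img) > 0.5] <- 255L
  m
}

#' Write a binary mask matrix as a grayscale raster file
#'
#' @param mask integer/numeric matrix, values 0/255 (rows = height).
#' @param path output path; format from the extension (`.png`, `.jpg`).
#' @export
write_mask_image <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask) / 255), path)
  invisible(path)
}

#' Write the per-leaf results table
#'
#' Fixed column order and fixed floating-point formatting so identical runs
#' produce byte-identical files.
#'
#' @param df data frame with columns `frame_time` (`POSIXct`), `leaf_id`,
#'   `cx`, `cy`, `pixel_count`, `area_mm2`, `growth_rate_mm2_per_h`.
#' @param path output CSV path.
#' @export
write_results_csv <- function(df, path) {
  cols <- c("frame_time", "leaf_id", "cx", "cy", "pixel_count",
            "area_mm2", "growth_rate_mm2_per_h")
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  out <- df[cols]
  out$frame_time <- format_timestamp(out$frame_time)
  for (cc in c("cx", "cy", "area_mm2", "growth_rate_mm2_per_h")) {
    out[[cc]] <- sprintf("%.6f", out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
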