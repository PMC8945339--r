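#' Define a region of interest
#'
#' ROIs carry a `role` that tells the pipeline what to do with them:
#' `"tail"` regions are tracked, the `"axis"` line measures the resting cell
#' length L0, `"signal"` and `"background"` rectangles feed fluorescence
#' extraction. Rectangles use 0-based `(row, col)` coordinates and are
#' half-open: a rectangle covers rows `[row0, row0 + height)` and columns
#' `[col0, col0 + width)`. Line endpoints may be sub-pixel.
#'
#' @param label text label; used in error messages and output tables.
#' @param role one of `"tail"`, `"axis"`, `"signal"`, `"background"`.
#' @param rect for rectangular roles, numeric `c(row0, col0, height, width)`.
#' @param line for `role = "axis"`, numeric 2x2 matrix, one endpoint
#'   `(row, col)` per row.
#'
#' @return An object of class `roi_spec`.
#' @export
#' @examples
#' roi_spec("tail1", "tail", rect = c(10, 5, 20, 12))
#' roi_spec("axis1", "axis", line = rbind(c(32, 10), c(32, 110)))
roi_spec <- function(label, role, rect = NULL, line = NULL) {
  role <- match.arg(role, c("tail", "axis", "signal", "background"))
  if (role == "axis") {
    if (is.null(line)) abort_input(sprintf("ROI '%s': role 'axis' requires line geometry", label))
    line <- matrix(as.numeric(line), nrow = 2L)
    if (all(line[1L, ] == line[2L, ]))
      abort_input(sprintf("ROI '%s': line endpoints must be distinct", label))
    geom <- list(type = "line", line = line)
  } else {
    if (is.null(rect)) abort_input(sprintf("ROI '%s': role '%s' requires rectangle geometry", label, role))
    rect <- as.numeric(rect)
    if (length(rect) != 4L || rect[3L] < 1 || rect[4L] < 1)
      abort_input(sprintf("ROI '%s': rectangle must be (row0, col0, height, width) with positive size", label))
    geom <- list(type = "rect", rect = rect)
  }
  structure(list(label = as.character(label), role = role, geometry = geom),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  g <- x$geometry
  desc <- if (g$type == "rect")
    sprintf("rect [%g,%g) x [%g,%g)", g$rect[1L], g$rect[1L] + g$rect[3L],
            g$rect[2L], g$rect[2L] + g$rect[4L])
  else
    sprintf("line (%g,%g)-(%g,%g)", g$line[1L, 1L], g$line[1L, 2L],
            g$line[2L, 1L], g$line[2L, 2L])
  cat(sprintf("<roi_spec> '%s' role=%s %s\n", x$label, x$role, desc))
  invisible(x)
}

roi_center <- function(roi) {
  g <- roi$geometry
  if (g$type == "rect")
    c(g$rect[1L] + g$rect[3L] / 2, g$rect[2L] + g$rect[4L] / 2)
  else
    colMeans(g$line)
}

# validate a single ROI against frame bounds (height, width)
validate_roi_bounds <- function(roi, frame_shape) {
  g <- roi$geometry
  h <- frame_shape[1L]; w <- frame_shape[2L]
  ok <- if (g$type == "rect") {
    r <- g$rect
    r[1L] >= 0 && r[2L] >= 0 && r[1L] + r[3L] <= h && r[2L] + r[4L] <= w
  } else {
    all(g$line[, 1L] >= 0) && all(g$line[, 1L] <= h - 1) &&
      all(g$line[, 2L] >= 0) && all(g$line[, 2L] <= w - 1)
  }
  if (!ok)
    abort_input(sprintf("ROI '%s' extends outside the %d x %d frame", roi$label, h, w))
  invisible(roi)
}

# extract the pixel block of a rectangular ROI from one frame (1-based array)
roi_pixels <- function(stack, roi, frame) {
  g <- roi$geometry
  if (g$type != "rect") abort_input(sprintf("ROI '%s' is not rectangular", roi$label))
  r <- round(g$rect)
  stack$pixels[frame, (r[1L] + 1L):(r[1L] + r[3L]), (r[2L] + 1L):(r[2L] + r[4L])]
}

#' Read ROI definitions from disk
#'
#' Supports the package's JSON dialect (see [write_rois()]), single ImageJ
#' `.roi` files and ImageJ `.zip` ROI archives. ImageJ ROIs carry no role
#' metadata, so roles are inferred from the ROI name by prefix, case
#' insensitively: `tail*`, `axis*`, `signal*`, `bg*` (or `background*`). The
#' JSON dialect stores roles explicitly.
#'
#' For `.zip` archives the ROI name is the archive entry name; for a single
#' `.roi` file it is the file's base name.
#'
#' @param path path to a `.json`, `.roi` or `.zip` file.
#' @param frame_shape integer `c(height, width)`; every ROI is validated
#'   against these bounds.
#'
#' @return A list of [roi_spec()] objects.
#' @export
read_rois <- function(path, frame_shape) {
  if (!file.exists(path)) abort_input(sprintf("ROI file not found: %s", path))
  rois <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_rois_json(path)
  } else if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    list(read_imagej_roi(path, sub("\\.roi$", "", basename(path), ignore.case = TRUE)))
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    read_imagej_zip(path)
  } else {
    abort_input(sprintf("unrecognised ROI container: %s (expected .json, .roi or .zip)", path))
  }
  for (roi in rois) validate_roi_bounds(roi, frame_shape)
  rois
}

#' Write ROI definitions as JSON
#'
#' The JSON dialect is a top-level object `{"rois": [...]}` where each entry
#' has `label`, `role`, and either `rect` (`{"row0":..,"col0":..,"height":..,
#' "width":..}`) or `line` (`{"from":[row,col],"to":[row,col]}`). Coordinates
#' follow the package convention: 0-based, row first, rectangles half-open.
#'
#' @param rois list of [roi_spec()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  entries <- lapply(rois, function(roi) {
    g <- roi$geometry
    e <- list(label = roi$label, role = roi$role)
    if (g$type == "rect") {
      r <- g$rect
      e$rect <- list(row0 = r[1L], col0 = r[2L], height = r[3L], width = r[4L])
    } else {
      e$line <- list(from = g$line[1L, ], to = g$line[2L, ])
    }
    e
  })
  jsonlite::write_json(list(rois = entries), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_rois_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$rois)) abort_input(sprintf("'%s': no top-level \"rois\" array", path))
  lapply(doc$rois, function(e) {
    label <- e$label %||% "(unnamed)"
    role <- e$role %||% abort_input(sprintf("ROI '%s': missing role", label))
    if (!role %in% c("tail", "axis", "signal", "background"))
      abort_input(sprintf("ROI '%s': unknown role '%s'", label, role))
    if (!is.null(e$rect)) {
      r <- e$rect
      roi_spec(label, role, rect = c(r$row0, r$col0, r$height, r$width))
    } else if (!is.null(e$line)) {
      roi_spec(label, role,
               line = rbind(unlist(e$line$from), unlist(e$line$to)))
    } else {
      abort_input(sprintf("ROI '%s': needs either \"rect\" or \"line\" geometry", label))
    }
  })
}

# role from ImageJ ROI name prefix, case-insensitive
role_from_name <- function(name) {
  low <- tolower(name)
  if (startsWith(low, "tail")) return("tail")
  if (startsWith(low, "axis")) return("axis")
  if (startsWith(low, "signal")) return("signal")
  if (startsWith(low, "bg") || startsWith(low, "background")) return("background")
  abort_input(sprintf(
    "cannot infer a role for ImageJ ROI '%s' (expected prefix tail/axis/signal/bg)", name))
}

# Minimal ImageJ .roi binary reader: rectangles (type 1) and straight lines
# (type 3). The format is big-endian; bounds live at byte offsets 8..15 as
# shorts (top, left, bottom, right) and line endpoints at 18..33 as floats
# (x1, y1, x2, y2). ImageJ x is our col, ImageJ y our row; ImageJ rectangles
# are already half-open (width = right - left).
read_imagej_roi <- function(path, name) {
  raw <- readBin(path, "raw", n = file.size(path))
  parse_imagej_roi(raw, name)
}

parse_imagej_roi <- function(raw, name) {
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    abort_input(sprintf("'%s' is not an ImageJ ROI (missing Iout magic)", name))
  type <- as.integer(raw[7L])
  be_short <- function(off) readBin(raw[(off + 1L):(off + 2L)], "integer",
                                    size = 2L, endian = "big")
  be_float <- function(off) readBin(raw[(off + 1L):(off + 4L)], "numeric",
                                    size = 4L, endian = "big")
  role <- role_from_name(name)
  if (type == 1L) {  # rectangle
    top <- be_short(8L); left <- be_short(10L)
    bottom <- be_short(12L); right <- be_short(14L)
    roi_spec(name, role, rect = c(top, left, bottom - top, right - left))
  } else if (type == 3L) {  # straight line
    x1 <- be_float(18L); y1 <- be_float(22L)
    x2 <- be_float(26L); y2 <- be_float(30L)
    roi_spec(name, role, line = rbind(c(y1, x1), c(y2, x2)))
  } else {
    abort_input(sprintf(
      "ImageJ ROI '%s' has unsupported type %d (only rectangles and lines are read)",
      name, type))
  }
}

read_imagej_zip <- function(path) {
  exdir <- tempfile("rois_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = exdir)
  files <- files[grepl("\\.roi$", files, ignore.case = TRUE)]
  if (length(files) == 0L)
    abort_input(sprintf("'%s' contains no .roi entries", path))
  files <- files[order(basename(files))]
  lapply(files, function(f)
    read_imagej_roi(f, sub("\\.roi$", "", basename(f), ignore.case = TRUE)))
}
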