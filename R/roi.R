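# Pleura-anchored region of interest. The upper limit follows a hand-drawn
# (or automatically detected) trace of the pleural surface; the lateral and
# bottom sides are drawn by the computer with square angles while enforcing
# an exactly constant area (50,000 or 100,000 pixels by convention).

#' Pleural line trace
#'
#' An ordered polyline of (row, column) points spanning the traced pleural
#' surface, columns strictly increasing. Coordinates are 1-based matrix
#' indices with row 1 at the skin surface.
#'
#' @param rows,cols numeric vectors of equal length (>= 2)
#' @return object of class `pleural_trace`
#' @export
pleural_trace <- function(rows, cols) {
  stop_if_not(length(rows) == length(cols), "rows and cols must have equal length")
  stop_if_not(length(rows) >= 2, "a trace needs at least 2 points")
  stop_if_not(all(diff(cols) > 0), "trace columns must be strictly increasing")
  stop_if_not(all(is.finite(rows)) && all(is.finite(cols)) && all(rows >= 1) && all(cols >= 1),
              "trace points must be finite and >= 1")
  structure(list(rows = as.numeric(rows), cols = as.numeric(cols)),
            class = "pleural_trace")
}

#' Interpolate a pleural trace to per-column rows
#'
#' Linear interpolation between polyline points; columns outside the traced
#' span carry no trace (and no ROI).
#'
#' @param trace a [pleural_trace()]
#' @return list with integer vector `cols` (spanned columns) and numeric
#'   vector `rows` (interpolated pleural row per column)
#' @export
interpolate_trace <- function(trace) {
  stop_if_not(inherits(trace, "pleural_trace"), "trace must be a pleural_trace")
  cols <- seq(ceiling(trace$cols[1]), floor(trace$cols[length(trace$cols)]))
  rows <- stats::approx(trace$cols, trace$rows, xout = cols, method = "linear")$y
  list(cols = as.integer(cols), rows = rows)
}

#' Build a constant-area ROI below a pleural trace
#'
#' For each spanned column, ROI pixels run from one pixel below the
#' interpolated trace down to a common depth offset `d` (square lateral
#' angles through the trace endpoints). `d` is the smallest depth whose
#' enclosed pixel count reaches `area_target`; the surplus is then trimmed
#' from the deepest layer, rightmost columns first, so the achieved area is
#' exact. Columns whose pleura sits deep may be cut short by the frame
#' bottom; the common depth simply grows until the target is met, which is
#' why two targets built from one trace are nested (the larger ROI adds
#' deeper rows only).
#'
#' @param trace a [pleural_trace()]
#' @param frame_dim frame dimensions `c(rows, cols)` or an [lus_frame()]
#' @param area_target ROI area in pixels (conventionally 50000 or 100000)
#' @return object of class `roi_mask` with fields `mask` (logical matrix),
#'   `area_target`, `achieved_area`
#' @export
build_roi <- function(trace, frame_dim, area_target) {
  if (inherits(frame_dim, "lus_frame")) frame_dim <- dim(frame_dim$pixels)
  stop_if_not(length(frame_dim) == 2 && all(frame_dim >= 1), "frame_dim must be c(rows, cols)")
  stop_if_not(length(area_target) == 1 && area_target > 0 && area_target == round(area_target),
              "area_target must be a positive integer")
  nr <- frame_dim[1]; nc <- frame_dim[2]
  it <- interpolate_trace(trace)
  stop_if_not(all(it$cols >= 1 & it$cols <= nc), "trace extends beyond frame columns")
  stop_if_not(all(it$rows >= 1 & it$rows <= nr), "trace extends beyond frame rows")

  top <- floor(it$rows) + 1L           # first ROI row: strictly below the trace
  avail <- pmax(0L, nr - top + 1L)     # rows available down to the frame bottom
  capacity <- sum(avail)
  if (area_target > capacity)
    stop("frame too shallow for area_target ", area_target,
         ": at most ", capacity, " pixels available below the trace", call. = FALSE)

  # Smallest common depth d with >= area_target pixels enclosed.
  count_at <- function(d) sum(pmin(d, avail))
  lo <- floor(area_target / length(it$cols))
  d <- max(1L, lo)
  while (count_at(d) < area_target) d <- d + 1L

  mask <- matrix(FALSE, nr, nc)
  depth_col <- pmin(d, avail)
  for (k in seq_along(it$cols)) {
    if (depth_col[k] > 0)
      mask[top[k]:(top[k] + depth_col[k] - 1L), it$cols[k]] <- TRUE
  }
  # Trim the surplus from the deepest layer, rightmost columns first.
  excess <- count_at(d) - area_target
  if (excess > 0) {
    deepest <- which(avail >= d)         # columns that reach layer d
    drop_k <- rev(deepest)[seq_len(excess)]
    for (k in drop_k) mask[top[k] + d - 1L, it$cols[k]] <- FALSE
  }

  structure(list(mask = mask, area_target = as.integer(area_target),
                 achieved_area = sum(mask), depth = d,
                 cols = it$cols, top_rows = top),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> target %d px, achieved %d px, depth %d rows, %d columns\n",
              x$area_target, x$achieved_area, x$depth, length(x$cols)))
  invisible(x)
}

#' Extract ROI pixel values in row-major order
#'
#' @param frame an [lus_frame()] or pixel matrix
#' @param mask an [build_roi()] result or logical matrix of the same shape
#' @return integer vector of gray values, length = mask area
#' @export
extract_pixels <- function(frame, mask) {
  px <- frame_pixels(frame)
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stop_if_not(is.logical(m) && identical(dim(m), dim(px)),
              "mask shape must equal frame shape")
  tp <- t(px)
  tp[t(m)]  # transpose => row-major enumeration
}

#' Automatic pleural trace for synthetic frames
#'
#' Heuristic intended for frames from [generate_frame()]: per column, the
#' brightest row within the superficial third of the frame, smoothed by a
#' moving median, taken as the top edge of the pleural band. Not a clinical
#' pleura detector.
#'
#' @param frame an [lus_frame()] or pixel matrix
#' @param search_fraction fraction of the frame depth (from the top) to
#'   search for the pleural band
#' @param smooth_k moving-median window in columns (odd)
#' @return a [pleural_trace()] with one point per column
#' @export
auto_trace <- function(frame, search_fraction = 1 / 3, smooth_k = 15) {
  px <- frame_pixels(frame)
  depth <- max(2L, floor(nrow(px) * search_fraction))
  band <- px[seq_len(depth), , drop = FALSE]
  rows <- apply(band, 2, which.max)
  rows <- as.numeric(stats::runmed(rows, k = smooth_k))
  pleural_trace(rows = rows, cols = seq_len(ncol(px)))
}

#' Read hand-drawn pleural traces from CSV
#'
#' Expected columns: `frame_path`, `point_index`, `row`, `col`; one polyline
#' per frame path, points ordered by `point_index`.
#'
#' @param path CSV path
#' @return named list of [pleural_trace()], keyed by frame path
#' @export
read_trace_csv <- function(path) {
  stop_if_not(file.exists(path), "no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame_path", "point_index", "row", "col")
  stop_if_not(all(needed %in% names(df)),
              "trace CSV needs columns: ", paste(needed, collapse = ", "))
  lapply(split(df, df$frame_path), function(g) {
    g <- g[order(g$point_index), ]
    pleural_trace(g$row, g$col)
  })
}
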