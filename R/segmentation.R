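#' Segment yeast cells from the cell-wall stain channel
#'
#' Cells are identified from the wall-stain (e.g. conA-Alexa594) channel:
#' Gaussian smoothing, Otsu threshold, morphological closing and hole
#' filling, distance-transform watershed to split touching objects, size
#' filtering, and exclusion of border cells. Every step parameter is
#' exposed. The default area bounds bracket the synthetic radius range and
#' must be set by the user for real data.
#'
#' Border policy: a cell is dropped when its +`border_margin` outward ring
#' would leave the frame, so outside rings of retained cells are always
#' complete.
#'
#' @param wall single-channel 2-D numeric matrix (wall-stain intensities).
#' @param min_area,max_area retained cell area bounds in px^2.
#' @param smooth_sigma Gaussian pre-smoothing sigma in px (0 disables).
#' @param closing_size diameter of the disc used for morphological closing.
#' @param watershed_tolerance minimum object-separating depth passed to the
#'   distance-transform watershed.
#' @param border_margin width in px of the frame band a cell mask must not
#'   enter (default 4, the number of outward rings).
#' @return A `cell_label_map`: list with `labels` (integer matrix,
#'   0 = background, cells relabelled consecutively from 1) and `cells`
#'   (data.frame: `cell_id`, `area`, `cx`, `cy`, bbox `x0,x1,y0,y1`).
#'   A blank image yields an empty map, not an error.
#' @export
segment_cells <- function(wall, min_area = 200, max_area = 5000,
                          smooth_sigma = 2, closing_size = 3,
                          watershed_tolerance = 1, border_margin = 4) {
  if (!is.matrix(wall) || !is.numeric(wall))
    stop("wall must be a 2-D numeric matrix")
  if (min_area >= max_area) stop("min_area must be < max_area")

  img <- wall
  if (smooth_sigma > 0)
    img <- EBImage::gblur(img, sigma = smooth_sigma)
  rng <- range(img)
  if (diff(rng) <= 0) return(empty_label_map(dim(wall)))
  norm <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (closing_size > 1)
    bw <- EBImage::closing(bw, EBImage::makeBrush(closing_size, "disc"))
  bw <- EBImage::fillHull(bw)
  if (!any(bw)) return(empty_label_map(dim(wall)))

  dm <- EBImage::distmap(bw)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance))
  storage.mode(labels) <- "integer"

  nr <- nrow(labels); nc <- ncol(labels)
  keep <- integer(0)
  for (id in sort(unique(labels[labels > 0L]))) {
    px <- which(labels == id, arr.ind = TRUE)
    area <- nrow(px)
    in_band <- any(px[, 1] <= border_margin | px[, 1] > nr - border_margin |
                   px[, 2] <= border_margin | px[, 2] > nc - border_margin)
    if (area >= min_area && area <= max_area && !in_band)
      keep <- c(keep, id)
    else
      labels[labels == id] <- 0L
  }
  # relabel consecutively in scan order of first occurrence
  out <- matrix(0L, nr, nc)
  rows <- list()
  for (j in seq_along(keep)) {
    px <- which(labels == keep[j], arr.ind = TRUE)
    out[px] <- j
    rows[[j]] <- data.frame(cell_id = j, area = nrow(px),
                            cx = mean(px[, 1]), cy = mean(px[, 2]),
                            x0 = min(px[, 1]), x1 = max(px[, 1]),
                            y0 = min(px[, 2]), y1 = max(px[, 2]))
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), area = integer(0), cx = numeric(0),
               cy = numeric(0), x0 = integer(0), x1 = integer(0),
               y0 = integer(0), y1 = integer(0))
  structure(list(labels = out, cells = cells), class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("cell_label_map: %d cells on a %d x %d frame\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

empty_label_map <- function(dims) {
  structure(list(labels = matrix(0L, dims[1], dims[2]),
                 cells = data.frame(cell_id = integer(0), area = integer(0),
                                    cx = numeric(0), cy = numeric(0),
                                    x0 = integer(0), x1 = integer(0),
                                    y0 = integer(0), y1 = integer(0))),
            class = "cell_label_map")
}

#' Build a cell_label_map from an existing label matrix
#'
#' Useful for running downstream stages directly on ground-truth masks.
#' @param labels integer matrix, 0 = background
#' @return a `cell_label_map`
#' @export
as_cell_label_map <- function(labels) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(seq_along(ids), function(j) {
    px <- which(labels == ids[j], arr.ind = TRUE)
    data.frame(cell_id = ids[j], area = nrow(px),
               cx = mean(px[, 1]), cy = mean(px[, 2]),
               x0 = min(px[, 1]), x1 = max(px[, 1]),
               y0 = min(px[, 2]), y1 = max(px[, 2]))
  })
  cells <- if (length(rows)) do.call(rbind, rows) else
    empty_label_map(dim(labels))$cells
  structure(list(labels = labels, cells = cells), class = "cell_label_map")
}
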