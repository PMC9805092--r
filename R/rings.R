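#' Concentric ring decomposition of segmented cells
#'
#' Partition every cell of a label map into signed one-pixel concentric
#' rings relative to the segmented border. Ring coordinate 0 is the
#' outermost ring *inside* the mask (the pixels removed by the first
#' one-pixel erosion), ring -k is the set removed by the (k+1)-th erosion
#' and not the k-th, and the residual interior after `n_in` erosions is the
#' CORE. Outward rings +1 ... +n_out are defined analogously by successive
#' one-pixel dilations into unclaimed background, with pixels claimed by at
#' most one cell (nearest cell wins; exact ties go to the smaller label).
#'
#' Erosion/dilation use a 3x3 cross (4-connected) structuring element by
#' default, the closest isotropic one-pixel peel; a 3x3 square
#' (8-connected) is available via `connectivity = 8`. Pixels outside the
#' image frame count as background, so masks touching the frame erode from
#' the frame side.
#'
#' @param cells a `cell_label_map` (see [segment_cells()]) or an integer
#'   label matrix with 0 = background and cells labelled 1..n.
#' @param n_in number of one-pixel inward rings (default 10, coordinates
#'   0 ... -9); the remainder is the CORE.
#' @param n_out number of one-pixel outward rings (default 4).
#' @param connectivity 4 (cross) or 8 (square) structuring element.
#' @return An object of class `ring_decomposition`: a list with
#'   \describe{
#'     \item{labels}{the input label matrix}
#'     \item{coord}{integer matrix of ring coordinates; `NA` for pixels in
#'       no ring, `-n_in` codes the CORE}
#'     \item{owner}{integer matrix giving the owning cell for every ring
#'       pixel (inward and outward), 0 elsewhere}
#'     \item{counts}{data.frame with columns `cell_id`, `ring`
#'       (coordinate, `-n_in` = CORE), `npix`}
#'     \item{n_in, n_out}{the ring counts used}
#'   }
#'
#' Small cells simply run out: if ring -k is empty so are all deeper rings
#' and the CORE. Inward rings plus CORE exactly tile each cell mask.
#' @export
peel_rings <- function(cells, n_in = 10, n_out = 4, connectivity = 4) {
  labels <- label_matrix(cells)
  if (n_in < 1) stop("n_in must be >= 1")
  if (n_out < 0) stop("n_out must be >= 0")
  kern <- ring_kernel(connectivity)
  nr <- nrow(labels); nc <- ncol(labels)
  coord <- matrix(NA_integer_, nr, nc)
  owner <- matrix(0L, nr, nc)
  ids <- sort(unique(labels[labels > 0L]))

  counts <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    px <- which(labels == id, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1])); r1 <- min(nr, max(px[, 1]))
    c0 <- max(1L, min(px[, 2])); c1 <- min(nc, max(px[, 2]))
    # explicit 1-px zero pad: pixels beyond the frame count as background
    core_sub <- (labels[r0:r1, c0:c1, drop = FALSE] == id) * 1
    sub <- matrix(0, nrow(core_sub) + 2L, ncol(core_sub) + 2L)
    sub[2:(nrow(core_sub) + 1L), 2:(ncol(core_sub) + 1L)] <- core_sub
    depth <- matrix(NA_integer_, nrow(sub), ncol(sub))
    cur <- sub
    for (k in 0:(n_in - 1L)) {
      if (!any(cur > 0)) break
      nxt <- EBImage::erode(cur, kern)
      depth[cur > 0 & !(nxt > 0)] <- -k
      cur <- nxt
    }
    depth[!is.na(cur) & cur > 0] <- -n_in  # CORE
    depth <- depth[2:(nrow(depth) - 1L), 2:(ncol(depth) - 1L), drop = FALSE]
    sel <- !is.na(depth)
    coord[r0:r1, c0:c1][sel] <- depth[sel]
    owner[r0:r1, c0:c1][sel] <- id
    ring_vals <- depth[sel]
    tab <- table(factor(ring_vals, levels = -(0:n_in)))
    counts[[j]] <- data.frame(cell_id = id,
                              ring = -(0:n_in),
                              npix = as.integer(tab))
  }

  if (n_out > 0 && length(ids)) {
    claimed <- labels  # grows by one dilation step at a time
    for (k in seq_len(n_out)) {
      new_owner <- matrix(0L, nr, nc)
      conflict <- matrix(FALSE, nr, nc)
      for (id in ids) {
        cur <- (claimed == id) * 1
        grown <- EBImage::dilate(cur, kern)
        cand <- grown > 0 & claimed == 0L
        hit <- cand & new_owner != 0L
        conflict[hit] <- TRUE
        take <- cand & new_owner == 0L
        new_owner[take] <- id
        # ties: both cells reach the pixel at step k; smaller label (first
        # in the ids loop) keeps it, so nothing to do for `hit` pixels
      }
      sel <- new_owner != 0L
      claimed[sel] <- new_owner[sel]
      coord[sel] <- k
      owner[sel] <- new_owner[sel]
    }
    out_counts <- lapply(ids, function(id) {
      data.frame(cell_id = id, ring = seq_len(n_out),
                 npix = vapply(seq_len(n_out), function(k)
                   sum(owner == id & coord == k, na.rm = TRUE), integer(1)))
    })
    counts <- c(counts, out_counts)
  }

  counts <- do.call(rbind, counts)
  if (is.null(counts))
    counts <- data.frame(cell_id = integer(0), ring = integer(0),
                         npix = integer(0))
  counts <- counts[order(counts$cell_id, -counts$ring), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(labels = labels, coord = coord, owner = owner,
                 counts = counts, n_in = as.integer(n_in),
                 n_out = as.integer(n_out)),
            class = "ring_decomposition")
}

#' @export
print.ring_decomposition <- function(x, ...) {
  n_cells <- length(unique(x$counts$cell_id))
  cat(sprintf("ring_decomposition: %d cells, %d inward rings + CORE, %d outward rings\n",
              n_cells, x$n_in, x$n_out))
  invisible(x)
}

#' Ring coordinate code of the CORE region
#'
#' The CORE (residual interior after `n_in` erosions) is coded as `-n_in`
#' in `coord` matrices and `counts` tables.
#' @param rings a `ring_decomposition`
#' @return integer code
#' @export
core_code <- function(rings) -rings$n_in

#' Logical mask of one (cell, ring) region
#'
#' @param rings a `ring_decomposition`
#' @param cell_id cell label
#' @param ring ring coordinate (`core_code(rings)` for the CORE)
#' @return logical matrix
#' @export
ring_mask <- function(rings, cell_id, ring) {
  rings$owner == cell_id & !is.na(rings$coord) & rings$coord == ring
}

# coerce cell_label_map / Image / matrix to an integer label matrix
label_matrix <- function(cells) {
  if (inherits(cells, "cell_label_map")) return(cells$labels)
  m <- if (inherits(cells, "Image")) EBImage::imageData(cells) else cells
  if (!is.matrix(m)) stop("expected a 2-D label matrix")
  storage.mode(m) <- "integer"
  m
}

ring_kernel <- function(connectivity) {
  if (connectivity == 4) EBImage::makeBrush(3, shape = "diamond")
  else if (connectivity == 8) EBImage::makeBrush(3, shape = "box")
  else stop("connectivity must be 4 or 8")
}
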