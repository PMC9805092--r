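#' Median background intensity of a frame
#'
#' Median over pixels belonging to no cell mask and no outward ring (masks
#' dilated by `n_out` one-pixel steps are excluded), i.e. an area of the
#' image with no cells.
#'
#' @param image 2-D numeric matrix
#' @param cells `cell_label_map` or label matrix
#' @param n_out width in px of the excluded halo around every cell
#' @return scalar ADU
#' @export
estimate_background <- function(image, cells, n_out = 4) {
  labels <- label_matrix(cells)
  if (!all(dim(image) == dim(labels)))
    stop("image and label map must have the same shape")
  excl <- labels > 0L
  if (n_out > 0 && any(excl)) {
    kern <- ring_kernel(4)
    for (k in seq_len(n_out)) excl <- EBImage::dilate(excl * 1, kern) > 0
  }
  bg <- image[!excl]
  if (!length(bg)) stop("no background pixels: cells cover the whole frame")
  stats::median(bg)
}

#' Per-cell ring fluorescence profiles
#'
#' For every (cell, ring) region the median pixel intensity is computed;
#' the background-corrected median is normalized by the cell's
#' background-corrected CORE median, so the CORE value is 1 by
#' construction. Cells whose corrected CORE median is at or below
#' `eps_floor` (default 1e-6 of the image dynamic range) are flagged
#' invalid rather than erroring, and are excluded downstream.
#'
#' @param image 2-D numeric matrix (e.g. the GFP channel)
#' @param rings a [peel_rings()] decomposition from the same geometry
#' @param background scalar ADU, from [estimate_background()]
#' @param eps_floor positive floor for the normalization denominator;
#'   `NULL` uses 1e-6 * diff(range(image))
#' @return `radial_profiles`: list with `rings` (data.frame: `cell_id`,
#'   `ring`, `npix`, `median`, `normalized`) and `cells` (data.frame:
#'   `cell_id`, `inner_median` background-corrected CORE median, `valid`)
#' @export
ring_profile <- function(image, rings, background, eps_floor = NULL) {
  if (!all(dim(image) == dim(rings$labels)))
    stop("image and ring decomposition must have the same shape")
  if (is.null(eps_floor)) eps_floor <- 1e-6 * diff(range(image))
  cc <- rings$counts
  med <- rep(NA_real_, nrow(cc))
  ok <- cc$npix > 0
  # gather pixel values per (cell, ring) in one pass
  sel <- !is.na(rings$coord)
  key <- paste(rings$owner[sel], rings$coord[sel])
  vals <- split(image[sel], key)
  want <- paste(cc$cell_id, cc$ring)
  med[ok] <- vapply(want[ok], function(k) stats::median(vals[[k]]), numeric(1))
  core <- core_code(rings)
  cells <- unique(cc$cell_id)
  inner <- vapply(cells, function(id) {
    m <- med[cc$cell_id == id & cc$ring == core]
    if (length(m) && !is.na(m)) m - background else NA_real_
  }, numeric(1))
  valid <- !is.na(inner) & inner > eps_floor
  denom <- inner[match(cc$cell_id, cells)]
  normalized <- ifelse(valid[match(cc$cell_id, cells)] & !is.na(med),
                       (med - background) / denom, NA_real_)
  structure(list(
    rings = data.frame(cell_id = cc$cell_id, ring = cc$ring, npix = cc$npix,
                       median = med, normalized = normalized),
    cells = data.frame(cell_id = cells, inner_median = inner, valid = valid)),
    class = "radial_profiles")
}

#' @export
print.radial_profiles <- function(x, ...) {
  cat(sprintf("radial_profiles: %d cells (%d valid)\n",
              nrow(x$cells), sum(x$cells$valid)))
  invisible(x)
}

#' Ring coordinate of the profile maximum
#'
#' The coordinate of the maximum normalized value over the inward rings
#' (CORE and outward rings excluded; ties resolved to the outermost ring).
#' A peak at a wall-depth ring marks surface or membrane localization; a
#' maximum at the innermost ring is the intracellular pattern ("no surface
#' peak").
#'
#' @param profiles a `radial_profiles` object
#' @param cell_id single cell id; `NULL` returns a vector for all valid cells
#' @return integer ring coordinate(s)
#' @export
locate_peak <- function(profiles, cell_id = NULL) {
  one <- function(id) {
    p <- profiles$rings
    core <- min(p$ring)  # CORE carries the most negative code
    p <- p[p$cell_id == id & p$ring <= 0 & p$ring != core & p$npix > 0 &
             !is.na(p$normalized), , drop = FALSE]
    if (!nrow(p)) stop(sprintf("cell %s has an empty profile", id))
    cand <- p$ring[p$normalized == max(p$normalized)]
    max(cand)  # ties -> outermost
  }
  ids <- if (is.null(cell_id)) profiles$cells$cell_id[profiles$cells$valid]
         else cell_id
  out <- vapply(ids, one, numeric(1))
  if (length(ids) == 1) out[[1]] else stats::setNames(out, ids)
}

#' Estimate fluorescence bleed-through factors from intracellular controls
#'
#' For cells from declared intracellular-control strains, the fraction of
#' core signal detected in each wall ring, FB_i, is the mean over cells of
#' the normalized profile value at ring i (per-cell-then-mean; `aggregate
#' = "median"` is available). The per-ring dispersion (SD over cells) and
#' the number of cells used are recorded.
#'
#' @param profiles a `radial_profiles` object, or a list of them (pooled),
#'   containing only intracellular-control cells
#' @param min_cells minimum number of valid cells required (default 40)
#' @param wall_span inward ring coordinates to model (default 0 ... -9)
#' @param aggregate "mean" (default) or "median"
#' @return `bleedthrough_model`: list with `fb` (data.frame: `ring`, `fb`,
#'   `sd`, `n`), `n_cells`, `aggregate`
#' @export
estimate_bleedthrough <- function(profiles, min_cells = 40,
                                  wall_span = 0:-9, aggregate = "mean") {
  if (inherits(profiles, "radial_profiles")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    ok <- p$cells$cell_id[p$cells$valid]
    r <- p$rings[p$rings$cell_id %in% ok & p$rings$ring %in% wall_span &
                   p$rings$npix > 0, , drop = FALSE]
    r$cell_id <- paste(i, r$cell_id)  # unique ids across pooled frames
    r
  }))
  n_valid <- length(unique(rows$cell_id))
  if (n_valid < min_cells)
    stop(sprintf("bleed-through estimation needs >= %d valid control cells, got %d (deficit %d)",
                 min_cells, n_valid, min_cells - n_valid))
  agg_fun <- switch(aggregate, mean = mean, median = stats::median,
                    stop("aggregate must be 'mean' or 'median'"))
  fb <- do.call(rbind, lapply(sort(unique(rows$ring), decreasing = TRUE),
    function(rg) {
      v <- rows$normalized[rows$ring == rg]
      v <- v[!is.na(v)]
      data.frame(ring = rg, fb = agg_fun(v), sd = stats::sd(v), n = length(v))
    }))
  if (any(!is.finite(fb$fb)) || any(fb$fb < 0))
    stop("estimated FB values must be finite and non-negative")
  structure(list(fb = fb, n_cells = n_valid, aggregate = aggregate),
            class = "bleedthrough_model")
}

#' @export
print.bleedthrough_model <- function(x, ...) {
  cat(sprintf("bleedthrough_model (%s of %d cells):\n", x$aggregate, x$n_cells))
  print(x$fb, row.names = FALSE)
  invisible(x)
}

#' Look up FB for a ring coordinate
#' @param model a `bleedthrough_model`
#' @param ring ring coordinate(s)
#' @return FB value(s); error if a coordinate is missing from the model
#' @export
fb_lookup <- function(model, ring) {
  i <- match(ring, model$fb$ring)
  if (anyNA(i))
    stop(sprintf("no FB value for ring coordinate(s) %s",
                 paste(ring[is.na(i)], collapse = ", ")))
  model$fb$fb[i]
}
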