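#' Background-corrected integrated intensity of a region
#'
#' `corr1 = raw integral - background * P`, where P is the pixel count of
#' the region (a ring or the whole cell). Negative results are preserved.
#'
#' @param int_raw raw integrated intensity (sum of pixel values), ADU
#' @param npix pixel count P of the region
#' @param background median background ADU
#' @return corrected integrated intensity, ADU
#' @export
corrected_integrated_intensity <- function(int_raw, npix, background) {
  if (any(npix < 0)) stop("npix must be >= 0")
  ifelse(npix == 0, 0, int_raw - background * npix)
}

#' Bleed-through-corrected ring intensity
#'
#' `corr2 = corr1 - inner_median * FB_i * P_i`: the predicted contribution
#' of intracellular signal bleeding into wall ring i is subtracted from the
#' background-corrected ring integral. `inner_median` must already be
#' background-corrected. Negative results are preserved (flooring them
#' would bias the intracellular null upward).
#'
#' @param corr1 background-corrected ring integral, ADU
#' @param inner_median background-corrected CORE median of the same cell
#' @param fb bleed-through fraction FB_i for this ring
#' @param npix ring pixel count P_i
#' @return corrected ring intensity, ADU
#' @export
bleed_corrected_ring_intensity <- function(corr1, inner_median, fb, npix) {
  if (any(!is.finite(fb))) stop("FB must be finite")
  corr1 - inner_median * fb * npix
}

#' Displayed fraction of one cell
#'
#' `sum(corr2 over the wall rings) / corr1_total`. The raw value is kept
#' (it can fall outside \[0,1\] through noise and correction); the reported
#' value is clamped to \[0,1\]. A non-positive total invalidates the cell.
#'
#' @param corr2_rings vector of bleed-corrected wall-ring intensities
#' @param corr1_total background-corrected whole-cell integral
#' @return list `raw`, `reported`, `valid`
#' @export
display_fraction <- function(corr2_rings, corr1_total) {
  if (corr1_total <= 0)
    return(list(raw = NA_real_, reported = NA_real_, valid = FALSE))
  raw <- sum(corr2_rings) / corr1_total
  list(raw = raw, reported = min(max(raw, 0), 1), valid = TRUE)
}

#' Per-cell displayed-fraction records for a GFP image
#'
#' Applies the two-stage correction to every cell: ring and whole-cell
#' integrals are background-corrected (`corr1`), wall-ring integrals are
#' additionally corrected for intracellular bleed-through (`corr2`) using
#' the cell's background-corrected CORE median and the supplied FB model,
#' and the displayed fraction is the corr2 wall sum over the corr1 total.
#' The whole cell is the union of all inward rings and the CORE; outward
#' (+) rings never enter the numerator.
#'
#' @param gfp GFP-channel matrix, ADU
#' @param rings a [peel_rings()] decomposition
#' @param fb a [estimate_bleedthrough()] model
#' @param background median background ADU
#' @param wall_span wall ring coordinates summed in the numerator
#'   (default 0 ... -9; set `0:-8` for a 9-ring wall region)
#' @return data.frame of class `display_quant`: `cell_id`,
#'   `corr1_total`, `inner_median`, `fraction_raw`, `fraction` (clamped),
#'   `valid`
#' @export
quantify_display <- function(gfp, rings, fb, background, wall_span = 0:-9) {
  if (!all(wall_span %in% -(0:(rings$n_in - 1))))
    stop("wall_span must be a subset of the inward rings")
  fb_vals <- fb_lookup(fb, wall_span)
  core <- core_code(rings)
  cc <- rings$counts
  ids <- sort(unique(cc$cell_id))
  sel <- !is.na(rings$coord) & rings$coord <= 0
  key <- paste(rings$owner[sel], rings$coord[sel])
  sums <- vapply(split(gfp[sel], key), sum, numeric(1))
  meds <- vapply(split(gfp[sel], key), stats::median, numeric(1))
  rows <- lapply(ids, function(id) {
    inward <- cc[cc$cell_id == id & cc$ring <= 0, , drop = FALSE]
    area <- sum(inward$npix)
    tot_raw <- sum(sums[paste(id, inward$ring)], na.rm = TRUE)
    corr1_total <- corrected_integrated_intensity(tot_raw, area, background)
    core_med <- meds[paste(id, core)]
    inner <- if (is.na(core_med)) NA_real_ else core_med - background
    ring_rows <- inward[match(wall_span, inward$ring), , drop = FALSE]
    npix <- ifelse(is.na(ring_rows$npix), 0L, ring_rows$npix)
    raw_i <- sums[paste(id, wall_span)]
    raw_i[is.na(raw_i)] <- 0
    corr1_i <- corrected_integrated_intensity(raw_i, npix, background)
    if (is.na(inner)) {
      # no CORE (tiny cell): no bleed estimate possible; invalid
      return(data.frame(cell_id = id, corr1_total = corr1_total,
                        inner_median = NA_real_, fraction_raw = NA_real_,
                        fraction = NA_real_, valid = FALSE))
    }
    corr2_i <- bleed_corrected_ring_intensity(corr1_i, inner, fb_vals, npix)
    fr <- display_fraction(corr2_i, corr1_total)
    data.frame(cell_id = id, corr1_total = corr1_total, inner_median = inner,
               fraction_raw = fr$raw, fraction = fr$reported,
               valid = fr$valid)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("display_quant", class(out))
  out
}

#' Per-strain summary of displayed fractions
#'
#' Mean and SD of the per-cell displayed fraction over valid cells (the
#' per-strain statistic is the mean of per-cell fractions, not a
#' pooled-intensity ratio). Errors if fewer than `min_cells` valid cells
#' are available.
#'
#' @param records a `display_quant` data.frame (one strain/replicate)
#' @param min_cells minimum number of valid cells (default 200)
#' @param strain_id optional label carried into the summary
#' @param use_raw summarize the raw fraction instead of the clamped one
#' @return data.frame: `strain_id`, `n_cells`, `mean_fraction`,
#'   `sd_fraction`
#' @export
summarize_strain <- function(records, min_cells = 200, strain_id = NA,
                             use_raw = FALSE) {
  ok <- records[records$valid & !is.na(records$fraction), , drop = FALSE]
  if (nrow(ok) < min_cells)
    stop(sprintf("strain summary needs >= %d valid cells, got %d",
                 min_cells, nrow(ok)))
  v <- if (use_raw) ok$fraction_raw else ok$fraction
  data.frame(strain_id = strain_id, n_cells = nrow(ok),
             mean_fraction = mean(v), sd_fraction = stats::sd(v))
}
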