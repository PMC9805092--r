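# Shared small-scene builders: analysis stages chained on one scene, and a
# pooled profile set across several scenes of the same strain.

analyse_scene <- function(scene, ...) {
  cm <- segment_cells(scene$wall, ...)
  rg <- peel_rings(cm)
  bg <- estimate_background(scene$gfp, cm)
  pr <- ring_profile(scene$gfp, rg, bg)
  list(cells = cm, rings = rg, bg = bg, prof = pr)
}

make_scenes <- function(n_scenes, f_true, seed0, n_cells = 25,
                        shape = c(512, 512), ...) {
  lapply(seq_len(n_scenes), function(i)
    generate_micrograph(scene_spec(n_cells = n_cells, image_shape = shape,
                                   surface_fraction_true = f_true,
                                   seed = seed0 + i, ...)))
}

# FB model plus pooled display records for a strain against that model
pooled_quant <- function(scenes, fb) {
  recs <- lapply(scenes, function(sc) {
    a <- analyse_scene(sc)
    quantify_display(sc$gfp, a$rings, fb, a$bg)
  })
  do.call(rbind, recs)
}

pooled_fb <- function(scenes, min_cells = 40) {
  profs <- lapply(scenes, function(sc) analyse_scene(sc)$prof)
  estimate_bleedthrough(profs, min_cells = min_cells)
}
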