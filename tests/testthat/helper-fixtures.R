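# Shared fixture builders. All cohorts used in tests are generated at
# reduced frame sizes so the suite stays fast; the acceptance tests check
# the full 750 x 360 frame once.

small_effect <- function(...) {
  args <- modifyList(list(choroid_corr_px = 8), list(...))
  do.call(effect_model, args)
}

# 96 x 160 frame, disc radius 12 at the frame center.
small_cohort <- function(n = 4, seed = 1, effect = small_effect(), ...) {
  generate_cohort(n, effect = effect, seed = seed, shape = c(96, 160),
                  disc_radius = 12, ...)
}

small_annulus <- function(shape = c(96, 160), disc_r = 12) {
  make_annulus((shape + 1) / 2, disc_r, shape)
}

# One standalone synthetic patient spec for render_scan().
patient_spec <- function(t = 12, seed = 42L, irradiated_eye = "OD") {
  list(patient_id = "P01", irradiated_eye = irradiated_eye,
       time_from_treatment = t, rng_seed = as.integer(seed))
}

# Hand-built superpixel object from an explicit label map (bypasses SLIC).
manual_seg <- function(labels) {
  structure(
    list(labels = labels, k = max(labels), n_target = max(labels),
         compactness = 50, seed = 1L, mean_mbr = NULL, defined = NULL,
         n_px = NULL, n_valid = NULL),
    class = "lsfg_superpixels"
  )
}

# Minimal scan wrapper around a bare matrix.
mat_scan <- function(m, valid = NULL) {
  lsfg_scan(m, valid = valid, patient_id = "T", eye = "OD")
}
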