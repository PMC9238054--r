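test_that("the flow multiplier follows max(m_min, 1 - k t) and fellow eyes are unaffected", {
  eff <- effect_model()
  expect_equal(flow_multiplier(eff, 0, TRUE), 1)
  expect_equal(flow_multiplier(eff, 1e6, FALSE), 1)
  t <- seq(0, 200, by = 5)
  m <- flow_multiplier(eff, t, TRUE)
  expect_true(all(diff(m) <= 0))          # non-increasing
  expect_true(all(m >= eff$min_flow_multiplier))
  expect_equal(flow_multiplier(eff, 60, TRUE), 0.4) # 1 - 0.01*60 = 0.4 floor
  expect_equal(flow_multiplier(eff, 30, TRUE), 0.7)
})

test_that("effect_model rejects parameters implying negative or invalid flow", {
  expect_error(effect_model(baseline_vessel_mbr = -1), class = "lsfg_bad_effect")
  expect_error(effect_model(min_flow_multiplier = 0), class = "lsfg_bad_effect")
  expect_error(effect_model(undefined_pixel_fraction = 1), class = "lsfg_bad_effect")
  expect_error(effect_model(scan_noise_sd = -0.1), class = "lsfg_bad_effect")
})

test_that("vessel trees are seeded, bounded in density, and reject degenerate shapes", {
  m1 <- generate_vessel_tree(c(96, 160), seed = 1)
  m2 <- generate_vessel_tree(c(96, 160), seed = 1)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_vessel_tree(c(96, 160), seed = 2)))
  for (s in 1:3) {
    fr <- mean(generate_vessel_tree(c(360, 750), seed = s))
    expect_gte(fr, 0.02)
    expect_lte(fr, 0.20)
  }
  expect_error(generate_vessel_tree(c(20, 100), seed = 1),
               class = "lsfg_bad_shape")
  # zero branching: only the root trunks are stamped (subset of the default)
  trunks <- generate_vessel_tree(c(96, 160), 1, list(branch_prob = 0))
  expect_gt(sum(trunks), 0)
  expect_lte(sum(trunks), sum(generate_vessel_tree(c(96, 160), 1)))
})

test_that("rendered scans obey the effect model", {
  eff <- small_effect(undefined_pixel_fraction = 0)
  shape <- c(96, 160)

  # at t = 0 the irradiated eye is statistically identical to a fellow eye
  sc_irr <- render_scan(patient_spec(t = 0), "OD", 1, eff, shape = shape,
                        disc_radius = 12)
  sc_fel <- render_scan(patient_spec(t = 0, irradiated_eye = "OS"), "OD", 1,
                        eff, shape = shape, disc_radius = 12)
  expect_identical(sc_irr$mbr, sc_fel$mbr) # m(0) = 1: same seeds, same map
  expect_true(all(sc_irr$valid))
  expect_true(all(sc_irr$mbr >= 0))

  # at t = 60 months the irradiated map is 0.4 x the fellow expectation;
  # same anatomy (same rng_seed/eye), so the ratio is visible per scan
  irr60 <- render_scan(patient_spec(t = 60), "OD", 1, eff, shape = shape,
                       disc_radius = 12)
  fel60 <- render_scan(patient_spec(t = 60, irradiated_eye = "OS"), "OD", 1,
                       eff, shape = shape, disc_radius = 12)
  hi <- fel60$mbr > 20 # vessel/disc pixels in the unirradiated rendering
  ratio <- mean(irr60$mbr[hi]) / mean(fel60$mbr[hi])
  expect_lt(abs(ratio - 0.4), 0.03)

  # undefined pixels appear at the requested rate
  eff2 <- small_effect(undefined_pixel_fraction = 0.01)
  sc <- render_scan(patient_spec(), "OD", 1, eff2, shape = shape,
                    disc_radius = 12)
  expect_equal(sum(!sc$valid), round(0.01 * prod(shape)))
  expect_error(render_scan(patient_spec(), "OD", 4, eff2), class = "lsfg_bad_scan")
})

test_that("generate_cohort produces the paired 3-scan structure deterministically", {
  coh <- small_cohort(n = 4, seed = 7)
  expect_equal(nrow(coh$patients), 4)
  expect_equal(nrow(coh$scans), 24) # 4 patients x 2 eyes x 3 scans
  tab <- dplyr::count(coh$scans, patient_id, eye)
  expect_true(all(tab$n == 3))
  irr_per_patient <- coh$scans |>
    dplyr::distinct(patient_id, eye, irradiated) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(n_irr = sum(irradiated))
  expect_true(all(irr_per_patient$n_irr == 1))
  expect_true(all(coh$patients$sbp > coh$patients$dbp))
  expect_true(all(coh$patients$dbp > 0))
  expect_true(all(coh$patients$time_from_treatment >= 0))

  coh2 <- small_cohort(n = 4, seed = 7)
  expect_identical(coh$patients, coh2$patients)
  for (i in seq_len(nrow(coh$scans))) {
    expect_identical(coh$scans$scan[[i]]$mbr, coh2$scans$scan[[i]]$mbr)
  }
  expect_error(generate_cohort(1), class = "lsfg_bad_cohort")
})

test_that("repeat scans of one eye share anatomy but differ in noise", {
  coh <- small_cohort(n = 2, seed = 21)
  eye1 <- purrr::keep(coh$scans$scan, ~ .x$patient_id == "P01" && .x$eye == "OD")
  expect_length(eye1, 3)
  expect_false(identical(eye1[[1]]$mbr, eye1[[2]]$mbr))
  # anatomy shared: the scans are highly correlated on jointly valid pixels
  both <- eye1[[1]]$valid & eye1[[2]]$valid
  expect_gt(cor(eye1[[1]]$mbr[both], eye1[[2]]$mbr[both]), 0.9)
})

test_that("null cohorts yield paired differences centered at zero", {
  # k = 0: the irradiated label has no effect, so the paired mean-MBR
  # difference tests at the nominal 5% level
  eff <- effect_model(flow_decay_per_month = 0, min_flow_multiplier = 1,
                      choroid_corr_px = 5, undefined_pixel_fraction = 0)
  n_rep <- 200
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(5, effect = eff, seed = 5000 + r,
                           shape = c(48, 64), disc_radius = 7)
    eye_mean <- coh$scans |>
      dplyr::mutate(m = purrr::map_dbl(scan, ~ mean(.x$mbr[.x$valid]))) |>
      dplyr::group_by(patient_id, irradiated) |>
      dplyr::summarise(m = mean(m), .groups = "drop") |>
      tidyr::pivot_wider(names_from = irradiated, values_from = m)
    d <- eye_mean$`TRUE` - eye_mean$`FALSE`
    reject[r] <- t.test(d)$p.value < 0.05
  }
  bounds <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(sum(reject), bounds[1])
  expect_lte(sum(reject), bounds[2])
})
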