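test_that("SLIC partitions the frame into connected, seeded-deterministic superpixels", {
  sc <- render_scan(patient_spec(), "OD", 1, small_effect(),
                    shape = c(96, 160), disc_radius = 12)
  seg1 <- slic_segment(sc, n_target = 250)
  seg2 <- slic_segment(sc, n_target = 250)
  expect_identical(seg1$labels, seg2$labels)
  expect_setequal(unique(as.vector(seg1$labels)), seq_len(seg1$k)) # partition, all non-empty
  expect_true(labels_connected(seg1$labels))
  expect_lt(abs(seg1$k - 250) / 250, 0.25)

  expect_error(slic_segment(sc, n_target = 3), class = "lsfg_bad_segmentation")
  expect_error(slic_segment(sc, n_target = prod(dim(sc$mbr)) + 1),
               class = "lsfg_bad_segmentation")
  expect_error(slic_segment(mat_scan(matrix(1, 10, 10))), class = "lsfg_bad_shape")
})

test_that("a constant image splits into near-equal spatial tiles", {
  sc <- mat_scan(matrix(5, 64, 64))
  seg <- slic_segment(sc, n_target = 4)
  expect_equal(seg$k, 4)
  sizes <- tabulate(seg$labels, 4)
  expect_true(all(sizes <= 2 * 64 * 64 / 4))
  expect_true(all(sizes >= 64 * 64 / 4 / 2))
})

test_that("superpixel means, validity cutoff and conservation match brute force", {
  # hand-built 3-superpixel label map
  labels <- matrix(1L, 6, 6)
  labels[, 3:4] <- 2L
  labels[, 5:6] <- 3L
  m <- matrix(0, 6, 6)
  m[, 1:2] <- c(5, 7, 9)   # recycled; mean 7
  m[, 3:4] <- 12
  m[, 5:6] <- 30
  valid <- matrix(TRUE, 6, 6)
  valid[, 3] <- FALSE # 6 of 12 invalid in label 2 -> exactly 50%, defined
  sc <- mat_scan(m, valid)
  seg <- superpixel_means(sc, manual_seg(labels))
  expect_equal(seg$mean_mbr[1], 7)
  expect_true(seg$defined[2]) # valid fraction exactly at the 0.5 cutoff
  expect_equal(seg$mean_mbr[3], 30)

  # more than half invalid -> undefined
  valid2 <- valid
  valid2[1:2, 4] <- FALSE # 8/12 invalid
  seg2 <- superpixel_means(mat_scan(m, valid2), manual_seg(labels))
  expect_false(seg2$defined[2])
  expect_true(is.na(seg2$mean_mbr[2]))

  # conservation: valid-pixel-weighted mean of defined superpixels equals
  # the per-pixel sum (brute force)
  set.seed(31)
  mm <- matrix(runif(36, 0, 40), 6, 6)
  vv <- matrix(runif(36) > 0.2, 6, 6)
  seg3 <- superpixel_means(mat_scan(mm, vv), manual_seg(labels))
  def <- which(seg3$defined)
  lhs <- sum(seg3$n_valid[def] * seg3$mean_mbr[def])
  rhs <- sum(mm[vv & matrix(seg3$defined[labels], 6, 6)])
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("flow histograms match exhaustive per-pixel brute force on hand-built labels", {
  set.seed(77)
  for (rep in 1:5) {
    nr <- sample(20:50, 1); nc <- sample(20:50, 1)
    k <- sample(4:9, 1)
    # random rectangular-ish label tiling via k-means on coordinates
    cx <- runif(k, 1, nc); cy <- runif(k, 1, nr)
    labels <- matrix(0L, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      labels[r, c] <- which.min((r - cy)^2 + (c - cx)^2)
    }
    labels <- matrix(as.integer(factor(labels)), nr, nc)
    mbr <- matrix(runif(nr * nc, 0, 30), nr, nc)
    valid <- matrix(runif(nr * nc) > 0.3, nr, nc)
    sc <- mat_scan(mbr, valid)
    seg <- superpixel_means(sc, manual_seg(labels))
    h <- bin_histogram(seg)
    oracle <- histogram_brute(mbr, valid, labels)
    expect_equal(h$percent, oracle$percent, tolerance = 1e-12)
    expect_equal(attr(h, "n_defined"), oracle$n_defined)
    expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  }
})

test_that("bin edges are half-open with the last bin owning 20", {
  labels <- matrix(rep(1:5, each = 40), 10, 20)
  means <- c(3, 7, 12, 17, 25)
  m <- matrix(means[labels], 10, 20)
  seg <- superpixel_means(mat_scan(m), manual_seg(labels))
  h <- bin_histogram(seg)
  expect_equal(h$percent, rep(20, 5))

  # a superpixel mean of exactly 5 goes to [5, 10), and exactly 20 to >= 20
  m2 <- matrix(c(5, 20, 1, 1, 1)[labels], 10, 20)
  h2 <- bin_histogram(superpixel_means(mat_scan(m2), manual_seg(labels)))
  expect_equal(h2$percent, c(60, 20, 0, 0, 20))

  # single-level case
  h3 <- bin_histogram(superpixel_means(mat_scan(matrix(7, 10, 20)),
                                       manual_seg(labels)))
  expect_equal(h3$percent, c(0, 100, 0, 0, 0))

  # zero defined superpixels errors
  sc_invalid <- lsfg_scan(matrix(NaN, 10, 20))
  expect_error(bin_histogram(superpixel_means(sc_invalid, manual_seg(labels))),
               class = "lsfg_no_defined_superpixels")
})

test_that("range maps tile the frame and project the headline measures", {
  sc <- render_scan(patient_spec(), "OD", 1,
                    small_effect(undefined_pixel_fraction = 0.02),
                    shape = c(96, 160), disc_radius = 12)
  seg <- superpixel_means(sc, slic_segment(sc, n_target = 200))
  maps <- lapply(1:5, function(b) range_map(seg, b))
  overlap <- Reduce(`+`, maps)
  expect_true(all(overlap <= 1)) # pairwise disjoint
  undef_px <- matrix(!seg$defined[seg$labels], 96, 160)
  expect_true(all(overlap + undef_px == 1)) # union + undefined = frame

  h <- bin_histogram(seg)
  fm <- flow_measures(seg)
  expect_equal(fm$pct_ge20, h$percent[5])
  expect_equal(fm$pct_lt5, h$percent[1])
  expect_error(range_map(seg, 6), class = "lsfg_bad_segmentation")

  # all-constant high-flow image: bin 5 map covers the full frame
  sc25 <- mat_scan(matrix(25, 64, 64))
  seg25 <- superpixel_means(sc25, slic_segment(sc25, n_target = 16))
  expect_true(all(range_map(seg25, 5)))
  expect_equal(flow_measures(seg25)$pct_ge20, 100)
  expect_equal(flow_measures(seg25)$pct_lt5, 0)
})

test_that("reducing flow moves mass from pct_ge20 toward pct_lt5", {
  sc <- render_scan(patient_spec(t = 0), "OD", 1, small_effect(),
                    shape = c(96, 160), disc_radius = 12)
  seg_hi <- superpixel_means(sc, slic_segment(sc, n_target = 250))
  fm_hi <- flow_measures(seg_hi)
  for (f in c(0.6, 0.4, 0.2)) {
    sc_lo <- sc
    sc_lo$mbr <- sc$mbr * f
    seg_lo <- superpixel_means(sc_lo, slic_segment(sc_lo, n_target = 250))
    fm_lo <- flow_measures(seg_lo)
    expect_lte(fm_lo$pct_ge20, fm_hi$pct_ge20)
    expect_gte(fm_lo$pct_lt5, fm_hi$pct_lt5)
  }
})
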