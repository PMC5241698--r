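test_that("candidate detection finds isolated PSFs and nothing else", {
  st <- emitters_stack(1150, 1180)
  cand <- detect_candidates(st$frames[, , 1])
  expect_equal(nrow(cand), 1L)
  # within 1 px of the truth (pixel 11-ish)
  expect_lt(abs(cand$col - 0.5 - 1150 / 110), 1)
  expect_lt(abs(cand$row - 0.5 - 1180 / 110), 1)
  # blank offset-only frame: no candidates
  blank <- matrix(100, 21, 21)
  expect_equal(nrow(detect_candidates(blank)), 0L)
  # two PSFs 8 px apart: two candidates
  st2 <- emitters_stack(c(700, 700 + 8 * 110), c(1100, 1100),
                        field = c(28L, 21L))
  expect_equal(nrow(detect_candidates(st2$frames[, , 1])), 2L)
  expect_error(detect_candidates(matrix(0, 0, 0)), "non-empty")
})

test_that("noise-free fits are accurate to the nanometre", {
  set.seed(3)
  for (i in 1:4) {
    x <- 1150 + runif(1, -55, 55); y <- 1150 + runif(1, -55, 55)
    st <- emitters_stack(x, y)
    cand <- detect_candidates(st$frames[, , 1])
    rec <- fit_emitter(st$frames[, , 1], cand$row[1], cand$col[1],
                       st$optics, st$camera)
    expect_lt(sqrt((rec$x - x)^2 + (rec$y - y)^2), 1)
    expect_equal(rec$sigma, st$optics$psf_sigma_nm, tolerance = 0.02)
    expect_equal(rec$intensity, 450, tolerance = 0.01)
  }
})

test_that("reported precision is on the sigma/sqrt(N) scale", {
  st <- emitters_stack(1150, 1150)
  cand <- detect_candidates(st$frames[, , 1])
  rec <- fit_emitter(st$frames[, , 1], cand$row[1], cand$col[1],
                     st$optics, st$camera)
  scale_nm <- 73.2 / sqrt(450)
  expect_gt(rec$uncertainty, scale_nm / 2)
  expect_lt(rec$uncertainty, scale_nm * 2)
})

test_that("border candidates are refused rather than silently truncated", {
  st <- emitters_stack(220, 220)
  expect_error(fit_emitter(st$frames[, , 1], 2, 2, st$optics, st$camera),
               "border")
})

test_that("width filter rejects merged two-emitter fits but keeps clean ones", {
  # two emitters 300 nm apart fit as one inflated/elongated Gaussian
  st <- emitters_stack(c(1000, 1300), c(1150, 1150), field = c(24L, 21L))
  cand <- detect_candidates(st$frames[, , 1])
  expect_equal(nrow(cand), 1L)   # below the detector min-distance
  rec <- fit_emitter(st$frames[, , 1], cand$row[1], cand$col[1],
                     st$optics, st$camera)
  out <- reject_fits(rec, 73.2)
  expect_equal(nrow(out$kept), 0L)
  expect_gt(max(rec$sigma_x, rec$sigma_y) / 73.2, 1.5)
  # a clean single fit passes
  st1 <- emitters_stack(1150, 1150)
  cand1 <- detect_candidates(st1$frames[, , 1])
  rec1 <- fit_emitter(st1$frames[, , 1], cand1$row[1], cand1$col[1],
                      st1$optics, st1$camera)
  out1 <- reject_fits(rec1, 73.2)
  expect_equal(nrow(out1$kept), 1L)
  # all-rejected input leaves an empty kept set without error
  out2 <- reject_fits(rec, 73.2, sigma_bounds = c(0.99, 1.01))
  expect_equal(nrow(out2$kept), 0L)
})

test_that("stack localization recovers one activation per frame", {
  b <- cached("one_per_frame", one_per_frame_stack(100))
  tab <- localize_stack(b$stack)
  expect_gte(nrow(tab), 95)
  d <- match_to_truth(tab, b$truth)
  expect_gt(mean(!is.na(d)), 0.95)
  # reported uncertainty is per-axis; the matched distance is radial (2D),
  # so compare the per-axis RMSE = radial RMSE / sqrt(2)
  rmse_axis <- sqrt(mean(d^2, na.rm = TRUE) / 2)
  expect_lt(rmse_axis, 2 * mean(tab$uncertainty))
  # frames processed independently: no two candidates closer than the
  # detector min-distance within one frame
  px <- attr(tab, "pixel_size_nm")
  for (f in unique(tab$frame)) {
    sub <- tab[tab$frame == f, ]
    if (nrow(sub) < 2) next
    dmin <- min(stats::dist(cbind(sub$x, sub$y)))
    expect_gte(dmin, 3 * px * 0.99)
  }
})

test_that("an empty stack yields an empty table", {
  blank <- render_frames(data.frame(frame = integer(0), id = integer(0),
                                    x = numeric(0), y = numeric(0),
                                    on_fraction = numeric(0)),
                         optics_config(field_px = c(16L, 16L)),
                         camera_model(), seed = 1, n_frames = 3L)
  tab <- localize_stack(blank)
  expect_equal(nrow(tab), 0L)
})

test_that("doubling the photon budget improves the reported precision", {
  lo <- one_per_frame_stack(40, photons = 300, seed = 5)
  hi <- one_per_frame_stack(40, photons = 600, seed = 5)
  t_lo <- localize_stack(lo$stack)
  t_hi <- localize_stack(hi$stack)
  expect_lt(stats::median(t_hi$uncertainty), stats::median(t_lo$uncertainty))
})

test_that("separation sweep partitions into three ordered contiguous regimes", {
  sw <- cached("sweep", separation_sweep(seq(100, 900, by = 50)))
  reg <- sw$regime
  # contiguous blocks in the order merged -> biased -> accurate
  expect_identical(unique(reg),
                   intersect(c("merged", "biased", "accurate"), unique(reg)))
  expect_identical(reg, reg[order(match(reg, c("merged", "biased", "accurate")))])
  expect_true(all(c("merged", "accurate") %in% reg))
  est <- estimate_exclusion_radius(sw)
  expect_lt(est$merge_threshold_nm, est$accurate_threshold_nm)
  expect_lte(est$accurate_threshold_nm, 700)
  # expected bracket for the reference fitter at default optics
  expect_gte(est$accurate_threshold_nm, 150)
})

test_that("a wider PSF pushes both sweep thresholds outward", {
  sw1 <- cached("sweep", separation_sweep(seq(100, 900, by = 50)))
  o2 <- optics_config(field_px = c(40L, 24L))
  o2$psf_sigma_nm <- o2$psf_sigma_nm * 1.5
  sw2 <- separation_sweep(seq(100, 1000, by = 50), optics = o2)
  e1 <- estimate_exclusion_radius(sw1)
  e2 <- estimate_exclusion_radius(sw2)
  expect_gt(e2$merge_threshold_nm, e1$merge_threshold_nm)
  expect_gte(e2$accurate_threshold_nm, e1$accurate_threshold_nm)
})

test_that("a sweep that misses a regime is an explicit error", {
  sw <- cached("sweep", separation_sweep(seq(100, 900, by = 50)))
  only_acc <- sw[sw$regime == "accurate", ]
  class(only_acc) <- class(sw)
  expect_error(estimate_exclusion_radius(only_acc), "bracket")
})
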