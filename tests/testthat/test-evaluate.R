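test_that("reconstruction rendering uses the floor-division convention", {
  tab <- data.frame(x = 105, y = 42, frame = 1L)
  img <- render_reconstruction(tab, pixel_nm = 10, bounds = c(0, 200, 0, 100))
  expect_equal(sum(img), 1)
  # (105, 42) -> 0-based pixel (10, 4): matrix row 5, column 11
  expect_equal(img[5, 11], 1)
  # count conservation for arbitrary tables
  set.seed(1)
  tab2 <- data.frame(x = runif(500, 0, 1000), y = runif(500, 0, 1000),
                     frame = 1L)
  expect_equal(sum(render_reconstruction(tab2, 10)), 500)
  expect_warning(render_reconstruction(tab2[0, ]), "empty")
})

test_that("FRC of identical halves is unity, of independent noise near zero", {
  set.seed(2)
  img <- matrix(rpois(128 * 128, 2), 128, 128)
  cv <- locspeed:::frc_curve(img, img)
  expect_true(all(abs(cv$frc - 1) < 1e-10, na.rm = TRUE))
  # two independent uniform point sets decorrelate beyond the lowest
  # rings: each ring fluctuates around zero at the 1/sqrt(n_samples / 2)
  # scale, so the RMS over well-sampled rings must be well below any
  # genuine correlation level
  n <- 8000
  t1 <- data.frame(x = runif(n, 0, 2560), y = runif(n, 0, 2560))
  t2 <- data.frame(x = runif(n, 0, 2560), y = runif(n, 0, 2560))
  b <- c(0, 2560, 0, 2560)
  i1 <- render_reconstruction(t1, 10, b); i2 <- render_reconstruction(t2, 10, b)
  cv2 <- locspeed:::frc_curve(i1, i2)
  hi <- cv2$n_samples >= 300 & cv2$ring > 2
  expect_lt(sqrt(mean(cv2$frc[hi]^2)), 0.1)
  expect_lt(abs(mean(cv2$frc[hi])), 0.02)
  # symmetry under swapping the halves
  cv3 <- locspeed:::frc_curve(i2, i1)
  expect_equal(cv2$frc, cv3$frc, tolerance = 1e-12)
})

test_that("FRC resolution improves as localization error shrinks", {
  # dense broadband ground truth: points on randomly oriented segments
  # (a periodic structure would put spectral peaks right at the threshold
  # crossing and confound the error-driven rolloff)
  set.seed(3)
  n_seg <- 40
  p0 <- matrix(runif(n_seg * 2, 0, 3000), n_seg, 2)
  ang <- runif(n_seg, 0, pi)
  len <- runif(n_seg, 500, 1500)
  pts <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
    t <- runif(150, 0, len[i])
    cbind(p0[i, 1] + t * cos(ang[i]), p0[i, 2] + t * sin(ang[i]))
  }))
  n <- nrow(pts)
  gx <- pts[, 1]; gy <- pts[, 2]
  res <- vapply(c(5, 10, 20, 40), function(s) {
    tab <- data.frame(x = gx + rnorm(n, sd = s), y = gy + rnorm(n, sd = s),
                      frame = 1L)
    frc_resolution(tab, n_splits = 8, pixel_nm = 10, seed = 4)$resolution_nm
  }, numeric(1))
  expect_true(all(diff(res) > 0))   # larger error -> coarser resolution
})

test_that("FRC averages the requested number of splits and flags unresolved", {
  set.seed(5)
  tab <- data.frame(x = runif(500, 0, 2000), y = runif(500, 0, 2000),
                    frame = 1L)
  r <- frc_resolution(tab, n_splits = 20, seed = 6)
  expect_equal(ncol(r$curves), 20)
  expect_equal(r$n_splits, 20)
  # a tiny scattered table triggers the high-variance warning
  expect_warning(frc_resolution(tab[1:50, ], n_splits = 3, seed = 7),
                 "variance")
})

test_that("frame extrapolation is linear with the documented arithmetic", {
  expect_equal(frames_to_quality(10, 1e4, 1 / 25), 40)
  expect_equal(frames_to_quality(10, 1e4, 2 / 25), 80)
  expect_warning(f0 <- frames_to_quality(0, 1e4), "unreachable")
  expect_identical(f0, Inf)
})

test_that("activation density estimators behave as documented", {
  tab <- data.frame(x = 1, y = 1, frame = rep(1:1000, length.out = 1000),
                    intensity = 100)
  a <- activation_density_from_counts(tab, 5.56e6, 1000)
  expect_equal(a * 1e6, 0.18, tolerance = 0.005)
  expect_equal(activation_density_from_counts(tab[0, ], 5.56e6, 1000), 0)
  # invariant to frame reordering
  tab2 <- tab[sample(nrow(tab)), ]
  expect_equal(activation_density_from_counts(tab2, 5.56e6, 1000), a)
  # brightness proxy: n equal-brightness localizations count as n, a
  # merged double-brightness fit counts as 2
  expect_equal(activation_proxy_from_brightness(rep(100, 7), 100), 7)
  expect_equal(activation_proxy_from_brightness(c(100, 100, 200), 100), 4)
  expect_equal(activation_proxy_from_brightness(numeric(0), 100), 0)
  expect_error(activation_proxy_from_brightness(1:3, 0), "positive")
  # proxy >= plain count whenever merged (brighter-than-median) fits exist
  ints <- c(rep(100, 10), 250, 320)
  expect_gte(activation_proxy_from_brightness(ints, 100), length(ints))
})

test_that("sample-area estimation removes small clusters", {
  img <- matrix(0, 80, 80)
  img[11:60, 11:60] <- 3                     # solid 50 x 50 blob
  attr(img, "pixel_nm") <- 10
  expect_equal(estimate_sample_area(img), 2500 * 100)
  # isolated single pixels all removed
  img2 <- matrix(0, 40, 40)
  img2[cbind(seq(2, 34, by = 4), seq(2, 34, by = 4))] <- 1
  expect_equal(estimate_sample_area(img2, pixel_nm = 10), 0)
  # a 10-px component survives, a 9-px one does not
  img3 <- matrix(0, 40, 40)
  img3[2:11, 3] <- 1                          # 10 px line
  img3[20:28, 30] <- 1                        # 9 px line
  expect_equal(estimate_sample_area(img3, pixel_nm = 10), 10 * 100)
  expect_warning(a0 <- estimate_sample_area(matrix(0, 5, 5), pixel_nm = 10),
                 "empty")
  expect_equal(a0, 0)
})

test_that("8-connectivity joins diagonal pixels", {
  img <- matrix(0, 20, 20)
  d <- cbind(3:12, 3:12)                      # 10 px diagonal
  img[d] <- 1
  expect_equal(estimate_sample_area(img, pixel_nm = 10), 10 * 100)
})

test_that("frame subsampling trims, randomizes and reproduces", {
  tab <- data.frame(frame = rep(1:1000, each = 2), x = 1, y = 1)
  attr(tab, "n_frames") <- 1000
  # identity (up to order) when requesting everything that remains
  full <- subsample_frames(tab, 900, seed = 1)
  expect_setequal(attr(full, "frames_used"), 51:950)
  # deterministic per seed
  s1 <- subsample_frames(tab, 100, seed = 2)
  s2 <- subsample_frames(tab, 100, seed = 2)
  expect_identical(s1, s2)
  expect_error(subsample_frames(tab, 950, seed = 1), "remain after trimming")
  # sampled frames look uniform over the trimmed range
  pvals <- vapply(1:20, function(s) {
    ss <- subsample_frames(tab, 80, seed = s)
    f <- unique(ss$frame)
    stats::ks.test(f + runif(length(f), -0.5, 0.5), "punif", 50.5,
                   950.5)$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.01), 1)
})
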