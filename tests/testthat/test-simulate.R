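test_that("standard structures have the benchmark dimensions", {
  strand <- make_structure("strand")
  expect_equal(geometry_area(strand), 8 * 3520)
  expect_equal(strand$dimensionality, 1L)
  expect_equal(strand$width_nm, 8)
  point <- make_structure("point")
  expect_equal(geometry_area(point), 64)
  ves <- make_structure("vesicles")
  expect_equal(length(ves$primitives), 4L)
  expect_equal(geometry_area(ves), 4 * pi * 30^2)
  # quoted relative offsets
  xy <- t(vapply(ves$primitives, function(p) c(p$x, p$y), numeric(2)))
  expect_equal(xy, matrix(c(0, 0, 200, 200, 200, 400, 400, 600),
                          ncol = 2, byrow = TRUE))
  expect_error(make_structure("helix"))
})

test_that("emitter seeding is Poisson with uniform positions", {
  point <- make_structure("point")
  # mean count = density * area = 0.5 * 64 = 32, within 3 SE over replicates
  set.seed(1)
  counts <- replicate(400, nrow(seed_emitters(point, 0.5)))
  se <- sqrt(32 / 400)
  expect_lt(abs(mean(counts) - 32), 3 * se)
  # x-coordinate uniformity: KS test not rejected at alpha = 0.01 in more
  # than 19 of 20 seeds
  plane <- make_structure("plane", size_nm = c(1000, 1000))
  pvals <- vapply(1:20, function(s) {
    em <- seed_emitters(plane, 2e-3, seed = s)
    stats::ks.test(em$x, "punif", 0, 1000)$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.01), 1L)
  expect_warning(e0 <- seed_emitters(point, 0), "no emitters")
  expect_equal(nrow(e0), 0L)
  expect_error(seed_emitters(plane, 5, max_emitters = 1e4), "lower the tagging")
})

test_that("photophysics model is a proper Markov chain", {
  pm <- photophysics_model(0.01, p_deact = 0.4, p_dark = 0.05,
                           p_dark_recover = 0.2, p_bleach = 0.01)
  expect_equal(rowSums(pm$transition), rep(1, 4), ignore_attr = TRUE)
  expect_equal(pm$transition["bleached", "bleached"], 1)
  expect_error(photophysics_model(1.2), "\\[0, 1\\]")
  expect_error(photophysics_model(0.1, p_deact = 0.8, p_dark = 0.3),
               "sum to more")
})

test_that("blinking dynamics are Poisson-like and respect absorbing bleach", {
  strand <- make_structure("strand")
  em <- seed_emitters(strand, 0.1, seed = 5)
  tr <- simulate_blinking(em, photophysics_model(1e-3), 1000, seed = 6)
  per_frame <- tabulate(tr$active$frame, nbins = 1000)
  expect_gte(mean(per_frame), 5)
  ratio <- stats::var(per_frame) / mean(per_frame)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
  # bleached is absorbing: with certain bleaching from the active state,
  # each emitter has exactly one active frame, ever
  trc <- simulate_blinking(em, photophysics_model(5e-3, p_deact = 0,
                                                  p_bleach = 1), 300,
                           seed = 8)
  expect_lte(max(table(trc$active$id)), 1L)
})

test_that("mean active count matches the independent-Bernoulli expectation", {
  # pool model with instant return: active each frame ~ Binomial(M, p_act)
  strand <- make_structure("strand")
  em <- seed_emitters(strand, 0.1, seed = 9)
  m <- nrow(em)
  tr <- simulate_blinking(em, photophysics_model(2e-3, p_deact = 1), 800,
                          seed = 10)
  expected <- m * 2e-3
  se <- sqrt(expected / 800)
  expect_lt(abs(nrow(tr$active) / 800 - expected), 4 * se)
})

test_that("activation density ladder is monotone in p_act", {
  strand <- make_structure("strand")
  em <- seed_emitters(strand, 0.1, seed = 11)
  area <- geometry_area(strand)
  a_measured <- vapply(c(5e-4, 1e-3, 2e-3, 4e-3), function(p) {
    mean(vapply(1:5, function(s) {
      tr <- simulate_blinking(em, photophysics_model(p), 150, seed = 100 + s)
      measured_activation_density(tr, area)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(a_measured) > 0))
})

test_that("rendering conserves flux and is deterministic", {
  # full-frame emitter, noise off: summed image (minus offset) ~ photon
  # budget within 0.5% (PSF sigma 73 nm << field, tails negligible)
  st <- emitters_stack(1150, 1150, photons = 450, noise = FALSE)
  expect_equal(sum(st$frames) - 21 * 21 * 100, 450, tolerance = 0.005)
  # flux independent of subpixel position within 0.1%
  st2 <- emitters_stack(1150 + 37.3, 1150 - 52.9, photons = 450, noise = FALSE)
  expect_equal(sum(st2$frames), sum(st$frames), tolerance = 0.001)
  # no active emitters, no read noise: every pixel equals the baseline
  blank <- render_frames(data.frame(frame = integer(0), id = integer(0),
                                    x = numeric(0), y = numeric(0),
                                    on_fraction = numeric(0)),
                         optics_config(field_px = c(8L, 8L)),
                         camera_model(readout_noise_rms = 0), noise = TRUE,
                         n_frames = 2L)
  expect_true(all(blank$frames == 100))
  # identical seeds give bit-identical stacks
  act <- data.frame(frame = 1:3, id = 1:3, x = c(500, 900, 1300),
                    y = c(600, 1000, 800), on_fraction = 1)
  o <- optics_config(field_px = c(16L, 16L))
  s1 <- render_frames(act, o, camera_model(), seed = 21, n_frames = 3L)
  s2 <- render_frames(act, o, camera_model(), seed = 21, n_frames = 3L)
  expect_identical(s1$frames, s2$frames)
})

test_that("pixel-integrated PSF sums to the photon budget on a wide grid", {
  g <- locspeed:::pixel_gauss(60, 30 * 110, 73.2, 110)
  expect_equal(sum(g), 1, tolerance = 1e-12)
})

test_that("on-fractions are partial only on the first frame of an on-run", {
  strand <- make_structure("strand")
  em <- seed_emitters(strand, 0.1, seed = 12)
  tr <- simulate_blinking(em, photophysics_model(2e-3, p_deact = 0.3), 200,
                          seed = 13)
  a <- tr$active[order(tr$active$id, tr$active$frame), ]
  run_start <- c(TRUE, diff(a$frame) != 1 | diff(a$id) != 0)
  expect_true(all(a$on_fraction[!run_start] == 1))
  expect_true(all(a$on_fraction >= 0 & a$on_fraction <= 1))
})
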