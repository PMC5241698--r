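test_that("analytic exclusion areas reproduce the dimensional pattern", {
  # 1D strand: E = 2 w r
  expect_equal(exclusion_area(exclusion_model(1, 400, 7)), 5600)
  expect_equal(exclusion_area(exclusion_model(1, 600, 25)), 30000)
  # 2D plane: E = pi r^2
  expect_equal(exclusion_area(exclusion_model(2, 400)), pi * 400^2)
  expect_equal(exclusion_area(exclusion_model(2, 600)) / 1e6, 1.13,
               tolerance = 0.005)
  # 0D point: E = w1 w2, independent of the radius
  expect_equal(exclusion_area(exclusion_model(0, 400, c(8, 8))), 64)
  expect_equal(exclusion_area(exclusion_model(0, 600, c(8, 8))), 64)
})

test_that("invalid exclusion models are refused", {
  expect_error(exclusion_model(1, -5, 7), "positive")
  expect_error(exclusion_model(1, 400, -1), "positive")
  expect_error(exclusion_model(1, 400, NULL), "width")
  expect_error(exclusion_model(3, 400), "0, 1 or 2")
})

test_that("Monte-Carlo intersection area agrees with the analytic forms", {
  # disc fully inside a large plane
  plane <- make_structure("plane", size_nm = c(20000, 20000))
  a2 <- intersection_area_numeric(plane, 10000, 10000, 600,
                                  n_points = 2e5, seed = 1)
  expect_equal(a2 / 1e6, 1.13, tolerance = 0.01)
  # thin strip through the disc centre: ~ 2 w r
  strip <- make_structure("strand", size_nm = c(25, 30000))
  a1 <- intersection_area_numeric(strip, 12.5, 15000, 600,
                                  n_points = 5e5, seed = 2)
  expect_equal(a1, 2 * 25 * 600, tolerance = 0.02)
  expect_equal(a1 / 1e6, 0.03, tolerance = 0.02)
  # r -> 0 limit
  expect_equal(intersection_area_numeric(plane, 10000, 10000, 0), 0)
  # centre outside the structure is a domain error
  expect_error(intersection_area_numeric(strip, 5000, 15000, 600), "inside")
})

test_that("scale-separated geometries match the analytic area within 2%", {
  r <- 400
  # strand: length >= 10 r, width <= r / 10
  strand <- make_structure("strand", size_nm = c(30, 10000))
  num <- intersection_area_numeric(strand, 15, 5000, r, n_points = 5e5,
                                   seed = 3)
  expect_equal(num, exclusion_area(exclusion_model(1, r, 30)),
               tolerance = 0.02)
  # plane: extent >= 10 r
  plane <- make_structure("plane", size_nm = c(10000, 10000))
  num2 <- intersection_area_numeric(plane, 5000, 5000, r, n_points = 5e5,
                                    seed = 4)
  expect_equal(num2, exclusion_area(exclusion_model(2, r)), tolerance = 0.02)
})

test_that("acquisition time has the stated closed form and properties", {
  Q <- 1 / 25
  # E = 0: exponential term is unity
  expect_equal(acquisition_time(Q, 0.001, 0), Q / 0.001)
  # optimum a = 1/E gives T = e Q E, matching a dense grid search
  E <- 5600
  a_grid <- exp(seq(log(1e-3 / E), log(1e3 / E), length.out = 1e4))
  t_grid <- acquisition_time(Q, a_grid, E)
  i_min <- which.min(t_grid)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(a_grid))           # interior minimum
  expect_equal(a_grid[i_min], 1 / E, tolerance = 2e-3)
  expect_equal(min(t_grid), exp(1) * Q * E, tolerance = 1e-5)
  expect_equal(acquisition_time(Q, 1 / E, E), exp(1) * Q * E)
  # a = 2/E costs a factor e/2 over the optimum
  expect_equal(acquisition_time(Q, 2 / E, E) / min(t_grid), exp(1) / 2,
               tolerance = 1e-5)
  # linearity in Q
  expect_equal(acquisition_time(3 * Q, 0.0002, E),
               3 * acquisition_time(Q, 0.0002, E))
  expect_error(acquisition_time(Q, -1, E), "positive")
})

test_that("optimal activation is the reciprocal exclusion area", {
  opt <- optimal_activation(1 / 25, 0.03 * 1e6)
  expect_equal(opt$a_star * 1e6, 33.3, tolerance = 0.01)   # per um^2
  expect_false(opt$degenerate)
  # doubling E halves a* and doubles T_min
  o1 <- optimal_activation(1, 1000); o2 <- optimal_activation(1, 2000)
  expect_equal(o2$a_star, o1$a_star / 2)
  expect_equal(o2$t_min_frames, 2 * o1$t_min_frames)
  # degenerate E = 0 flagged, not silently infinite
  expect_warning(o0 <- optimal_activation(1, 0), "no interior minimum")
  expect_true(o0$degenerate)
})

test_that("speed ratios reproduce the dimensionality penalty", {
  fa <- make_structure("plane")                       # focal-adhesion-like
  mt <- make_structure("strand", size_nm = c(25, 20000))  # microtubule-like
  expect_equal(round(speed_ratio(fa, mt, 600)), 38)
  expect_equal(speed_ratio(fa, fa, 600), 1)
  thin <- make_structure("strand", size_nm = c(7, 20000))
  r <- speed_ratio(fa, thin, 400)
  expect_equal(r, (pi * 400^2) / 5600, tolerance = 1e-10)
  expect_gt(r, 80)   # "almost a factor of 100"
  expect_lt(r, 100)
})

test_that("Poisson void probability links the model to simulation", {
  a <- 1 / (pi * 400^2)     # a E = 1
  v <- void_probability_mc(a, 400, n_activations = 1e5, seed = 1)
  expect_lt(abs(v$fraction_isolated - v$expected), 3 * v$se)
})

test_that("acquisition plan bundles E, a*, T_min consistently", {
  geom <- make_structure("strand", size_nm = c(7, 20000))
  plan <- plan_acquisition(geom, 400, Q = 1 / 25)
  expect_equal(plan$exclusion_area_nm2, 5600)
  expect_equal(plan$a_star * plan$exclusion_area_nm2, 1)
  expect_equal(min(plan$curve$frames), plan$t_min_frames, tolerance = 1e-3)
})
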