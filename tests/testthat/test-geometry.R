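test_that("exact motion/pursuit law matches closed-form algebra", {
  expect_equal(exact_relative_depth(0.25, 1), 1 / 3)
  expect_equal(exact_relative_depth(0.25, 1) * 36, 12)
  expect_equal(exact_relative_depth(0, 5), 0)
  expect_equal(exact_relative_depth(0.5, 1), 1)
  expect_error(exact_relative_depth(1, 1), "undefined")
  expect_error(exact_relative_depth(2, 1), "undefined")
  expect_error(exact_relative_depth(0.2, 0), "dalpha")
  expect_error(exact_relative_depth(0.2, -1), "dalpha")
})

test_that("approximate depth reproduces the worked prediction and limits", {
  expect_equal(approx_depth(dtheta = 0.25, dalpha = 1, f = 36), 9)
  expect_equal(approx_depth(dtheta = 0.042, dalpha = 1, f = 72), 3.024)
  expect_equal(approx_depth(dtheta = 0, dalpha = 2, f = 50), 0)
  cond <- stimulus_condition(f = 36, dtheta = 1.2375, dalpha = 4.95)
  expect_equal(approx_depth(cond), 0.25 * 36)
  expect_error(approx_depth(dtheta = 3, dalpha = 2, f = 36), "undefined")
})

test_that("exact law dominates the approximation and converges to it", {
  r <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(exact_relative_depth(r, 1) > r))
  # first-order agreement: the relative gap equals the ratio itself,
  # i.e. at most 1% at ratio 0.01
  gap <- (exact_relative_depth(0.01, 1) - 0.01) / exact_relative_depth(0.01, 1)
  expect_equal(gap, 0.01, tolerance = 1e-12)
})

test_that("distance-square law reproduces printed depths and round-trips", {
  expect_equal(disparity_to_depth(23.3, f = 36, i = 6.5), 1.351368,
               tolerance = 1e-6)
  expect_equal(disparity_to_depth(4.66, f = 72, i = 6.5), 1.081095,
               tolerance = 1e-6)
  expect_equal(disparity_to_depth(0, f = 50), 0)
  expect_equal(disparity_to_depth(disparity_stimulus(23.3, 36)),
               disparity_to_depth(23.3, 36))
  expect_error(disparity_to_depth(5, f = -1), "f")
  expect_error(disparity_to_depth(5, f = 36, i = 0), "i")
  # inverse identity over the usable disparity range
  delta <- seq(0.1, 30, length.out = 40)
  for (f in c(36, 54, 72)) {
    back <- depth_to_disparity(disparity_to_depth(delta, f), f)
    expect_equal(back, delta, tolerance = 1e-12)
  }
})

test_that("empirical depth evaluates the power-law transducer model", {
  expect_equal(empirical_depth(dtheta = 1, dalpha = 1, f = 36), 0.0313 * 36)
  # frozen hand-evaluation of 0.0313*36*0.5^0.416/4.95^0.192
  expect_equal(empirical_depth(dtheta = 0.5, dalpha = 4.95, f = 36),
               0.6212325, tolerance = 1e-6)
  # frozen hand-evaluation of the adjusted model 0.0444*72*0.14^0.428/1.1^0.148
  adj <- transducer_model(r = 0.428, e = 0.148, k = 0.0444)
  expect_equal(empirical_depth(adj, dtheta = 0.14, dalpha = 1.1, f = 72),
               1.3587268, tolerance = 1e-6)
  expect_error(empirical_depth(dtheta = 0, dalpha = 1, f = 36), "dtheta")
  expect_error(empirical_depth(dtheta = 1, dalpha = -2, f = 36), "dalpha")
})

test_that("unit rescaling moves only k and preserves predictions", {
  m <- transducer_model()
  expect_equal(rescale_model(m, 1)[c("r", "e", "k")], m[c("r", "e", "k")])
  rad <- rescale_model(m, pi / 180)
  expect_equal(rad$r, m$r)
  expect_equal(rad$e, m$e)
  expect_equal(rad$k, 0.0313 / (pi / 180)^0.224, tolerance = 1e-10)
  expect_identical(rad$angle_unit, "radian")
  # round trip restores k
  back <- rescale_model(rad, 180 / pi)
  expect_equal(back$k, m$k, tolerance = 1e-12)
  expect_error(rescale_model(m, -1), "c")
  # prediction invariance when rates are converted consistently
  set.seed(1)
  dth <- runif(20, 0.14, 1.65)
  dal <- runif(20, 1.1, 11.57)
  c_ <- pi / 180
  d_deg <- empirical_depth(m, dtheta = dth, dalpha = dal, f = 54)
  d_rad <- empirical_depth(rescale_model(m, c_),
                           dtheta = dth * c_, dalpha = dal * c_, f = 54)
  expect_equal(d_rad, d_deg, tolerance = 1e-10)
})

test_that("stereo depth-constancy scaling is linear in distance", {
  expect_equal(johnston_ratio(36), 2.015 - 0.011 * 36)
  expect_equal(johnston_ratio(72), 1.223)
  # unity crossing implied by the printed coefficients
  f1 <- (2.015 - 1) / 0.011
  expect_equal(johnston_ratio(f1), 1, tolerance = 1e-12)
  expect_equal(f1, 92.27, tolerance = 1e-3)
  expect_equal(johnston_ratio(50, johnston_scaling(a = 1, b = 0)), 1)
})

test_that("head-speed and pixel conversions follow small-angle geometry", {
  expect_equal(head_speed_to_pursuit_rate(11.0, 36), 17.507, tolerance = 1e-4)
  expect_equal(head_speed_to_pursuit_rate(12.1, 72), 9.6289, tolerance = 1e-4)
  expect_equal(head_speed_to_pursuit_rate(0, 40), 0)
  expect_error(head_speed_to_pursuit_rate(10, 0), "f")
  expect_equal(pixel_to_angle(1, 0.244, 36), 2.3300, tolerance = 1e-4)
  expect_equal(pixel_to_angle(1, 0.244, 54), 1.5534, tolerance = 1e-4)
  expect_equal(pixel_to_angle(1, 0.244, 72), 1.1650, tolerance = 1e-4)
  expect_error(pixel_to_angle(1, 0, 36), "pitch")
})

test_that("pursuit fraction is a percentage of the total eye speed", {
  expect_equal(pursuit_fraction(6.6, 17.5), 37.714, tolerance = 1e-4)
  expect_equal(pursuit_fraction(4.15, 9.3), 44.624, tolerance = 1e-4)
  expect_equal(pursuit_fraction(3.3, 3.3), 100)
  expect_error(pursuit_fraction(1, 0), "total")
})

test_that("empirical depth is foreshortened relative to geometry on the default grid", {
  grid <- build_stimulus_grid(simulation_config())
  stat <- grid[grid$head_state == "stationary", ]
  surf <- predict_depth_surface(transducer_model(), stat)
  expect_true(all(surf$d_empirical < surf$d_geometric))
  expect_true(all(surf$foreshortening > 0 & surf$foreshortening < 1))
})

test_that("empirical depth is monotone in its inputs", {
  m <- transducer_model()
  # increasing in dtheta at fixed dalpha
  d <- empirical_depth(m, dtheta = seq(0.14, 1.65, length.out = 20),
                       dalpha = 4.95, f = 36)
  expect_true(all(diff(d) > 0))
  # increasing in dalpha at fixed motion/pursuit ratio (r > e)
  al <- seq(1.1, 11.57, length.out = 20)
  d <- empirical_depth(m, dtheta = 0.1 * al, dalpha = al, f = 36)
  expect_true(all(diff(d) > 0))
  # linear in f
  d36 <- empirical_depth(m, dtheta = 0.5, dalpha = 4.95, f = 36)
  d54 <- empirical_depth(m, dtheta = 0.5, dalpha = 4.95, f = 54)
  d72 <- empirical_depth(m, dtheta = 0.5, dalpha = 4.95, f = 72)
  expect_equal(d54 / d36, 54 / 36, tolerance = 1e-12)
  expect_equal(d72 / d36, 2, tolerance = 1e-12)
})

test_that("stimulus condition validates its geometry", {
  expect_error(stimulus_condition(f = -1, dtheta = 0.5, dalpha = 2), "f")
  expect_error(stimulus_condition(f = 36, dtheta = 3, dalpha = 2), "ratio")
  expect_s3_class(stimulus_condition(36, 0.5, 2), "stimulus_condition")
})
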