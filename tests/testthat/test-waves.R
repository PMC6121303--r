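test_that("pool configuration and the ouabain shift behave as amplitudes", {
  pools <- default_pools()
  expect_equal(pools$spatial_extent, c(250, 500))
  expect_equal(pools$frequency, c(150, 500))

  expect_identical(apply_ouabain_shift(pools, 0), pools)
  shifted <- apply_ouabain_shift(pools, 1)
  expect_equal(shifted$amplitude[shifted$name == "signaling"], 0)
  expect_equal(shifted$amplitude[shifted$name == "pumping"], 1)
  expect_error(apply_ouabain_shift(pools, 1.2), class = "pumploop_argument_error")
  expect_error(apply_ouabain_shift(pools, -0.1), class = "pumploop_argument_error")
  expect_error(pool_config("x", 10, -5), class = "pumploop_argument_error")
})

test_that("the field equals each pool's analytic plane wave on its own domain", {
  zero <- build_field(pool_config("signaling", 50, 100, amplitude = 0),
                      duration = 0.25, sample_rate = 512, dx = 10)
  expect_true(all(zero$values == 0))

  one <- build_field(pool_config("signaling", 50, 100, amplitude = 2, phase = 0.3),
                     duration = 0.25, sample_rate = 512, dx = 10)
  analytic <- 2 * exp(1i * (2 * pi * 100 * one$time + 0.3))
  for (row in seq_along(one$space)) {
    expect_equal(one$values[row, ], analytic, tolerance = 1e-12)
  }

  # default config: the first 250 arb units carry only the 150 Hz tone
  f <- build_field(default_pools(), dx = 25)
  sig_rows <- f$domain == "signaling"
  expect_true(all(f$space[sig_rows] < 250))
  spec_sig <- power_spectrum(
    structure(list(space = f$space[sig_rows], time = f$time,
                   values = f$values[sig_rows, , drop = FALSE],
                   sample_rate = f$sample_rate),
              class = "wave_field"))
  top <- peak_locations(spec_sig, 1)
  expect_equal(top$frequency, 150)
  expect_lt(sum(spec_sig$power[spec_sig$frequency != 150]),
            1e-12 * sum(spec_sig$power))

  err <- tryCatch(build_field(default_pools(), sample_rate = 800),
                  error = function(e) conditionMessage(e))
  expect_match(err, "1000", fixed = TRUE)  # names the required rate
})

test_that("the power spectrum separates the two pools and obeys Parseval", {
  f <- build_field(default_pools(), dx = 5)
  s <- power_spectrum(f)
  expect_true(all(s$power >= 0))

  pk <- peak_locations(s, 2)
  expect_equal(sort(pk$frequency), c(150, 500))
  # pumping pool occupies 2/3 of space: taller peak at 500 Hz
  expect_equal(pk$frequency[1], 500)

  # Parseval: summed spectral power equals the spatially averaged
  # time-domain mean square (independent direct summation)
  ms <- mean(Mod(f$values)^2)
  expect_equal(sum(s$power), ms, tolerance = 1e-8 * ms)

  bad <- f
  bad$time[3] <- bad$time[3] * 1.5
  expect_error(power_spectrum(bad), class = "pumploop_argument_error")
})

test_that("peak detection finds tones and returns nothing for silence", {
  tone <- build_field(pool_config("signaling", 20, 100), duration = 0.5,
                      sample_rate = 1024, dx = 10)
  s <- power_spectrum(tone)
  pk <- peak_locations(s, 1)
  expect_lte(abs(pk$frequency - 100), attr(s, "bin_width"))

  silent <- build_field(pool_config("signaling", 20, 100, amplitude = 0),
                        duration = 0.5, sample_rate = 1024, dx = 10)
  expect_warning(pk0 <- peak_locations(power_spectrum(silent), 2),
                 "local maxima")
  expect_equal(nrow(pk0), 0)
})

test_that("peak frequencies are recovered within one bin for random pools", {
  withr::with_seed(99, {
    for (i in 1:12) {
      freq <- runif(1, 20, 450)
      f <- build_field(pool_config("p", 30, freq), duration = 0.5,
                       sample_rate = 1024, dx = 10)
      s <- power_spectrum(f)
      pk <- peak_locations(s, 1)
      expect_lte(abs(pk$frequency - freq), attr(s, "bin_width"))
      ms <- mean(Mod(f$values)^2)
      expect_equal(sum(s$power), ms, tolerance = 1e-8 * ms)
    }
  })
})

test_that("signaling peak height decreases monotonically in the shift", {
  shifts <- c(0, 0.05, 0.2, 0.5, 0.8, 1)
  heights <- vapply(shifts, function(sh) {
    pools <- apply_ouabain_shift(default_pools(), sh)
    s <- power_spectrum(build_field(pools, dx = 25))
    s$power[s$frequency == 150]
  }, numeric(1))
  expect_true(all(diff(heights) <= 1e-15))
  expect_equal(heights[length(heights)], 0)
  # pumping peak untouched by the shift
  h500 <- vapply(c(0, 0.5), function(sh) {
    pools <- apply_ouabain_shift(default_pools(), sh)
    s <- power_spectrum(build_field(pools, dx = 25))
    s$power[s$frequency == 500]
  }, numeric(1))
  expect_equal(h500[1], h500[2], tolerance = 1e-12)
})

test_that("disjoint-domain superposition is spatially weighted linear", {
  pools <- default_pools()
  s_both <- power_spectrum(build_field(pools, dx = 25))
  s_sig <- power_spectrum(build_field(pools[1, ], dx = 25))
  s_pump <- power_spectrum(build_field(pools[2, ], dx = 25))
  w <- pools$spatial_extent / sum(pools$spatial_extent)
  combo <- w[1] * s_sig$power + w[2] * s_pump$power
  expect_equal(s_both$power, combo, tolerance = 1e-8 * max(combo))
})
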