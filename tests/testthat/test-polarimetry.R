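test_that("intensity image matches the closed-form angular SD", {
  # pure sin^2(2 theta) profile: sum of squared deviations is exactly 2.25
  stk <- uniform_stack(model18())
  expect_equal(intensity_image(stk)[1, 1], sqrt(2.25 / 17), tolerance = 1e-12)

  # constant pixel -> exactly zero
  expect_equal(intensity_image(uniform_stack(rep(7, 18)))[1, 1], 0)

  # homogeneity: scaling every frame scales the map
  stk3 <- polar_stack(stk$frames * 3.5, stk$angles)
  expect_equal(intensity_image(stk3), 3.5 * intensity_image(stk),
               tolerance = 1e-12)

  expect_error(intensity_image(uniform_stack(5)), "2 frames")
})

test_that("orientation image takes the discrete argmax with smallest-angle ties", {
  # the sin^2(2(theta-phi)) signal peaks 45 deg away from phi (mod 90)
  expect_equal(orientation_image(uniform_stack(model18(phi = 45)))[1, 1], 0)
  expect_equal(orientation_image(uniform_stack(model18(phi = 30)))[1, 1], 75)
  # all-tie constant pixel resolves to the smallest angle
  expect_equal(orientation_image(uniform_stack(rep(2, 18)))[1, 1], 0)

  # 50 random phases against direct 18-term evaluation
  set.seed(11)
  angles <- seq(0, 85, by = 5)
  for (phi in runif(50, 0, 90)) {
    y <- model18(A = runif(1, 0.1, 2), phi = phi, offset = runif(1, 0, 0.3))
    expect_equal(orientation_image(uniform_stack(y))[1, 1],
                 angles[which.max(y)] %% 90)
  }
})

test_that("alignment image reproduces hand-enumerated window examples", {
  # 12 px at 10 deg, 13 at 30 deg: 156 cross pairs of 20 deg over 300 pairs
  o1 <- matrix(c(rep(10, 12), rep(30, 13)), 5, 5)
  expect_equal(alignment_image(o1, 5)$mad[3, 3], 10.4)

  # wraparound: 85 vs 5 deg differ by 10, not 80
  o2 <- matrix(c(rep(85, 13), rep(5, 12)), 5, 5)
  expect_equal(alignment_image(o2, 5)$mad[3, 3], (13 * 12 * 10) / 300)

  # uniform field -> zero everywhere valid
  al <- alignment_image(matrix(40, 8, 8), 5)
  expect_true(all(al$mad[al$valid_mask] == 0))
  expect_false(any(al$valid_mask[1:2, ]))

  expect_error(alignment_image(matrix(0, 8, 8), 4), "odd")
  expect_error(alignment_image(matrix(0, 8, 8), 9), "exceeds")
})

test_that("alignment image agrees with the O(n^2) pairwise oracle", {
  set.seed(21)
  angles <- seq(0, 85, by = 5)
  for (rep_i in 1:5) {
    # discrete 18-angle fields (the count-based fast path)
    od <- matrix(sample(angles, 81, replace = TRUE), 9, 9)
    expect_equal(alignment_image(od, 5)$mad, oracle_mad(od, 5),
                 tolerance = 1e-12)
    # continuous fields (the generic pair path)
    oc <- matrix(runif(81, 0, 90), 9, 9)
    expect_equal(alignment_image(oc, 5)$mad, oracle_mad(oc, 5),
                 tolerance = 1e-12)
  }
  # window 3 as well
  o3 <- matrix(runif(49, 0, 90), 7, 7)
  expect_equal(alignment_image(o3, 3)$mad, oracle_mad(o3, 3),
               tolerance = 1e-12)
})

test_that("abundance R^2 is 1 on model pixels, 0 on constant pixels, high under noise", {
  set.seed(31)
  for (i in 1:10) {
    y <- model18(A = runif(1, 0.2, 2), phi = runif(1, 0, 90),
                 offset = runif(1, 0, 0.5))
    ab <- abundance_image(uniform_stack(y))
    expect_equal(ab$r2[1, 1], 1, tolerance = 1e-10)
    expect_true(ab$mask[1, 1])
  }
  ab0 <- abundance_image(uniform_stack(rep(3, 18)))
  expect_equal(ab0$r2[1, 1], 0)
  expect_false(ab0$mask[1, 1])

  # 1000 replicate pixels of sin^2(2 theta) + N(0, 0.05^2)
  set.seed(32)
  y <- model18()
  fr <- array(0, dim = c(1000, 1, 18))
  for (z in 1:18) fr[, 1, z] <- y[z] + rnorm(1000, 0, 0.05)
  ab <- abundance_image(polar_stack(pmax(fr, 0)))
  expect_gt(mean(ab$r2), 0.9)
  expect_gt(mean(ab$mask), 0.99)

  expect_error(abundance_image(uniform_stack(c(1, 2, 3))), "4 frames")
})

test_that("flood-field correction is exact on simulator output", {
  # uniform reference leaves the stack unchanged
  ph <- generate_stack(phantom_spec(width = 24, height = 24, noise_sd = 0,
                                    gain_map_sd = 0, seed = 5))
  ref_u <- polar_stack(array(0.6, dim = dim(ph$stack$frames)))
  expect_equal(flood_field_correct(ph$stack, ref_u)$frames, ph$stack$frames,
               tolerance = 1e-12)

  # gain round-trip: divide out the simulated inhomogeneity
  phg <- generate_stack(phantom_spec(width = 32, height = 32, noise_sd = 0,
                                     gain_map_sd = 0.2, seed = 6))
  gain <- phg$truth$gain_map
  ref <- polar_stack(array(rep(0.4 * gain, 18), dim = dim(phg$stack$frames)))
  corrected <- flood_field_correct(phg$stack, ref)
  truth <- generate_stack(phantom_spec(width = 32, height = 32, noise_sd = 0,
                                       gain_map_sd = 0, seed = 6))
  rel <- abs(corrected$frames - truth$stack$frames * mean(gain)) /
    pmax(abs(truth$stack$frames * mean(gain)), 1e-12)
  expect_lt(max(rel), 1e-6)

  # nonpositive reference pixels are counted in the error
  bad <- ref
  bad$frames[1, 1, 1] <- 0
  expect_error(flood_field_correct(phg$stack, bad), "1 nonpositive")
  expect_error(flood_field_correct(ph$stack, polar_stack(
    array(1, dim = c(24, 24, 18)), seq(2, 87, by = 5))), "angles")
})

test_that("derived images are independent of the measurement geometry", {
  # relabeling angles by a cyclic frame shift: MIR and R^2 invariant,
  # orientation shifted by the same constant modulo 90
  set.seed(41)
  ph <- generate_stack(phantom_spec(width = 20, height = 20, noise_sd = 0.02,
                                    seed = 41))
  shift <- 4L  # 20 degrees
  fr <- ph$stack$frames
  fr2 <- fr[, , c((shift + 1):18, 1:shift)]
  stk2 <- polar_stack(fr2, ph$stack$angles)
  expect_equal(intensity_image(stk2), intensity_image(ph$stack),
               tolerance = 1e-9)
  expect_equal(abundance_image(stk2)$r2, abundance_image(ph$stack)$r2,
               tolerance = 1e-9)
  b1 <- orientation_image(ph$stack)
  b2 <- orientation_image(stk2)
  expect_true(all((b1 - b2 - shift * 5) %% 90 == 0))
})

test_that("orientation recovered on phantoms is within half the angular step", {
  ph <- generate_stack(phantom_spec(width = 64, height = 64, noise_sd = 0,
                                    gain_map_sd = 0, dark_offset = 0.05,
                                    seed = 8))
  b <- orientation_image(ph$stack)
  mask <- ph$truth$fiber_mask & ph$truth$amplitude_map > 0.05
  # expected argmax angle: 45 deg from the fiber orientation, mod 90
  want <- (ph$truth$orientation_map + 45) %% 90
  d <- abs(b[mask] - want[mask])
  d <- pmin(d, 90 - d)
  expect_lte(max(d), 2.5)
  # abundance mask detects exactly the modulating pixels (noise-free)
  ab <- abundance_image(ph$stack)
  expect_true(all(ab$mask[mask]))
  expect_false(any(ab$mask[!ph$truth$fiber_mask]))
})
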