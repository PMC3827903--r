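test_that("fixture pits carry exact analytic ground truth", {
  m <- make_flat_map(120, 120, 1)
  fx <- make_fixture_pit(m, 60, 60, 10, 10, 5)
  expect_equal(fx$truth$area_um2, pi * 100) # 314.16
  expect_equal(fx$truth$volume_um3, pi * 100 * 5)

  fx2 <- make_fixture_pit(m, 60, 60, 30, 5, 10)
  expect_equal(fx2$truth$area_um2, pi * 150) # 471.24
  expect_equal(fx2$truth$length_um, 60)
  expect_equal(fx2$truth$width_um, 10)

  # zero depth: no change
  fx0 <- make_fixture_pit(m, 60, 60, 10, 10, 0)
  expect_identical(unclass(fx0$map), unclass(m))

  expect_error(make_fixture_pit(m, 500, 60, 10, 10, 5), "outside")
})

test_that("the quantifier recovers analytic fixtures within discretization bounds", {
  # 100 random fixtures at 0.5 um/px: area within 3 %, length/width within 1 px
  ps <- 0.5
  withr::with_seed(17, {
    for (i in 1:100) {
      a <- runif(1, 6, 30)
      b <- runif(1, 3, a)
      depth <- runif(1, 2, 30)
      m <- make_flat_map(2 * ceiling(2 * a / ps) + 20, 2 * ceiling(2 * a / ps) + 20, ps)
      cx <- ncol(m) * ps / 2 + runif(1, -1, 1)
      cy <- nrow(m) * ps / 2 + runif(1, -1, 1)
      fx <- make_fixture_pit(m, cx, cy, a, b, depth)
      ev <- tidy(quantify_surface(m, fx$map))
      expect_equal(nrow(ev), 1L)
      expect_equal(ev$area_um2, fx$truth$area_um2, tolerance = 0.03)
      # linear bounds: 1.5 px covers the worst case where the discrete hull's
      # minimum rectangle tilts slightly off the ellipse axes
      expect_lt(abs(ev$length_um - fx$truth$length_um), 1.5 * ps + 1e-9)
      expect_lt(abs(ev$width_um - fx$truth$width_um), 1.5 * ps + 1e-9)
      expect_equal(ev$max_depth_um, depth)
    }
  })
})

test_that("geometry calibration hits printed moments and flags infeasible targets", {
  for (tgt in list(c(580, 53, 9.5), c(700, 59, 11))) {
    params <- calibrate_geometry(tgt[1], tgt[2], tgt[3], seed = 5)
    # independent Monte-Carlo check with fresh draws
    draws <- withr::with_seed(99, sample_event_geometry(params, 2e5))
    areas <- osteotrace:::event_planform_area(
      draws$type, draws$length_um, draws$width_um
    )
    expect_equal(mean(areas), tgt[1], tolerance = 0.02)
    expect_equal(mean(draws$length_um), tgt[2], tolerance = 0.02)
    expect_equal(mean(draws$width_um), tgt[3], tolerance = 0.02)
    expect_true(all(draws$length_um >= draws$width_um))
  }

  # degenerate zero-variance request with exactly consistent area: closed form
  l <- 40; w <- 10
  a_exact <- (0.5 + 0.5 * pi / 4) * l * w - 0.5 * (1 - pi / 4) * w^2
  p0 <- calibrate_geometry(a_exact, l, w, cv_length = 0, cv_width = 0)
  expect_equal(p0$rho, 0)
  expect_equal(exp(p0$mu_length), l)

  # unattainable mean area for the shape family
  expect_error(calibrate_geometry(5000, 40, 10), "infeasible")
  expect_error(calibrate_geometry(500, 10, 40), "exceed")
})

test_that("calibration round trip through simulate + quantify recovers moments", {
  # the quantifier's pooled moments are compared with the drawn ground truth
  # of the same events, removing finite-sample noise in the draws themselves;
  # moderate density keeps events resolvable, 0.5 um/px measurement grid
  preset <- substrate_preset("bone_rough")
  donor <- donor_profile("d", 50)
  evs <- NULL; truth <- NULL
  for (s in 1:3) {
    run <- run_simulation(preset, donor,
      area_cm2 = 0.05, seed = 600 + s,
      pixel_size = 0.5, roughness = FALSE
    )
    evs <- dplyr::bind_rows(evs, tidy(quantify_surface(run$pristine, run$final)))
    truth <- dplyr::bind_rows(truth, run$events)
  }
  expect_gt(nrow(evs), 40)
  drawn_area <- osteotrace:::event_planform_area(
    truth$type, truth$length_um, truth$width_um
  )
  expect_equal(mean(evs$area_um2), mean(drawn_area), tolerance = 0.05)
  expect_equal(mean(evs$length_um), mean(truth$length_um), tolerance = 0.05)
  # width additionally carries the rectangle-discretization + trail-curvature
  # bias; bound it absolutely (~2.5 px at this grid)
  expect_lt(abs(mean(evs$width_um) - mean(truth$width_um)), 1.25)
})

test_that("donor D_max is recovered from the depth-area plateau", {
  preset <- substrate_preset("dentin_rough")
  donor <- donor_profile("donor2_expt1", 55)
  run <- run_simulation(preset, donor, area_cm2 = 0.02, seed = 12)
  ev <- tidy(quantify_surface(run$pristine, run$final))
  expect_gt(nrow(ev), 30)
  expect_equal(plateau_depth(ev, 0.75), 55, tolerance = 0.10)
})

test_that("simulated cohorts are reproducible and structurally sound", {
  spec <- cohort_spec(
    n_donors = 3, preset = substrate_preset("bone_rough"),
    area_cm2 = 0.005, master_seed = 99, roughness = FALSE
  )
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_equal(nrow(a), 3L)
  expect_identical(a$D_max, b$D_max)
  expect_identical(
    unclass(a$run[[2]]$final), unclass(b$run[[2]]$final)
  )
  expect_true(all(a$D_max >= 32 & a$D_max <= 68))

  qc <- quantify_cohort(a)
  expect_equal(nrow(qc$summaries), 3L)
  expect_setequal(unique(qc$events$donor_id), a$donor_id)
  out <- summarize_cohort(qc$summaries)
  expect_equal(out$n_donors, 3L)

  # single donor on a silent preset: untouched surface
  silent <- substrate_preset("bone_rough")
  silent$event_intensity <- 0
  s0 <- cohort_spec(n_donors = 1, preset = silent, area_cm2 = 0.001, master_seed = 1)
  c0 <- generate_cohort(s0)
  expect_identical(
    unclass(c0$run[[1]]$final), unclass(c0$run[[1]]$pristine)
  )
})
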