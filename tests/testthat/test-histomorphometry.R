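test_that("event detection finds, separates and merges components correctly", {
  m <- make_flat_map(200, 200, 1)
  cfg <- detection_config()

  # untouched surface: no events
  expect_equal(max(detect_events(m, m, cfg)), 0L)

  # two disjoint pits: two labels
  f <- resorb_pit(m, pit_event(50, 50, 20, 20, 5))
  f <- resorb_pit(f, pit_event(150, 150, 20, 20, 5), pristine = m)
  expect_equal(max(detect_events(m, f, cfg)), 2L)

  # overlapping pits: one merged label
  g <- resorb_pit(m, pit_event(100, 100, 20, 20, 5))
  g <- resorb_pit(g, pit_event(112, 100, 20, 20, 5), pristine = m)
  expect_equal(max(detect_events(m, g, cfg)), 1L)

  # shape mismatch rejected
  expect_error(detect_events(m, make_flat_map(10, 10, 1), cfg), "shape")

  # sub-threshold texture creates no events
  r <- synthesize_roughness(m, 6.27, seed = 2)
  expect_equal(max(detect_events(r, r, cfg)), 0L)
})

test_that("event measurement matches the analytic ellipse oracle", {
  m <- make_flat_map(200, 200, 1)
  fx <- make_fixture_pit(m, 100.3, 100.6, 30, 5, 10)
  q <- quantify_surface(m, fx$map)
  ev <- tidy(q)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$area_um2, fx$truth$area_um2, tolerance = 0.03) # pi*30*5
  expect_equal(ev$length_um, 60, tolerance = 1 / 60)             # within 1 px
  expect_equal(ev$width_um, 10, tolerance = 1 / 10)              # within 1 px
  expect_equal(ev$max_depth_um, 10)
  expect_equal(ev$volume_um3, fx$truth$volume_um3, tolerance = 0.03)
  expect_false(ev$touches_edge)
})

test_that("axis-aligned squares and depth quantization follow the rules", {
  m <- make_flat_map(60, 60, 1)
  h <- unclass(m)
  h[21:30, 31:40] <- -12.3 # 10 x 10 um square, 12.3 um deep
  f <- height_map(h, 1)
  cfg <- detection_config(z_step = 2)
  ev <- measure_events(detect_events(m, f, cfg), m, f, cfg)
  expect_equal(ev$length_um, 10)
  expect_equal(ev$width_um, 10)
  expect_equal(ev$area_um2, 100)
  # 12.3 um at 2 um z-step: ceil(12.3 / 2) = 7 slices -> 14 um
  expect_equal(ev$quantized_depth_um, 14)
  # quantized depth bounds: >= true depth, < true + z_step
  expect_gte(ev$quantized_depth_um, ev$max_depth_um)
  expect_lt(ev$quantized_depth_um - ev$max_depth_um, 2)
})

test_that("length/width are robust to rotation of the component", {
  m <- make_flat_map(220, 220, 1)
  base <- tidy(quantify_surface(
    m, resorb_pit(m, pit_event(110.2, 110.4, 60, 16, 5, orientation = 0))
  ))
  rot <- tidy(quantify_surface(
    m, resorb_pit(m, pit_event(110.2, 110.4, 60, 16, 5, orientation = 37 * pi / 180))
  ))
  expect_lt(abs(base$length_um - rot$length_um), 2)
  expect_lt(abs(base$width_um - rot$width_um), 2)
})

test_that("surface summaries report resorbed fraction and event density", {
  m <- make_flat_map(1000, 1000, 1) # 0.01 cm^2
  expect_equal(
    glance(quantify_surface(m, m))[, c("resorbed_area_pct", "events_per_cm2")],
    tibble::tibble(resorbed_area_pct = 0, events_per_cm2 = 0)
  )

  fx <- make_fixture_pit(m, 500, 500, 30, 5, 10)
  s <- glance(quantify_surface(m, fx$map))
  expect_equal(s$events_per_cm2, 100)
  expect_equal(s$resorbed_area_pct, 100 * pi * 30 * 5 / 1e6, tolerance = 0.03)
})

test_that("area conservation and pooling invariance hold", {
  m <- make_flat_map(300, 150, 1)
  f <- resorb_pit(m, pit_event(60, 70, 24, 12, 6))
  f <- resorb_pit(f, pit_event(220, 80, 30, 10, 9), pristine = m)
  cfg <- detection_config()
  lab <- detect_events(m, f, cfg)
  ev <- measure_events(lab, m, f, cfg)
  # sum of event areas equals the mask area exactly, same discretization
  expect_equal(sum(ev$area_um2), sum(lab > 0) * 1)

  # quantify two half-maps (cut avoids both events) and pool
  left <- height_map(unclass(m)[, 1:150], 1)
  right <- height_map(unclass(m)[, 151:300], 1)
  fl <- height_map(unclass(f)[, 1:150], 1)
  fr <- height_map(unclass(f)[, 151:300], 1)
  pooled <- dplyr::bind_rows(
    tidy(quantify_surface(left, fl, cfg)),
    tidy(quantify_surface(right, fr, cfg))
  )
  expect_equal(sort(pooled$area_um2), sort(ev$area_um2))
  expect_equal(sort(pooled$max_depth_um), sort(ev$max_depth_um))
})

test_that("edge-touching events are flagged and switchable in summaries", {
  m <- make_flat_map(100, 100, 1)
  f <- resorb_pit(m, pit_event(3, 50, 20, 10, 5)) # clipped at the left edge
  f <- resorb_pit(f, pit_event(60, 50, 20, 10, 5), pristine = m)
  q_all <- quantify_surface(m, f, include_edge = TRUE)
  q_int <- quantify_surface(m, f, include_edge = FALSE)
  expect_equal(glance(q_all)$n_events, 2L)
  expect_equal(glance(q_int)$n_events, 1L)
  expect_equal(glance(q_all)$n_edge_events, 1L)
})

test_that("minimum-area rectangle degenerates gracefully", {
  # single point
  r1 <- min_area_rect(5, 5, pad = 1)
  expect_equal(c(r1$length, r1$width), c(1, 1))
  # collinear points
  r2 <- min_area_rect(c(0, 3, 6), c(0, 4, 8), pad = 1)
  expect_equal(r2$length, 11)
  expect_equal(r2$width, 1)
})
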