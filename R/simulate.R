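#' Place resorption events on a substrate
#'
#' Events arrive as a homogeneous Poisson process: the count is
#' `Poisson(event_intensity x activity_scale x area)`, positions are uniform
#' over the substrate, types are Bernoulli(trail_fraction), and planform
#' geometry is drawn from the preset's calibrated [geometry_params()]. The
#' per-event target depth follows the saturating depth-area law
#' `depth = ceiling x (1 - exp(-area / a0))`, where the ceiling is the donor's
#' plateau depth `D_max` (jittered downward by `D_max_sd` when non-zero, never
#' above `D_max`): small events are shallow, large events resorb at the donor
#' plateau.
#'
#' Trails are decomposed into resorption cycles: the centerline length
#' `L - W` is split into steps of mechanistically bounded length (3-21 um,
#' the span sealed by one crescent actin ring), aiming at ~12 um per cycle;
#' cycle headings follow a persistent random walk (wrapped-normal increments,
#' sd 5 degrees - trails are gently curved, so the transverse width read off
#' the minimum-area rectangle stays the excavation width).
#'
#' @param preset One-row tibble from [substrate_preset()].
#' @param donor One-row tibble from [donor_profile()].
#' @param area_cm2 Substrate area in cm^2 (> 0). Positions are drawn uniformly
#'   on the square of this area.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A tibble with one row per event: `event_id`, `type`, `center_x_um`,
#'   `center_y_um` (trail start for trails), `length_um`, `width_um`,
#'   `depth_um` (realized target depth, <= donor `D_max`), `orientation`
#'   (radians; pit axis or initial trail heading), `donor_id`, and a `cycles`
#'   list column of per-cycle tibbles (`s_um`, `w_um`, `target_depth_um`,
#'   `heading`) for trails (`NULL` for pits).
#' @export
place_events <- function(preset, donor, area_cm2, seed = NULL) {
  stopifnot(nrow(preset) == 1L, nrow(donor) == 1L)
  if (!is.numeric(area_cm2) || area_cm2 <= 0) {
    stop("`area_cm2` must be > 0", call. = FALSE)
  }
  with_optional_seed(seed, {
    lambda <- preset$event_intensity * donor$activity_scale * area_cm2
    n <- stats::rpois(1L, lambda)
    side_um <- sqrt(area_cm2 * 1e8)
    params <- preset$geometry[[1L]]
    geom <- sample_event_geometry(params, n, preset$trail_fraction)
    depth_ceiling <- rep(donor$D_max, n)
    if (donor$D_max_sd > 0 && n > 0) {
      depth_ceiling <- pmin(
        donor$D_max,
        pmax(0.1, stats::rnorm(n, donor$D_max, donor$D_max_sd))
      )
    }
    area_req <- event_planform_area(geom$type, geom$length_um, geom$width_um)
    depth <- depth_ceiling * (1 - exp(-area_req / params$depth_saturation_area))
    ev <- tibble::tibble(
      event_id = seq_len(n),
      type = geom$type,
      center_x_um = stats::runif(n, 0, side_um),
      center_y_um = stats::runif(n, 0, side_um),
      length_um = geom$length_um,
      width_um = geom$width_um,
      depth_um = depth,
      orientation = stats::runif(n, 0, 2 * pi),
      donor_id = rep(donor$donor_id, n)
    )
    ev$cycles <- purrr::pmap(
      list(ev$type, ev$length_um, ev$width_um, ev$depth_um, ev$orientation),
      function(type, l, w, d, theta0) {
        if (type != "trail") return(NULL)
        build_trail_cycles(l, w, d, theta0)
      }
    )
    ev
  })
}

# Split a trail of overall length l (including end caps) into cycles.
# Centerline length is l - w; step lengths are equal within a trail and kept
# inside the mechanistic 3-21 um bound (target ~12 um per cycle).
build_trail_cycles <- function(l, w, d, theta0, heading_sd = 5 * pi / 180) {
  p <- max(l - w, 3)
  n <- max(1L, round(p / 12))
  s <- p / n
  if (s > 21) {
    n <- as.integer(ceiling(p / 21)); s <- p / n
  } else if (s < 3) {
    n <- max(1L, as.integer(floor(p / 3))); s <- max(3, p / n)
  }
  headings <- theta0 + cumsum(c(0, stats::rnorm(n - 1L, 0, heading_sd)))
  tibble::tibble(
    s_um = rep(s, n),
    w_um = rep(w, n),
    target_depth_um = rep(d, n),
    heading = headings
  )
}

#' Excavate a resorption pit
#'
#' Lowers heights inside the event's (rotated) ellipse footprint to
#' `depth` um below the local pristine surface, clamped at the donor maximum
#' depth: walls are vertical at pixel resolution and material is only removed
#' (pointwise minimum with the current surface, so overlapping events deepen
#' but never refill).
#'
#' @param map Current `height_map`.
#' @param event One-row event tibble (see [place_events()]) with
#'   `type == "pit"`.
#' @param pristine Pristine reference `height_map` (defaults to `map`,
#'   appropriate for a first excavation of an untouched surface).
#' @param D_max Depth clamp in um (default `Inf`; pass the donor plateau).
#' @return The updated `height_map`.
#' @export
resorb_pit <- function(map, event, pristine = map, D_max = Inf) {
  stopifnot(nrow(event) == 1L, event$type == "pit")
  assert_congruent(map, pristine)
  depth <- min(event$depth_um, D_max)
  if (depth <= 0) return(map)
  ps <- pixel_size(map)
  h <- unclass(map) + 0 # fresh copy; the kernel excavates it in place
  n <- .stamp_ellipse_cpp(
    h, unclass(pristine), event$center_x_um, event$center_y_um,
    event$length_um / 2, event$width_um / 2, event$orientation, depth, ps
  )
  if (n == 0L) warning("pit footprint entirely outside the map; nothing excavated")
  height_map(h, ps)
}

#' Apply one trail resorption cycle
#'
#' One cycle of the layer-by-layer trail mechanism: the crescent actin ring
#' seals a band of horizontal extent `s_um` (3-21 um) and width `w_um` ahead
#' of the current front, and the cell resorbs that layer from the surface down
#' to `target_depth_um` below the local pristine surface. The band interior
#' and the rear cap are excavated to full depth (the rear cap completes the
#' ramp left by the previous cycle, giving a continuous floor); the front cap
#' carries a linear radial ramp from full depth to the surface - the layer
#' still in progress. The front then advances by `s_um` along the cycle
#' heading.
#'
#' For an isolated cycle on a flat surface the removed volume is
#' `s * w * depth * f(s, w)` with ramp/cap shape factor `f = 1 + pi*w/(6*s)`
#' (see [trail_shape_factor()]).
#'
#' @param map Current `height_map`.
#' @param state List with `x`, `y` (front position, um) and optionally `D_max`.
#' @param cycle One-row tibble with `s_um`, `w_um`, `target_depth_um`,
#'   `heading` (radians).
#' @param pristine Pristine reference map (default `map`).
#' @return List: `map` (updated `height_map`) and `state` (front advanced).
#' @export
resorb_trail_cycle <- function(map, state, cycle, pristine = map) {
  stopifnot(nrow(cycle) == 1L)
  assert_congruent(map, pristine)
  s <- cycle$s_um; w <- cycle$w_um
  if (!is.finite(s) || s < 3 || s > 21) {
    stop("cycle step length must lie in [3, 21] um (one actin-ring advance)",
      call. = FALSE
    )
  }
  if (w <= 0) stop("cycle width must be > 0", call. = FALSE)
  D_max <- if (!is.null(state$D_max)) state$D_max else Inf
  depth <- min(cycle$target_depth_um, D_max)
  ps <- pixel_size(map)
  x0 <- state$x; y0 <- state$y
  x1 <- x0 + s * cos(cycle$heading); y1 <- y0 + s * sin(cycle$heading)
  state$x <- x1; state$y <- y1
  if (depth <= 0) return(list(map = map, state = state))
  h <- unclass(map) + 0
  .stamp_cycle_cpp(h, unclass(pristine), x0, y0, x1, y1, w / 2, depth, ps)
  list(map = height_map(h, ps), state = state)
}

#' Ramp/cap shape factor of a single trail cycle
#'
#' Removed volume of one isolated cycle on a flat surface, expressed as a
#' multiple of the sealed-band volume `s * w * depth`: the stadium band and
#' rear cap are at full depth, the front cap ramp averages one third of it,
#' giving `f = 1 + pi * w / (6 * s)`.
#'
#' @param s_um,w_um Cycle step length and width, um.
#' @return The dimensionless factor f.
#' @export
trail_shape_factor <- function(s_um, w_um) {
  1 + pi * w_um / (6 * s_um)
}

#' Excavate a full resorption trail
#'
#' Applies all cycles of a trail event in order, starting at the event's
#' start position.
#'
#' @inheritParams resorb_pit
#' @param event One-row event tibble with `type == "trail"` and a `cycles`
#'   list column.
#' @return The updated `height_map`.
#' @export
resorb_trail <- function(map, event, pristine = map, D_max = Inf) {
  stopifnot(nrow(event) == 1L, event$type == "trail")
  cycles <- event$cycles[[1L]]
  if (is.null(cycles) || nrow(cycles) < 1L) {
    stop("trail event must carry at least one cycle", call. = FALSE)
  }
  h <- unclass(map) + 0
  stamp_event_inplace(h, unclass(pristine), event, D_max, pixel_size(map))
  height_map(h, pixel_size(map))
}

# Excavate one event into matrix `h` (modified in place; callers own the copy).
stamp_event_inplace <- function(h, pristine_mat, event, D_max, ps) {
  if (event$type == "pit") {
    depth <- min(event$depth_um, D_max)
    if (depth > 0) {
      .stamp_ellipse_cpp(
        h, pristine_mat, event$center_x_um, event$center_y_um,
        event$length_um / 2, event$width_um / 2, event$orientation, depth, ps
      )
    }
  } else {
    cycles <- event$cycles[[1L]]
    x <- event$center_x_um; y <- event$center_y_um
    for (i in seq_len(nrow(cycles))) {
      s <- cycles$s_um[i]
      if (s < 3 || s > 21) {
        stop("cycle step length must lie in [3, 21] um", call. = FALSE)
      }
      x1 <- x + s * cos(cycles$heading[i])
      y1 <- y + s * sin(cycles$heading[i])
      depth <- min(cycles$target_depth_um[i], D_max)
      if (depth > 0) {
        .stamp_cycle_cpp(h, pristine_mat, x, y, x1, y1, cycles$w_um[i] / 2, depth, ps)
      }
      x <- x1; y <- y1
    }
  }
  invisible(NULL)
}

#' Run a full resorption simulation
#'
#' Builds (or takes) a substrate surface, places Poisson events for one donor
#' on one substrate preset, and excavates every pit and trail. Overlapping
#' events take the pointwise minimum height (deepest wins); merging into
#' single measured events is the quantifier's job. Fully reproducible from
#' `seed`.
#'
#' @param preset One-row tibble from [substrate_preset()].
#' @param donor One-row tibble from [donor_profile()].
#' @param map Optional pre-built `height_map`; when `NULL`, a square map of
#'   `area_cm2` at `pixel_size` um/px is created and given the preset's
#'   roughness texture.
#' @param area_cm2 Substrate area when `map` is `NULL`.
#' @param seed Integer seed driving placement, geometry and roughness.
#' @param pixel_size um per pixel for a generated map (default 1).
#' @param roughness Synthesize the preset's Ra texture on a generated map
#'   (default `TRUE`; detection works on the pristine-final difference, so
#'   texture does not change the measured events, only the realism of the
#'   surface).
#' @return A `resorption_run` object: list with `pristine` and `final`
#'   `height_map`s, the ground-truth `events` tibble, `preset_name`,
#'   `donor`, and `seed`.
#' @export
run_simulation <- function(preset, donor, map = NULL, area_cm2 = NULL,
                           seed = NULL, pixel_size = 1, roughness = TRUE) {
  stopifnot(nrow(preset) == 1L, nrow(donor) == 1L)
  with_optional_seed(seed, {
    if (is.null(map)) {
      if (is.null(area_cm2)) stop("give either `map` or `area_cm2`", call. = FALSE)
      side_px <- max(1L, round(sqrt(area_cm2 * 1e8) / pixel_size))
      map <- make_flat_map(side_px, side_px, pixel_size)
      if (roughness && preset$Ra_target_um > 0) {
        map <- synthesize_roughness(map, preset$Ra_target_um)
      }
    }
    pristine <- map
    events <- place_events(preset, donor, map_area_cm2(map))
    h <- unclass(map) + 0
    pm <- unclass(pristine)
    ps <- pixel_size(map)
    for (i in seq_len(nrow(events))) {
      stamp_event_inplace(h, pm, events[i, ], donor$D_max, ps)
    }
    final <- height_map(h, ps)
    structure(
      list(
        pristine = pristine, final = final, events = events,
        preset_name = preset$name, donor = donor, seed = seed
      ),
      class = "resorption_run"
    )
  })
}

#' @export
print.resorption_run <- function(x, ...) {
  cat(sprintf(
    "<resorption_run> %s, donor %s: %d events (%d pits, %d trails) on %.4g cm^2\n",
    x$preset_name, x$donor$donor_id, nrow(x$events),
    sum(x$events$type == "pit"), sum(x$events$type == "trail"),
    map_area_cm2(x$pristine)
  ))
  invisible(x)
}

#' Tidy the ground truth of a simulation run
#'
#' @param x A `resorption_run`.
#' @param ... Unused.
#' @return `tidy()`: the ground-truth events tibble (without the nested cycle
#'   column, plus `n_cycles`). `glance()`: a one-row run summary.
#' @export
tidy.resorption_run <- function(x, ...) {
  ev <- x$events
  ev$n_cycles <- purrr::map_int(ev$cycles, ~ if (is.null(.x)) 0L else nrow(.x))
  ev$cycles <- NULL
  ev
}

#' @rdname tidy.resorption_run
#' @export
glance.resorption_run <- function(x, ...) {
  exc <- unclass(x$pristine) - unclass(x$final)
  tibble::tibble(
    preset = x$preset_name,
    donor_id = x$donor$donor_id,
    area_cm2 = map_area_cm2(x$pristine),
    n_events = nrow(x$events),
    n_trails = sum(x$events$type == "trail"),
    removed_volume_um3 = sum(exc) * pixel_size(x$pristine)^2,
    max_depth_um = max(exc)
  )
}
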