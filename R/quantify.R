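#' Detection configuration for resorption-event quantification
#'
#' @param depth_threshold Minimum excavation (pristine minus final, um) for a
#'   pixel to count as resorbed. The default 0.5 um sits far above numerical
#'   noise yet far below real event depths (several to tens of um).
#' @param connectivity Pixel connectivity for merging resorbed pixels into
#'   events: 4 or 8 (default 8).
#' @param min_event_area Components smaller than this (um^2) are discarded as
#'   noise (default 20 um^2).
#' @param z_step Depth quantization step in um, emulating confocal z-stack
#'   depth reading: reported quantized depth is `z_step x (number of slices
#'   spanned)` (default 1 um).
#' @return A `detection_config` list.
#' @export
detection_config <- function(depth_threshold = 0.5, connectivity = 8,
                             min_event_area = 20, z_step = 1) {
  if (depth_threshold <= 0) stop("`depth_threshold` must be > 0", call. = FALSE)
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (min_event_area < 0) stop("`min_event_area` must be >= 0", call. = FALSE)
  if (z_step <= 0) stop("`z_step` must be > 0", call. = FALSE)
  structure(
    list(
      depth_threshold = depth_threshold, connectivity = as.integer(connectivity),
      min_event_area = min_event_area, z_step = z_step
    ),
    class = "detection_config"
  )
}

#' Detect resorption events on a height map
#'
#' A resorption event is an area of resorption surrounded by a margin of
#' unresorbed material: pixels whose excavation (pristine minus final height)
#' exceeds the depth threshold are grouped into connected components, and each
#' surviving component (>= `min_event_area`) is one labeled event. Working on
#' the pristine-final difference means surface roughness texture never creates
#' false events.
#'
#' @param pristine,final Congruent `height_map`s before and after resorption.
#' @param cfg A [detection_config()].
#' @return An integer label matrix (same shape as the maps; 0 = background,
#'   1..k = events) with attribute `pixel_size`.
#' @export
detect_events <- function(pristine, final, cfg = detection_config()) {
  assert_congruent(pristine, final)
  if (length(pristine) == 0L) stop("maps must contain at least one pixel", call. = FALSE)
  ps <- pixel_size(pristine)
  mask <- .excavation_mask_cpp(unclass(pristine), unclass(final), cfg$depth_threshold)
  lab <- .label_components_cpp(mask, cfg$connectivity)
  if (cfg$min_event_area > 0) {
    min_px <- ceiling(cfg$min_event_area / ps^2)
    if (min_px > 1) {
      sizes <- tabulate(lab[lab > 0L])
      keep <- which(sizes >= min_px)
      relab <- integer(length(sizes))
      relab[keep] <- seq_along(keep)
      pos <- lab > 0L
      lab[pos] <- relab[lab[pos]]
    }
  }
  attr(lab, "pixel_size") <- ps
  lab
}

#' Measure every detected resorption event
#'
#' Per-event morphometrics on a label map: planform area (pixel count x
#' pixel area), length and width as the longer and shorter side of the
#' minimum-area rotated bounding rectangle, maximum excavation depth,
#' confocal-style quantized depth (`z_step x ceiling(max_depth / z_step)`),
#' excavated volume, centroid, and whether the event touches the map edge.
#'
#' @param labels Label matrix from [detect_events()].
#' @param pristine,final The height maps the labels were derived from.
#' @param cfg The [detection_config()] (supplies `z_step`).
#' @return A tibble, one row per event: `label`, `area_um2`, `length_um`,
#'   `width_um`, `max_depth_um`, `quantized_depth_um`, `volume_um3`,
#'   `centroid_x_um`, `centroid_y_um`, `touches_edge`.
#' @export
measure_events <- function(labels, pristine, final, cfg = detection_config()) {
  assert_congruent(pristine, final)
  ps <- attr(labels, "pixel_size")
  if (is.null(ps)) ps <- pixel_size(pristine)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(
      label = integer(), area_um2 = numeric(), length_um = numeric(),
      width_um = numeric(), max_depth_um = numeric(),
      quantized_depth_um = numeric(), volume_um3 = numeric(),
      centroid_x_um = numeric(), centroid_y_um = numeric(),
      touches_edge = logical()
    ))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  exc <- unclass(pristine)[idx] - unclass(final)[idx]
  ord <- order(lab)
  groups <- split(seq_along(lab)[ord], lab[ord])

  out <- purrr::map(groups, function(g) {
    x <- (cols[g] - 0.5) * ps
    y <- (rows[g] - 0.5) * ps
    rect <- min_area_rect(x, y, pad = ps)
    d <- exc[g]
    tibble::tibble(
      area_um2 = length(g) * ps^2,
      length_um = rect$length,
      width_um = rect$width,
      max_depth_um = max(d),
      volume_um3 = sum(d) * ps^2,
      centroid_x_um = mean(x),
      centroid_y_um = mean(y),
      touches_edge = any(rows[g] == 1L | rows[g] == nr | cols[g] == 1L | cols[g] == nc)
    )
  })
  res <- dplyr::bind_rows(out, .id = "label")
  res$label <- as.integer(res$label)
  res$quantized_depth_um <- cfg$z_step * ceiling(res$max_depth_um / cfg$z_step)
  res[, c(
    "label", "area_um2", "length_um", "width_um", "max_depth_um",
    "quantized_depth_um", "volume_um3", "centroid_x_um", "centroid_y_um",
    "touches_edge"
  )]
}

#' Minimum-area rotated bounding rectangle of a point set
#'
#' Rotating-calipers over the convex hull: the minimum-area enclosing
#' rectangle has one side collinear with a hull edge. Used for event length
#' (longer side) and width (shorter side); `pad` (one pixel size) is added to
#' both sides so pixel footprints, not just centers, are covered.
#'
#' @param x,y Point coordinates (um), e.g. pixel centers of one component.
#' @param pad Added to both rectangle sides (um), default 0.
#' @return List with `length`, `width` (um, length >= width) and `angle`
#'   (radians of the long side).
#' @export
min_area_rect <- function(x, y, pad = 0) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1L) {
    return(list(length = pad, width = pad, angle = 0))
  }
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) == 2L) {
    d <- hp[2L, ] - hp[1L, ]
    return(list(
      length = sqrt(sum(d^2)) + pad, width = pad,
      angle = atan2(d[2L], d[1L])
    ))
  }
  best <- NULL
  nh <- nrow(hp)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2L], u[1L])
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    if (is.null(best) || du * dv < best$area) {
      ang <- if (du >= dv) atan2(u[2L], u[1L]) else atan2(v[2L], v[1L])
      best <- list(area = du * dv, a = max(du, dv), b = min(du, dv), angle = ang)
    }
  }
  list(length = best$a + pad, width = best$b + pad, angle = best$angle)
}

#' Quantify osteoclastic resorption on a surface
#'
#' The full histomorphometric readout of one substrate: detect events,
#' measure each one, and aggregate to the standard summary parameters -
#' resorbed area (%), events per cm^2, and mean +/- SEM of per-event area,
#' length and width.
#'
#' @inheritParams detect_events
#' @param include_edge Include events touching the map edge in the summary
#'   (default `TRUE`, matching whole-slice imaging; they are flagged either
#'   way).
#' @return A `resorption_quant` object: list with `events` (per-event tibble,
#'   see [measure_events()]), `summary` (one-row tibble: `resorbed_area_pct`,
#'   `events_per_cm2`, `n_events`, `n_edge_events`, `mean_area_um2`,
#'   `sem_area_um2`, `mean_length_um`, `sem_length_um`, `mean_width_um`,
#'   `sem_width_um`, `area_cm2`), and `config`.
#' @export
quantify_surface <- function(pristine, final, cfg = detection_config(),
                             include_edge = TRUE) {
  labels <- detect_events(pristine, final, cfg)
  events <- measure_events(labels, pristine, final, cfg)
  area_cm2 <- map_area_cm2(pristine)
  mask_px <- sum(events$area_um2) / pixel_size(pristine)^2
  used <- if (include_edge) events else events[!events$touches_edge, ]
  summary <- tibble::tibble(
    resorbed_area_pct = 100 * mask_px / length(pristine),
    events_per_cm2 = nrow(used) / area_cm2,
    n_events = nrow(used),
    n_edge_events = sum(events$touches_edge),
    mean_area_um2 = mean_or_na(used$area_um2),
    sem_area_um2 = sem_or_na(used$area_um2),
    mean_length_um = mean_or_na(used$length_um),
    sem_length_um = sem_or_na(used$length_um),
    mean_width_um = mean_or_na(used$width_um),
    sem_width_um = sem_or_na(used$width_um),
    area_cm2 = area_cm2
  )
  structure(
    list(events = events, summary = summary, config = cfg),
    class = "resorption_quant"
  )
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sem_or_na <- function(x) {
  if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_
}

#' @export
print.resorption_quant <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<resorption_quant> %d events on %.4g cm^2: %.3g%% resorbed, %.0f events/cm^2\n",
    s$n_events, s$area_cm2, s$resorbed_area_pct, s$events_per_cm2
  ))
  cat(sprintf(
    "  mean area %.1f um^2, length %.1f um, width %.1f um\n",
    s$mean_area_um2, s$mean_length_um, s$mean_width_um
  ))
  invisible(x)
}

#' Tidy methods for quantification results
#'
#' @param x A `resorption_quant`.
#' @param ... Unused.
#' @return `tidy()`: the per-event measurement tibble. `glance()`: the one-row
#'   cohort summary.
#' @export
tidy.resorption_quant <- function(x, ...) x$events

#' @rdname tidy.resorption_quant
#' @export
glance.resorption_quant <- function(x, ...) x$summary

#' Histogram-style plot of measured event sizes
#'
#' @param object A `resorption_quant`.
#' @param variable `"length"` or `"width"`.
#' @param ... Unused.
#' @return A ggplot bar chart with the standard reporting bins.
#' @export
autoplot.resorption_quant <- function(object, variable = c("length", "width"), ...) {
  variable <- match.arg(variable)
  counts <- event_histogram(object$events, variable = variable)
  ggplot2::ggplot(counts, ggplot2::aes(.data$bin, .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = sprintf("%s bin (µm)", variable),
      y = "number of events"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
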