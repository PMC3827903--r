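#' Standard reporting bins for event length and width
#'
#' The length histogram uses 14 bins with edges 0, 20, 40, 60, 80, 100, 120,
#' 150, 180, 210, 240, 270, 300, 330 um and an open-ended final bin; the width
#' histogram uses 11 bins with edges 0, 5, 10, 15, 20, 25, 30, 40, 50, 60,
#' 70 um and an open-ended final bin. Bins are half-open `[lo, hi)`, so a
#' value on an edge falls in the upper bin, and the last bin is `[lo, Inf)` so
#' counts always conserve n.
#'
#' @return Numeric vector of bin lower edges (um), ending with the lower edge
#'   of the open-ended bin.
#' @export
length_bins <- function() {
  c(0, 20, 40, 60, 80, 100, 120, 150, 180, 210, 240, 270, 300, 330)
}

#' @rdname length_bins
#' @export
width_bins <- function() {
  c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70)
}

#' Bin event measurements into the standard size histogram
#'
#' @param measurements Per-event tibble (from [measure_events()] or
#'   [tidy.resorption_quant()]) with `length_um` / `width_um` columns, or a
#'   bare numeric vector of values in um.
#' @param variable `"length"` or `"width"` (picks the default bin edges).
#' @param edges Optional custom lower bin edges (strictly increasing; final
#'   bin open-ended).
#' @return A tibble: `bin` (label, e.g. `"20-40"`, last `">=330"`), `lo_um`,
#'   `hi_um` (`Inf` for the last), `count`. Counts sum to the number of
#'   events.
#' @examples
#' event_histogram(c(10, 30, 310), variable = "length")
#' @export
event_histogram <- function(measurements, variable = c("length", "width"),
                            edges = NULL) {
  variable <- match.arg(variable)
  if (is.numeric(measurements)) {
    values <- measurements
  } else {
    col <- paste0(variable, "_um")
    values <- measurements[[col]]
    if (is.null(values)) stop("no column `", col, "` in measurements", call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- if (variable == "length") length_bins() else width_bins()
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing", call. = FALSE)
  lo <- edges
  hi <- c(edges[-1L], Inf)
  counts <- vapply(
    seq_along(lo),
    function(i) sum(values >= lo[i] & values < hi[i]),
    integer(1)
  )
  tibble::tibble(
    bin = factor(
      ifelse(is.finite(hi), paste0(lo, "-", hi), paste0(">=", lo)),
      levels = ifelse(is.finite(hi), paste0(lo, "-", hi), paste0(">=", lo))
    ),
    lo_um = lo, hi_um = hi, count = counts
  )
}

#' Fold change between two summary values
#'
#' @param numerator,denominator Positive summary values (e.g. resorbed-area
#'   percentages or event densities on two substrates).
#' @return The plain ratio numerator / denominator.
#' @examples
#' fold_change(6.7, 0.6) # ~11-fold higher resorbed area on dentin
#' fold_change(3134, 449) # ~7-fold more events per cm^2
#' @export
fold_change <- function(numerator, denominator) {
  if (!is.numeric(denominator) || any(denominator == 0)) {
    stop("`denominator` must be non-zero", call. = FALSE)
  }
  numerator / denominator
}

#' Percent increase in adhered-cell density on dentin over bone
#'
#' @param bone_density,dentin_density Adhered cells per cm^2 (> 0 for bone).
#' @return Percent increase, `100 * (dentin / bone - 1)`.
#' @examples
#' adhesion_increase(11400, 17200) # ~51 percent more cells adhere on dentin
#' @export
adhesion_increase <- function(bone_density, dentin_density) {
  if (!is.numeric(bone_density) || any(bone_density == 0)) {
    stop("`bone_density` must be non-zero", call. = FALSE)
  }
  100 * (dentin_density / bone_density - 1)
}

#' Estimate the donor depth plateau from the depth-area relationship
#'
#' Resorption depth grows with event area only up to a donor-specific maximum
#' D_max; beyond that, events grow in area alone. The plateau is therefore
#' estimated as the mean maximum depth of the large-area events: those above
#' the `area_quantile` of the area distribution.
#'
#' @param measurements Per-event tibble with `area_um2` and `max_depth_um`
#'   columns (at least 10 events).
#' @param area_quantile Fraction of the area distribution below the "large
#'   event" cut (default 0.75).
#' @return Plateau depth estimate in um.
#' @export
plateau_depth <- function(measurements, area_quantile = 0.75) {
  if (nrow(measurements) < 10L) {
    stop("plateau estimation needs >= 10 events", call. = FALSE)
  }
  cut <- stats::quantile(measurements$area_um2, area_quantile, names = FALSE)
  big <- measurements$max_depth_um[measurements$area_um2 >= cut]
  mean(big)
}

#' Welch two-sample t-test between two groups of summary values
#'
#' Unequal-variance (Welch) test, appropriate for donor-level summaries whose
#' spread differs visibly between substrates; set `var_equal = TRUE` for the
#' classic Student test.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @param var_equal Assume equal variances (default `FALSE` = Welch).
#' @return A one-row tibble: `statistic` (t), `p_value`, `df`, `mean_a`,
#'   `mean_b`, `method`.
#' @export
two_sample_test <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
    mean(group_a) == mean(group_b)) {
    # degenerate but well-defined case: identical constant groups
    return(tibble::tibble(
      statistic = 0, p_value = 1,
      df = length(group_a) + length(group_b) - 2,
      mean_a = mean(group_a), mean_b = mean(group_b),
      method = "t-test (degenerate zero-variance)"
    ))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    mean_a = mean(group_a),
    mean_b = mean(group_b),
    method = tt$method
  )
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector (n >= 1; SEM is `NA` for n = 1).
#' @return A one-row tibble: `mean`, `sem`, `n`.
#' @examples
#' mean_sem(c(1, 2, 3, 4))
#' @export
mean_sem <- function(values) {
  if (!is.numeric(values) || length(values) < 1L) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  tibble::tibble(
    mean = mean(values),
    sem = if (length(values) >= 2L) stats::sd(values) / sqrt(length(values)) else NA_real_,
    n = length(values)
  )
}

#' Donor-level cohort summary of per-replicate quantification
#'
#' Reported summary statistics average per-donor values, not pooled events:
#' each donor's replicate is summarized first, then the mean and SEM are taken
#' across donors (n = number of donors), mirroring reporting over osteoclasts
#' from independent donors.
#'
#' @param summaries Tibble of per-replicate summaries: one row per donor
#'   replicate with a `donor_id` column plus the [quantify_surface()] summary
#'   columns.
#' @return A one-row tibble with across-donor `mean`/`sem` for resorbed area
#'   %, events per cm^2, mean event area, length and width, plus `n_donors`.
#' @export
summarize_cohort <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  per_donor <- summaries |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::summarise(
      resorbed_area_pct = mean(.data$resorbed_area_pct),
      events_per_cm2 = mean(.data$events_per_cm2),
      mean_area_um2 = mean(.data$mean_area_um2, na.rm = TRUE),
      mean_length_um = mean(.data$mean_length_um, na.rm = TRUE),
      mean_width_um = mean(.data$mean_width_um, na.rm = TRUE),
      .groups = "drop"
    )
  sem <- function(x) if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_
  tibble::tibble(
    n_donors = nrow(per_donor),
    resorbed_area_pct = mean(per_donor$resorbed_area_pct),
    resorbed_area_pct_sem = sem(per_donor$resorbed_area_pct),
    events_per_cm2 = mean(per_donor$events_per_cm2),
    events_per_cm2_sem = sem(per_donor$events_per_cm2),
    mean_area_um2 = mean(per_donor$mean_area_um2),
    mean_area_um2_sem = sem(per_donor$mean_area_um2),
    mean_length_um = mean(per_donor$mean_length_um),
    mean_length_um_sem = sem(per_donor$mean_length_um),
    mean_width_um = mean(per_donor$mean_width_um),
    mean_width_um_sem = sem(per_donor$mean_width_um)
  )
}

#' Scatter plot of the depth-area relationship
#'
#' @param measurements Per-event tibble with `area_um2` and `max_depth_um`.
#' @param area_quantile Cut used by [plateau_depth()]; drawn as a reference
#'   line together with the plateau estimate.
#' @return A ggplot.
#' @export
plot_depth_area <- function(measurements, area_quantile = 0.75) {
  p <- ggplot2::ggplot(
    measurements,
    ggplot2::aes(.data$area_um2, .data$max_depth_um)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "event area (µm²)", y = "max depth (µm)")
  if (nrow(measurements) >= 10L) {
    p <- p + ggplot2::geom_hline(
      yintercept = plateau_depth(measurements, area_quantile),
      linetype = "dashed"
    )
  }
  p
}
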