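#' Profile roughness metrics Ra and Rq
#'
#' `roughness_ra()` is the arithmetic-average roughness: the mean absolute
#' deviation of the profile from its mean line. `roughness_rq()` is the
#' root-mean-square roughness of the mean-centered profile. Both are the
#' standard profilometry definitions; for any profile `Rq >= Ra`
#' (Cauchy-Schwarz).
#'
#' @param profile Numeric vector of surface heights (um) along one scan line;
#'   at least 2 points.
#' @return Roughness in um.
#' @examples
#' roughness_ra(rep(3, 10)) # 0
#' roughness_ra(rep(c(2, -2), 50)) # 2
#' @export
roughness_ra <- function(profile) {
  check_profile(profile)
  mean(abs(profile - mean(profile)))
}

#' @rdname roughness_ra
#' @export
roughness_rq <- function(profile) {
  check_profile(profile)
  sqrt(mean((profile - mean(profile))^2))
}

check_profile <- function(profile) {
  if (!is.numeric(profile) || length(profile) < 2L) {
    stop("`profile` must be a numeric vector with >= 2 points", call. = FALSE)
  }
  if (!all(is.finite(profile))) stop("profile heights must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Surface roughness of a height map
#'
#' Computes Ra and Rq per grid row (each row is one scan line, matching a
#' stylus/confocal line scan across the surface) and averages over rows.
#'
#' @param map A `height_map`.
#' @return A one-row tibble: `Ra_um`, `Rq_um`, `scan_length_um` (row length),
#'   `n_profiles`.
#' @export
surface_roughness <- function(map) {
  ps <- pixel_size(map)
  h <- unclass(map)
  ra <- apply(h, 1L, roughness_ra)
  rq <- apply(h, 1L, roughness_rq)
  tibble::tibble(
    Ra_um = mean(ra),
    Rq_um = mean(rq),
    scan_length_um = ncol(h) * ps,
    n_profiles = nrow(h)
  )
}

#' Synthesize surface roughness to a target Ra
#'
#' Adds a smoothed Gaussian random field to the map, affinely rescaled so the
#' mean row-wise Ra equals `ra_target`. The field is white Gaussian noise
#' smoothed with an isotropic Gaussian kernel of standard deviation
#' `correlation_length` (um), applied by circular FFT convolution; one scale
#' factor then sets Ra exactly, so Rq is emergent (only `Rq >= Ra` is
#' guaranteed, since a single scale cannot pin Ra and Rq independently).
#' Deterministic given `seed`.
#'
#' @param map A `height_map` (typically flat).
#' @param ra_target Target mean row-wise Ra in um; 0 returns `map` unchanged.
#' @param correlation_length Kernel standard deviation in um; must be at least
#'   the pixel size.
#' @param seed Optional integer seed; the RNG state is restored afterwards.
#' @return A `height_map` with the rough texture added.
#' @export
synthesize_roughness <- function(map, ra_target, correlation_length = 20, seed = NULL) {
  if (!is.numeric(ra_target) || ra_target < 0) {
    stop("`ra_target` must be >= 0", call. = FALSE)
  }
  if (ra_target == 0) return(map)
  ps <- pixel_size(map)
  if (correlation_length < ps) {
    stop("`correlation_length` must be >= pixel_size", call. = FALSE)
  }
  nr <- nrow(map); nc <- ncol(map)
  noise <- with_optional_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  field <- gaussian_blur_circular(noise, sigma_px = correlation_length / ps)
  ra0 <- mean(apply(field, 1L, roughness_ra))
  if (ra0 == 0) stop("degenerate roughness field", call. = FALSE)
  height_map(unclass(map) + field * (ra_target / ra0), pixel_size = ps)
}

# Circular (periodic) separable Gaussian smoothing via FFT.
gaussian_blur_circular <- function(x, sigma_px) {
  # columns, then rows (transpose trick); inverse FFT normalized by n
  fft_conv <- function(m) {
    n <- nrow(m)
    off <- 0:(n - 1)
    k <- stats::dnorm(pmin(off, n - off), sd = sigma_px)
    k <- k / sum(k)
    kf <- stats::fft(k)
    Re(stats::mvfft(stats::mvfft(m) * kf, inverse = TRUE)) / n
  }
  t(fft_conv(t(fft_conv(x))))
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}
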