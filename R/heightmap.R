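#' Height-map representation of a mineralized substrate surface
#'
#' A `height_map` stores a rectangular grid of surface heights in micrometers.
#' Height 0 is the pristine surface plane; negative values are excavated
#' (resorbed) material. The grid is isotropic with `pixel_size` micrometers per
#' pixel; rows index the y axis, columns the x axis, with the origin at the
#' top-left pixel (row 1, column 1).
#'
#' @param heights Numeric matrix of heights in um. All values must be finite.
#' @param pixel_size Positive scalar, um per pixel (isotropic).
#'
#' @return An object of class `height_map`: the height matrix with attributes
#'   `pixel_size` (um/px).
#' @examples
#' hm <- height_map(matrix(0, 50, 50), pixel_size = 1)
#' map_area_cm2(hm)
#' @export
height_map <- function(heights, pixel_size = 1) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    stop("`heights` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(heights))) {
    stop("all heights must be finite", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  }
  structure(heights,
    pixel_size = as.numeric(pixel_size),
    class = c("height_map", "matrix", "array")
  )
}

#' Flat (pristine) substrate surface
#'
#' @param nx,ny Grid dimensions in pixels (columns, rows).
#' @param pixel_size um per pixel.
#' @return A `height_map` of all zeros, `ny` rows by `nx` columns.
#' @examples
#' make_flat_map(100, 100, pixel_size = 1)
#' @export
make_flat_map <- function(nx, ny, pixel_size = 1) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 1 || ny < 1) {
    stop("`nx` and `ny` must be >= 1", call. = FALSE)
  }
  height_map(matrix(0, nrow = as.integer(ny), ncol = as.integer(nx)),
    pixel_size = pixel_size
  )
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "<height_map> %d x %d px at %g um/px (%.4g cm^2); height range [%.3g, %.3g] um\n",
    nrow(x), ncol(x), pixel_size(x), map_area_cm2(x), min(x), max(x)
  ))
  invisible(x)
}

#' Pixel size of a height map
#' @param map A `height_map`.
#' @return um per pixel.
#' @export
pixel_size <- function(map) {
  ps <- attr(map, "pixel_size")
  if (is.null(ps)) stop("not a height_map: missing pixel_size", call. = FALSE)
  ps
}

#' Physical area of a height map in cm^2
#' @param map A `height_map`.
#' @return Area in cm^2 (1 cm^2 = 1e8 um^2).
#' @export
map_area_cm2 <- function(map) {
  length(map) * pixel_size(map)^2 / 1e8
}

assert_congruent <- function(a, b) {
  if (!identical(dim(a), dim(b)) || pixel_size(a) != pixel_size(b)) {
    stop("height maps must agree in shape and pixel size", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a height map to a long tibble
#'
#' One row per pixel with physical coordinates (pixel centers, um).
#'
#' @param x A `height_map`.
#' @param ... Unused.
#' @return A tibble with columns `x_um`, `y_um`, `height_um`.
#' @export
as_tibble.height_map <- function(x, ...) {
  ps <- pixel_size(x)
  tibble::tibble(
    x_um = rep((seq_len(ncol(x)) - 0.5) * ps, each = nrow(x)),
    y_um = rep((seq_len(nrow(x)) - 0.5) * ps, times = ncol(x)),
    height_um = as.vector(unclass(x))
  )
}

#' Write / read a height map as a CSV grid with a JSON sidecar
#'
#' The grid is stored as a headerless CSV of heights in um (rows = y); metadata
#' (pixel size and any extra fields such as seed or preset name) goes to
#' `<path>.json`.
#'
#' @param map A `height_map`.
#' @param path Path of the CSV file to write.
#' @param ... Extra metadata fields stored in the JSON sidecar.
#' @return `write_height_map()` returns `path` invisibly; `read_height_map()`
#'   returns a `height_map`.
#' @export
write_height_map <- function(map, path, ...) {
  utils::write.table(unclass(map), path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  meta <- c(list(pixel_size = pixel_size(map), nrow = nrow(map), ncol = ncol(map)), list(...))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(h) <- NULL
  height_map(h, pixel_size = meta$pixel_size)
}

#' Raster plot of a height map
#'
#' @param object A `height_map`.
#' @param ... Unused.
#' @return A ggplot: surface height in um over physical coordinates.
#' @export
autoplot.height_map <- function(object, ...) {
  df <- as_tibble.height_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$height_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "height (µm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}
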