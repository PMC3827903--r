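# Shared fixtures and independent oracles for the test suite.

# Voxel-sum oracle: removed volume of a run, in um^3.
voxel_removed_volume <- function(pristine, final) {
  sum(unclass(pristine) - unclass(final)) * pixel_size(pristine)^2
}

# Independent permutation two-sample test (difference of means statistic).
permutation_p <- function(a, b, n_perm = 2000, seed = 1) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pooled <- c(a, b)
    na <- length(a)
    hits <- replicate(n_perm, {
      idx <- sample.int(length(pooled), na)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
    })
    mean(hits)
  })
}

# A one-row trail event with deterministic straight cycles.
straight_trail_event <- function(x, y, length_um, width_um, depth_um, heading = 0) {
  p <- max(length_um - width_um, 3)
  n <- max(1L, round(p / 12))
  s <- p / n
  if (s > 21) {
    n <- as.integer(ceiling(p / 21)); s <- p / n
  } else if (s < 3) {
    s <- 3
  }
  tibble::tibble(
    type = "trail", center_x_um = x, center_y_um = y,
    length_um = length_um, width_um = width_um, depth_um = depth_um,
    orientation = heading,
    cycles = list(tibble::tibble(
      s_um = rep(s, n), w_um = width_um, target_depth_um = depth_um,
      heading = rep(heading, n)
    ))
  )
}

pit_event <- function(x, y, length_um, width_um, depth_um, orientation = 0) {
  tibble::tibble(
    type = "pit", center_x_um = x, center_y_um = y,
    length_um = length_um, width_um = width_um, depth_um = depth_um,
    orientation = orientation, cycles = list(NULL)
  )
}
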