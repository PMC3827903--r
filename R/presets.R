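#' Substrate presets for bone and dentin surfaces
#'
#' A substrate preset bundles the material/roughness condition of one in-vitro
#' culture surface: the resorption-event placement intensity (events/cm^2),
#' the pit:trail mix, the calibrated per-event geometry distribution, the
#' roughness targets and the adhered-cell density. The four built-in presets
#' are parameterized from printed histomorphometry of mature osteoclast
#' cultures on rough/smooth bone and elephant-ivory dentin:
#'
#' * `bone_rough`: 449 events/cm^2, Ra 6.27 / Rq 7.71 um, 11,400 cells/cm^2,
#'   geometry calibrated to mean area 580 um^2, length 53 um, width 9.5 um.
#' * `dentin_rough`: 3,134 events/cm^2, Ra 15.14 / Rq 18.51 um,
#'   17,200 cells/cm^2, geometry targets 700 um^2 / 59 um / 11 um.
#' * `bone_smooth`, `dentin_smooth`: Ra/Rq 1.05/2.27 and 3.75/5.21 um; no
#'   intensity was printed for smooth surfaces (only a non-significant trend to
#'   higher resorption on rough), so smooth presets use 0.75 x the rough
#'   intensity of the same material, with unchanged geometry.
#'
#' @param name One of `"bone_rough"`, `"bone_smooth"`, `"dentin_rough"`,
#'   `"dentin_smooth"`.
#' @return `substrate_preset()` returns a one-row tibble with columns `name`,
#'   `event_intensity` (events/cm^2), `trail_fraction`, `Ra_target_um`,
#'   `Rq_target_um`, `adhesion_density` (cells/cm^2) and a `geometry` list
#'   column holding [geometry_params()]. `substrate_presets()` returns all
#'   four rows.
#' @export
substrate_preset <- function(name) {
  presets <- substrate_presets()
  out <- presets[presets$name == name, ]
  if (nrow(out) != 1L) {
    stop("unknown preset; use one of: ", paste(presets$name, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' @rdname substrate_preset
#' @export
substrate_presets <- function() {
  geom_bone <- calibrate_geometry(
    target_mean_area = 580, target_mean_length = 53, target_mean_width = 9.5,
    n_mc = 0
  )
  geom_dentin <- calibrate_geometry(
    target_mean_area = 700, target_mean_length = 59, target_mean_width = 11,
    n_mc = 0
  )
  tibble::tibble(
    name = c("bone_rough", "bone_smooth", "dentin_rough", "dentin_smooth"),
    event_intensity = c(449, 0.75 * 449, 3134, 0.75 * 3134),
    trail_fraction = 0.5,
    Ra_target_um = c(6.27, 1.05, 15.14, 3.75),
    Rq_target_um = c(7.71, 2.27, 18.51, 5.21),
    adhesion_density = c(11400, 11400, 17200, 17200),
    geometry = list(geom_bone, geom_bone, geom_dentin, geom_dentin)
  )
}

#' Donor profile: donor-level resorption parameters
#'
#' Each donor's osteoclasts resorb down to an intrinsic maximum depth `D_max`:
#' pits deepen with growing area up to `D_max` and then grow only in area.
#' `donor_profile()` builds one profile; `reference_donors()` returns the six
#' donor/experiment plateau depths measured by confocal z-stacks on dentin
#' (experiment 1: 35, 55, 68 um; experiment 2, independent blood samples from
#' the same donors: 32, 59, 62 um).
#'
#' @param donor_id Identifier string.
#' @param D_max Maximum resorption depth, um (> 0).
#' @param D_max_sd Per-event spread of the depth ceiling, um (>= 0; default 0:
#'   every event shares the donor ceiling).
#' @param activity_scale Multiplier on the preset event intensity (default 1).
#' @return A one-row tibble with those columns.
#' @export
donor_profile <- function(donor_id, D_max, D_max_sd = 0, activity_scale = 1) {
  if (!is.numeric(D_max) || D_max <= 0) stop("`D_max` must be > 0", call. = FALSE)
  if (!is.numeric(D_max_sd) || D_max_sd < 0) stop("`D_max_sd` must be >= 0", call. = FALSE)
  tibble::tibble(
    donor_id = as.character(donor_id),
    D_max = as.numeric(D_max),
    D_max_sd = as.numeric(D_max_sd),
    activity_scale = as.numeric(activity_scale)
  )
}

#' @rdname donor_profile
#' @export
reference_donors <- function() {
  dplyr::bind_rows(
    donor_profile("donor1_expt1", 35),
    donor_profile("donor2_expt1", 55),
    donor_profile("donor3_expt1", 68),
    donor_profile("donor1_expt2", 32),
    donor_profile("donor2_expt2", 59),
    donor_profile("donor3_expt2", 62)
  )
}
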