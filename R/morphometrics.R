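# Flight-morphology indices.
#
# Five scalar indices summarize a queen's flight apparatus relative to the
# load she carries:
#   * flight muscle ratio (FMR)     thorax dry mass / total body dry mass
#   * wing loading                  body mass / total wing area   (mg/mm^2)
#   * abdomen drag reference area   abdomen volume^(2/3)          (mm^2)
#   * aspect ratio                  4 * forewing length^2 / wing area
#   * wing mass density             wing mass / wing area         (mg/mm^2)
# Abdomen volume uses the prolate-spheroid formula with the measured maximum
# length and height as the major and minor *diameters*:
#   V = (pi/6) * L * H^2.
# The semi-axis reading V = (4pi/3) * L * H^2 would overstate volume 8-fold
# and is deliberately not used; caliper-style measurements are full spans.

#' Flight muscle ratio
#'
#' Thorax dry mass divided by total body dry mass. Thorax mass is the
#' standard surrogate for flight muscle in ants; FMR is the strongest single
#' morphological predictor of insect flight performance.
#'
#' @param thorax_mass thorax dry mass, mg.
#' @param body_mass total body dry mass, mg; must exceed `thorax_mass`.
#' @return dimensionless ratio in (0, 1).
#' @export
flight_muscle_ratio <- function(thorax_mass, body_mass) {
  check_pos(thorax_mass, "thorax_mass"); check_pos(body_mass, "body_mass")
  if (any(thorax_mass >= body_mass)) {
    stop_fof("thorax_mass must be smaller than body_mass")
  }
  thorax_mass / body_mass
}

#' Wing loading
#'
#' Body dry mass divided by the combined area of all four wings (mg/mm^2).
#'
#' @param body_mass total body dry mass, mg.
#' @param total_wing_area combined area of all four wings, mm^2.
#' @return wing loading, mg/mm^2.
#' @export
wing_loading <- function(body_mass, total_wing_area) {
  check_pos(body_mass, "body_mass"); check_pos(total_wing_area, "total_wing_area")
  body_mass / total_wing_area
}

#' Abdomen volume (prolate spheroid)
#'
#' `V = (pi/6) * length * height^2`, treating the measured maximum abdomen
#' length and height as the major and minor diameters of a prolate spheroid.
#'
#' @param length abdomen length, mm (major axis; must be >= `height`).
#' @param height abdomen height, mm (minor axis).
#' @return volume, mm^3.
#' @export
abdomen_volume <- function(length, height) {
  check_pos(length, "length"); check_pos(height, "height")
  if (any(height > length)) {
    stop_fof("abdomen height must not exceed abdomen length")
  }
  (pi / 6) * length * height^2
}

#' Abdomen drag reference area
#'
#' Volumetric reference area, `volume^(2/3)` (mm^2): a two-dimensional
#' size-and-shape proxy proportional to the aerodynamic drag of the abdomen.
#'
#' @param volume abdomen volume, mm^3.
#' @return reference area, mm^2.
#' @export
drag_reference_area <- function(volume) {
  check_pos(volume, "volume")
  volume^(2 / 3)
}

#' Wing aspect ratio
#'
#' Wing narrowness: `4 * forewing_length^2 / total_wing_area`. Higher values
#' indicate narrower, aerodynamically more efficient wings.
#'
#' @param forewing_length forewing length, mm.
#' @param total_wing_area combined area of all four wings, mm^2.
#' @return dimensionless aspect ratio.
#' @export
aspect_ratio <- function(forewing_length, total_wing_area) {
  check_pos(forewing_length, "forewing_length")
  check_pos(total_wing_area, "total_wing_area")
  4 * forewing_length^2 / total_wing_area
}

#' Wing mass density
#'
#' Total wing dry mass divided by total wing area (mg/mm^2); a proxy for
#' wing stiffness and durability.
#'
#' @param wing_mass total wing dry mass, mg.
#' @param total_wing_area combined area of all four wings, mm^2.
#' @return density, mg/mm^2.
#' @export
wing_mass_density <- function(wing_mass, total_wing_area) {
  check_pos(wing_mass, "wing_mass"); check_pos(total_wing_area, "total_wing_area")
  wing_mass / total_wing_area
}

check_pos <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop_fof("%s must be finite and > 0", name)
  }
  invisible(TRUE)
}

PROFILE_REQUIRED <- c("thorax_mass", "body_mass", "total_wing_area",
                      "abdomen_length", "abdomen_height", "forewing_length",
                      "wing_mass")

#' Morphometric profile of queens
#'
#' Computes the five flight-morphology indices plus abdomen volume for each
#' queen record. All indices are computed per queen, never from group means;
#' group summaries should be taken over the per-queen values.
#'
#' @param morph data.frame of queen records (see [read_morphometry_table()]).
#' @return data.frame with columns `queen_id`, `species`, `caste`,
#'   `colony_id`, `abdomen_mass`, `fmr`, `wing_loading`, `abdomen_volume`,
#'   `drag_area`, `aspect_ratio`, `wing_mass_density`.
#' @export
profile_queens <- function(morph) {
  stopifnot(is.data.frame(morph))
  for (col in PROFILE_REQUIRED) {
    if (!col %in% names(morph)) stop_fof("morphometry lacks column %s", col)
    bad <- which(is.na(morph[[col]]))
    if (length(bad)) {
      stop_fof("queen %s is missing %s, required for profiling",
               morph$queen_id[bad[1]], col)
    }
  }
  vol <- abdomen_volume(morph$abdomen_length, morph$abdomen_height)
  data.frame(
    queen_id = morph$queen_id,
    species = morph$species %||% NA_character_,
    caste = morph$caste %||% NA_character_,
    colony_id = morph$colony_id %||% NA_character_,
    abdomen_mass = morph$abdomen_mass,
    fmr = flight_muscle_ratio(morph$thorax_mass, morph$body_mass),
    wing_loading = wing_loading(morph$body_mass, morph$total_wing_area),
    abdomen_volume = vol,
    drag_area = drag_reference_area(vol),
    aspect_ratio = aspect_ratio(morph$forewing_length, morph$total_wing_area),
    wing_mass_density = wing_mass_density(morph$wing_mass, morph$total_wing_area),
    stringsAsFactors = FALSE
  )
}
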