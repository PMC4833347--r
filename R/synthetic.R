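# Synthetic queen cohorts.
#
# The generator emulates the measured structure of two fire ant species
# (Solenopsis geminata, S. invicta), each with a claustral and a parasitic
# queen caste. Rather than drawing the derived indices directly, it draws a
# body frame (head, thorax, wings, residual mass) plus a variable abdomen, so
# that flight muscle ratio, wing loading and drag relationships with abdomen
# mass emerge mechanistically — the two castes are alternate nutrient loads
# on the same underlying body. That makes regression-slope recovery a genuine
# test rather than a tautology.
#
# Abdomen linear dimensions are derived from abdomen mass through a dry-mass
# density calibration: volume = mass / density, a per-queen shape ratio
# r = L/H >= 1 is drawn, and L, H are solved from the prolate-spheroid
# relation V = (pi/6) L H^2.

# Dry abdomen density calibration (mg/mm^3): chosen so the mean claustral
# S. geminata abdomen (5.652 mg) has a drag reference area of 4.82 mm^2,
# i.e. density = 5.652 / 4.82^(3/2). A calibration constant, not a
# measurement.
ABDOMEN_DRY_DENSITY <- 5.652 / 4.82^1.5

#' Synthetic caste specification
#'
#' Defines one species-by-caste cohort: sample sizes, trait means/SDs (units
#' mm / mg / mm^2), abdomen shape, density calibration, and the fraction of
#' trait SD attributable to between-colony variation. Total body mass is
#' never specified directly; it is the exact sum of the generated abdomen,
#' thorax, wing and residual masses.
#'
#' @param species `"geminata"` or `"invicta"`.
#' @param caste `"claustral"` or `"parasitic"`.
#' @param n_queens,n_colonies cohort size and number of source colonies
#'   (`n_queens >= n_colonies >= 1`).
#' @param head_width,abdomen_mass,thorax_mass,wing_mass,residual_body_mass,forewing_length,total_wing_area
#'   numeric `c(mean, sd)` pairs; SDs must be >= 0.
#' @param abdomen_shape_ratio `c(mean, sd)` of the length/height ratio
#'   (dimensionless, mean must be >= 1).
#' @param abdomen_dry_density dry-mass density used to convert abdomen mass
#'   to volume, mg/mm^3.
#' @param colony_sd_fraction between-colony SD as a fraction of total trait
#'   SD, in \[0, 1); the within-colony SD is scaled so the total is preserved.
#' @return object of class `caste_spec`.
#' @export
caste_spec <- function(species, caste, n_queens, n_colonies,
                       head_width, abdomen_mass, thorax_mass, wing_mass,
                       residual_body_mass, forewing_length, total_wing_area,
                       abdomen_shape_ratio = c(1.6, 0.08),
                       abdomen_dry_density = ABDOMEN_DRY_DENSITY,
                       colony_sd_fraction = 0.2) {
  species <- match.arg(species, SPECIES_LEVELS)
  caste <- match.arg(caste, CASTE_LEVELS)
  traits <- list(head_width = head_width, abdomen_mass = abdomen_mass,
                 thorax_mass = thorax_mass, wing_mass = wing_mass,
                 residual_body_mass = residual_body_mass,
                 forewing_length = forewing_length,
                 total_wing_area = total_wing_area,
                 abdomen_shape_ratio = abdomen_shape_ratio)
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (length(tr) != 2 || !all(is.finite(tr)) || tr[2] < 0 || tr[1] <= 0) {
      stop_fof("trait %s must be c(mean > 0, sd >= 0)", nm)
    }
  }
  if (abdomen_shape_ratio[1] < 1) {
    stop_fof("abdomen_shape_ratio mean must be >= 1 (length is the major axis)")
  }
  if (n_colonies < 1 || n_queens < n_colonies) {
    stop_fof("need n_queens >= n_colonies >= 1")
  }
  if (colony_sd_fraction < 0 || colony_sd_fraction >= 1) {
    stop_fof("colony_sd_fraction must be in [0, 1)")
  }
  if (abdomen_dry_density <= 0) stop_fof("abdomen_dry_density must be > 0")
  structure(list(
    species = species, caste = caste,
    n_queens = as.integer(n_queens), n_colonies = as.integer(n_colonies),
    traits = traits,
    abdomen_dry_density = abdomen_dry_density,
    colony_sd_fraction = colony_sd_fraction
  ), class = "caste_spec")
}

#' Reference caste specifications for the four fire ant queen types
#'
#' Cohort specifications parameterized from the published individual-average
#' trait table for claustral and parasitic queens of *S. geminata* (GC, GP)
#' and *S. invicta* (IC, IP): sample sizes, colony counts, head width,
#' abdomen mass, forewing length and wing area with their SDs. Thorax mass is
#' derived as mean FMR x mean dry mass, wing mass as mean wing mass density x
#' mean wing area, and residual (head/legs/petiole) mass as the remainder of
#' mean dry mass; their SDs scale the dry-mass SD proportionally.
#'
#' @return named list of [caste_spec()] objects (`GC`, `GP`, `IC`, `IP`).
#' @export
table2_specs <- function() {
  mk <- function(species, caste, n, ncol, hw, hw_sd, dry, dry_sd, abd, abd_sd,
                 fmr, wmd, fwl, fwl_sd, area, area_sd, drag) {
    thorax <- fmr * dry
    wing <- wmd * area
    residual <- dry - abd - thorax - wing
    stopifnot(residual > 0)
    sd_scale <- dry_sd / dry
    caste_spec(species, caste, n_queens = n, n_colonies = ncol,
               head_width = c(hw, hw_sd),
               abdomen_mass = c(abd, abd_sd),
               thorax_mass = c(thorax, thorax * sd_scale),
               wing_mass = c(wing, wing * sd_scale),
               residual_body_mass = c(residual, residual * sd_scale),
               forewing_length = c(fwl, fwl_sd),
               total_wing_area = c(area, area_sd),
               # density calibrated per caste so the cohort's mean abdomen
               # drag equals its reference value; parasitic abdomens are less
               # dense (little stored fat for the same cuticle envelope)
               abdomen_dry_density = abd / drag^1.5)
  }
  list(
    GC = mk("geminata", "claustral", 13, 3, 1.60, 0.058, 7.751, 0.95,
            5.652, 0.93, 0.13, 0.0042, 7.19, 0.14, 33.7, 1.1, 4.82),
    GP = mk("geminata", "parasitic", 38, 5, 1.56, 0.076, 4.101, 0.35,
            2.453, 0.24, 0.19, 0.0050, 6.66, 0.10, 29.1, 0.9, 3.66),
    IC = mk("invicta", "claustral", 58, 4, 1.41, 0.075, 7.242, 0.95,
            5.331, 0.91, 0.15, 0.0047, 6.48, 0.10, 27.0, 0.9, 4.76),
    IP = mk("invicta", "parasitic", 33, 6, 1.39, 0.062, 4.690, 0.75,
            2.745, 0.67, 0.24, 0.0059, 6.57, 0.12, 27.6, 1.0, 3.58)
  )
}

# Truncated-at-zero normal draw by rejection; exact mean when sd = 0.
rnorm_pos <- function(n, mean, sd, lower = .Machine$double.eps) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- which(x <= lower)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  stop_fof("truncated-normal rejection failed (mean %g, sd %g): mass at <= 0 too large",
           mean, sd)
}

#' Generate a synthetic morphometry cohort
#'
#' Draws `n_queens` records across `n_colonies`. Each trait is a shared
#' additive colony effect plus an individual truncated-positive normal draw;
#' body mass is the exact sum of abdomen, thorax, wing and residual masses;
#' abdomen length and height are solved from abdomen mass via the density
#' calibration and a per-queen shape ratio. All records satisfy the
#' morphometry invariants.
#'
#' @param spec a [caste_spec()].
#' @param seed integer seed; identical (spec, seed) gives identical output.
#' @return data.frame of queen records (schema of [read_morphometry_table()]).
#' @export
generate_morphometry <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "caste_spec"))
  n <- spec$n_queens
  tag <- paste0(toupper(substr(spec$species, 1, 1)),
                toupper(substr(spec$caste, 1, 1)))
  with_seed(derive_seed(seed, paste0("morph-", tag)), {
    colony <- rep_len(seq_len(spec$n_colonies), n)
    f <- spec$colony_sd_fraction
    draw_trait <- function(tr) {
      between <- f * tr[2]
      within <- tr[2] * sqrt(max(0, 1 - f^2))
      shift <- stats::rnorm(spec$n_colonies, 0, between)
      rnorm_pos(n, tr[1], within) + shift[colony]
    }
    tr <- spec$traits
    head_width <- pmax(draw_trait(tr$head_width), 1e-6)
    abdomen_mass <- pmax(draw_trait(tr$abdomen_mass), 1e-6)
    thorax_mass <- pmax(draw_trait(tr$thorax_mass), 1e-6)
    wing_mass <- pmax(draw_trait(tr$wing_mass), 1e-6)
    residual <- pmax(draw_trait(tr$residual_body_mass), 1e-6)
    forewing_length <- pmax(draw_trait(tr$forewing_length), 1e-6)
    total_wing_area <- pmax(draw_trait(tr$total_wing_area), 1e-6)
    shape <- pmax(draw_trait(tr$abdomen_shape_ratio), 1)
    body_mass <- abdomen_mass + thorax_mass + wing_mass + residual
    volume <- abdomen_mass / spec$abdomen_dry_density
    # V = (pi/6) r H^3 with L = r H  =>  H = (6V / (pi r))^(1/3)
    abdomen_height <- (6 * volume / (pi * shape))^(1 / 3)
    abdomen_length <- shape * abdomen_height
    data.frame(
      queen_id = sprintf("%s-q%03d", tag, seq_len(n)),
      species = spec$species,
      caste = spec$caste,
      colony_id = sprintf("%s-c%d", tag, colony),
      head_width = head_width,
      abdomen_length = abdomen_length,
      abdomen_height = abdomen_height,
      abdomen_mass = abdomen_mass,
      thorax_mass = thorax_mass,
      wing_mass = wing_mass,
      body_mass = body_mass,
      forewing_length = forewing_length,
      total_wing_area = total_wing_area,
      stringsAsFactors = FALSE
    )
  })
}

#' Tethered-flight generator specification
#'
#' The latent maximum total flight time of a queen with dry abdomen mass `a`
#' is `D_max(a) = max(intercept + slope * a, floor)`. A realized total is
#' `D_max * B` with `B` in (0, 1] drawn from a two-component Beta mixture:
#' with probability `p_full` the queen flies near her maximum
#' (`B ~ Beta(20 * opportunity_scale, 1)`), otherwise the flight is cut short
#' by non-biomechanical factors (`B ~ Beta(1, opportunity_scale)`). With the
#' defaults the 75th percentile of `B` is ~0.96, so the upper quartile of
#' totals tracks the endurance envelope while minimum durations stay short at
#' every mass. `opportunity_scale = Inf` forces `B = 1` exactly.
#'
#' @param endurance_intercept,endurance_slope envelope coefficients
#'   (s and s/mg; slope must be negative). Defaults are the published
#'   upper-quartile fit for claustral *S. invicta*.
#' @param duration_floor endurance floor in the heaviest queens, s.
#' @param opportunity_scale dimensionless shape of the sub-maximal duration
#'   distribution.
#' @param p_full probability a queen realizes (nearly) her full endurance.
#' @param n_bouts_max maximum take-off trials per queen.
#' @return object of class `flight_gen_spec`.
#' @export
flight_gen_spec <- function(endurance_intercept = 6742.350,
                            endurance_slope = -1096.915,
                            duration_floor = 160,
                            opportunity_scale = 1.5,
                            p_full = 0.35,
                            n_bouts_max = 6L) {
  if (endurance_slope >= 0) stop_fof("endurance_slope must be negative")
  if (duration_floor <= 0) stop_fof("duration_floor must be positive")
  if (opportunity_scale <= 0) stop_fof("opportunity_scale must be positive")
  if (p_full < 0 || p_full > 1) stop_fof("p_full must be in [0, 1]")
  if (n_bouts_max < 1) stop_fof("n_bouts_max must be >= 1")
  structure(list(endurance_intercept = endurance_intercept,
                 endurance_slope = endurance_slope,
                 duration_floor = duration_floor,
                 opportunity_scale = opportunity_scale,
                 p_full = p_full,
                 n_bouts_max = as.integer(n_bouts_max)),
            class = "flight_gen_spec")
}

#' Generate tethered-flight records for a cohort
#'
#' @param queens morphometry data.frame with `queen_id`, `colony_id` and
#'   `abdomen_mass` present.
#' @param spec a [flight_gen_spec()].
#' @param seed integer seed.
#' @return data.frame with one row per queen (`queen_id`, `colony_id`,
#'   `n_bouts`, `temperature_C`, `humidity_pct`, and a `bouts` list-column);
#'   bout durations sum to the realized total flight time.
#' @export
generate_flights <- function(queens, spec = flight_gen_spec(), seed = 1L) {
  stopifnot(inherits(spec, "flight_gen_spec"))
  if (any(is.na(queens$abdomen_mass))) {
    stop_fof("abdomen_mass must be present for all queens")
  }
  n <- nrow(queens)
  with_seed(derive_seed(seed, "flights"), {
    d_max <- pmax(spec$endurance_intercept + spec$endurance_slope * queens$abdomen_mass,
                  spec$duration_floor)
    if (is.infinite(spec$opportunity_scale)) {
      b <- rep(1, n)
    } else {
      full <- stats::runif(n) < spec$p_full
      b <- numeric(n)
      b[full] <- stats::rbeta(sum(full), 20 * spec$opportunity_scale, 1)
      b[!full] <- stats::rbeta(sum(!full), 1, spec$opportunity_scale)
      b <- pmin(pmax(b, 1e-3), 1)
    }
    total <- d_max * b
    k <- sample.int(spec$n_bouts_max, n, replace = TRUE)
    bouts <- lapply(seq_len(n), function(i) {
      w <- stats::rgamma(k[i], shape = 1)
      total[i] * w / sum(w)
    })
    out <- data.frame(
      queen_id = queens$queen_id,
      colony_id = queens$colony_id,
      n_bouts = k,
      temperature_C = round(stats::runif(n, 27.0, 29.6), 1),
      humidity_pct = round(stats::runif(n, 67, 79)),
      stringsAsFactors = FALSE
    )
    out$bouts <- bouts
    out
  })
}

#' Flatten a flight table to one row per bout
#'
#' Long-format companion to [generate_flights()] /[read_flight_table()],
#' suitable for CSV serialization.
#'
#' @param flights data.frame with a `bouts` list-column.
#' @return data.frame with columns `queen_id`, `colony_id`, `bout`,
#'   `duration_s`, `temperature_C`, `humidity_pct`.
#' @export
flights_to_long <- function(flights) {
  rows <- lapply(seq_len(nrow(flights)), function(i) {
    b <- flights$bouts[[i]]
    data.frame(queen_id = flights$queen_id[i],
               colony_id = flights$colony_id[i],
               bout = seq_along(b),
               duration_s = b,
               temperature_C = flights$temperature_C[i],
               humidity_pct = flights$humidity_pct[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
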