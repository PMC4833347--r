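# End-to-end pipeline: simulate or load data, profile queens, run the
# caste-comparison, regression, endurance and tradeoff stages, and write
# deterministic CSV reports with provenance headers.

#' Pipeline run configuration
#'
#' @param morph_path,flights_path optional CSV inputs; when `NULL` the
#'   synthetic generator supplies the data.
#' @param specs caste specifications for synthetic mode (default
#'   [table2_specs()]).
#' @param flight_spec a [flight_gen_spec()] for synthetic flights.
#' @param flight_cohort queen type flown in the endurance experiment
#'   (default `"IC"`, claustral *S. invicta*).
#' @param seed master seed; every stochastic stage derives a labelled child
#'   seed from it.
#' @param mode `"individual"`, `"colony"` or `"both"`: run comparisons on
#'   individual queens, colony averages, or both.
#' @param alpha_normality Shapiro–Wilk gate level.
#' @param tau upper quantile level for the endurance fits.
#' @param n_boot bootstrap resamples for quantile slope inference.
#' @param tradeoff a [tradeoff_config()].
#' @param out_dir output directory for CSV reports (`NULL` skips writing).
#' @return object of class `run_config`.
#' @export
run_config <- function(morph_path = NULL, flights_path = NULL,
                       specs = table2_specs(),
                       flight_spec = flight_gen_spec(),
                       flight_cohort = "IC",
                       seed = 1L,
                       mode = c("both", "individual", "colony"),
                       alpha_normality = 0.05,
                       tau = 0.75,
                       n_boot = 999,
                       tradeoff = tradeoff_config(),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  for (p in c(morph_path, flights_path)) {
    if (!is.null(p) && !file.exists(p)) stop_fof("input path not found: %s", p)
  }
  structure(list(morph_path = morph_path, flights_path = flights_path,
                 specs = specs, flight_spec = flight_spec,
                 flight_cohort = flight_cohort, seed = as.integer(seed),
                 mode = mode, alpha_normality = alpha_normality,
                 tau = tau, n_boot = n_boot, tradeoff = tradeoff,
                 out_dir = out_dir),
            class = "run_config")
}

#' Simulate queen cohorts to CSV fixtures
#'
#' Thin wrapper over the synthetic generator: draws every cohort in `specs`,
#' plus tethered flights for the chosen cohort, and writes `morph.csv` and
#' `flights.csv`.
#'
#' @param out_dir output directory (created if needed).
#' @param specs list of [caste_spec()] (default the four reference cohorts).
#' @param flight_spec a [flight_gen_spec()].
#' @param flight_cohort name of the cohort to fly (default `"IC"`).
#' @param seed master seed.
#' @return invisibly, list with `morph_path`, `flights_path`, and the
#'   generated data.frames.
#' @export
simulate_queens <- function(out_dir, specs = table2_specs(),
                            flight_spec = flight_gen_spec(),
                            flight_cohort = "IC", seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  morph <- do.call(rbind, lapply(specs, generate_morphometry, seed = seed))
  rownames(morph) <- NULL
  flights <- NULL
  if (!is.null(flight_cohort) && length(specs)) {
    cohort <- generate_morphometry(specs[[flight_cohort]], seed = seed)
    flights <- generate_flights(cohort, flight_spec, seed = seed)
  }
  prov <- list(stage = "simulate", seed = seed,
               config_digest = config_digest(list(specs, flight_spec)))
  morph_path <- file.path(out_dir, "morph.csv")
  write_results_table(morph, morph_path, provenance = prov)
  flights_path <- NULL
  if (!is.null(flights)) {
    flights_path <- file.path(out_dir, "flights.csv")
    write_results_table(flights_to_long(flights), flights_path, provenance = prov)
  }
  invisible(list(morph_path = morph_path, flights_path = flights_path,
                 morph = morph, flights = flights))
}

#' Run the full analysis pipeline
#'
#' Executes every stage against CSV inputs or synthetic cohorts: profiling,
#' caste-comparison summaries (individual and/or colony-average mode),
#' per-type regressions of each index on abdomen mass with Holm correction,
#' the tethered-flight endurance table, and the tradeoff curve and caste
#' contrast. With `out_dir` set, each table is written as a CSV with a
#' provenance header and a `manifest.csv` lists every output; identical
#' config + seed gives byte-identical files.
#'
#' @param config a [run_config()].
#' @return invisibly, named list of result data.frames (`profiles`,
#'   `caste_comparison_individual`, `caste_comparison_colony`,
#'   `regressions`, `colony_homogeneity`, `endurance`, `tradeoff_curve`,
#'   `caste_contrast`, `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  # --- inputs -----------------------------------------------------------
  if (!is.null(config$morph_path)) {
    morph <- read_morphometry_table(config$morph_path)
  } else {
    morph <- do.call(rbind, lapply(config$specs, generate_morphometry, seed = seed))
    rownames(morph) <- NULL
  }
  profiles <- profile_queens(morph)
  results <- list(profiles = profiles)
  # --- caste comparisons ------------------------------------------------
  if (config$mode %in% c("both", "individual")) {
    results$caste_comparison_individual <-
      caste_comparison_table(profiles, alpha_normality = config$alpha_normality)
  }
  if (config$mode %in% c("both", "colony")) {
    by_type <- split(profiles, paste(profiles$species, profiles$caste))
    col_prof <- do.call(rbind, lapply(by_type, colony_averages))
    rownames(col_prof) <- NULL
    results$caste_comparison_colony <-
      caste_comparison_table(col_prof, alpha_normality = config$alpha_normality)
  }
  results$regressions <- morphology_regression_table(profiles)
  # --- endurance --------------------------------------------------------
  if (!is.null(config$flights_path)) {
    flights <- read_flight_table(config$flights_path, morph)
    flown_profiles <- profiles
  } else {
    cohort <- generate_morphometry(config$specs[[config$flight_cohort]], seed = seed)
    flights <- generate_flights(cohort, config$flight_spec, seed = seed)
    flown_profiles <- profile_queens(cohort)
  }
  ds <- build_endurance_dataset(flights, flown_profiles)
  ds <- exclude_outliers(ds, k_sd = 3, apply = FALSE)
  results$colony_homogeneity <- colony_homogeneity(ds)
  results$endurance <- endurance_table(ds, tau = config$tau,
                                       n_boot = config$n_boot, seed = seed)
  # --- tradeoff ---------------------------------------------------------
  grid <- seq(1, 8, by = 0.1)
  results$tradeoff_curve <- tradeoff_curve(grid, config$tradeoff)
  results$caste_contrast <- caste_contrast(config = config$tradeoff)
  # --- reports ----------------------------------------------------------
  digest <- config_digest(config[setdiff(names(config), "out_dir")])
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- data.frame(table = character(0), path = character(0),
                           rows = integer(0), stringsAsFactors = FALSE)
    for (nm in names(results)) {
      path <- file.path(config$out_dir, paste0(nm, ".csv"))
      write_results_table(results[[nm]][!vapply(results[[nm]], is.list, logical(1))],
                          path,
                          provenance = list(stage = nm, seed = seed,
                                            config_digest = digest))
      manifest <- rbind(manifest, data.frame(
        table = nm, path = basename(path), rows = nrow(results[[nm]]),
        stringsAsFactors = FALSE))
    }
    write_results_table(manifest, file.path(config$out_dir, "manifest.csv"),
                        provenance = list(stage = "manifest", seed = seed,
                                          config_digest = digest))
    results$manifest <- manifest
  }
  invisible(results)
}
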