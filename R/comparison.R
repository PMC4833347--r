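# Caste-contrast battery: group summaries, normality-gated two-group tests,
# percent/fold contrasts, colony-average mode, per-type OLS of each index on
# abdomen mass, and Holm step-down familywise correction.

#' Summarize one group of trait values
#'
#' @param values numeric vector, n >= 1.
#' @return list with `n`, `mean`, `sd`, `median`, `iqr_low`, `iqr_high`
#'   (25th/75th percentiles, linear interpolation).
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_fof("summarize_group needs at least one value")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  list(n = length(values),
       mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0,
       median = stats::median(values),
       iqr_low = q[1], iqr_high = q[2])
}

# Shapiro-Wilk normality gate. Constant samples cannot be tested and are
# treated as non-normal (routed to the rank-based branch).
is_normal <- function(x, alpha) {
  if (length(unique(x)) < 3) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Compare a trait between claustral and parasitic queens
#'
#' Each group is gated through a Shapiro–Wilk normality test at
#' `alpha_normality`; if both pass, a two-sample t-test is used (Welch by
#' default), otherwise a two-group Kruskal–Wallis test (tie-corrected).
#' Contrasts are expressed relative to the parasitic group:
#' `percent_difference = 100 * (mean_c - mean_p) / mean_p` and
#' `fold_difference = mean_c / mean_p`.
#'
#' @param claustral,parasitic numeric trait values per caste (each n >= 3).
#' @param trait trait name carried into the result.
#' @param alpha_normality significance level of the normality gate.
#' @param transform `"identity"` or `"log"`: transform applied before the
#'   normality gate and test (summaries and contrasts stay on the raw scale).
#' @param t_variant `"welch"` (default) or `"student"` (pooled variance).
#' @return object of class `caste_comparison`: `trait`, `test_used`,
#'   `statistic`, `p_raw`, `claustral`/`parasitic` group summaries,
#'   `percent_difference`, `fold_difference`.
#' @export
compare_castes <- function(claustral, parasitic, trait = "trait",
                           alpha_normality = 0.05,
                           transform = c("identity", "log"),
                           t_variant = c("welch", "student")) {
  transform <- match.arg(transform)
  t_variant <- match.arg(t_variant)
  claustral <- claustral[!is.na(claustral)]
  parasitic <- parasitic[!is.na(parasitic)]
  if (length(claustral) < 3 || length(parasitic) < 3) {
    stop_fof("compare_castes needs >= 3 values per group (got %d and %d)",
             length(claustral), length(parasitic))
  }
  tc <- if (transform == "log") log(claustral) else claustral
  tp <- if (transform == "log") log(parasitic) else parasitic
  normal <- is_normal(tc, alpha_normality) && is_normal(tp, alpha_normality)
  if (normal) {
    ht <- stats::t.test(tc, tp, var.equal = (t_variant == "student"))
    test_used <- "t"
  } else {
    ht <- stats::kruskal.test(list(tc, tp))
    test_used <- "kruskal_wallis"
  }
  sc <- summarize_group(claustral); sp <- summarize_group(parasitic)
  structure(list(
    trait = trait,
    test_used = test_used,
    statistic = unname(ht$statistic),
    p_raw = unname(ht$p.value),
    claustral = sc, parasitic = sp,
    percent_difference = 100 * (sc$mean - sp$mean) / sp$mean,
    fold_difference = sc$mean / sp$mean
  ), class = "caste_comparison")
}

#' @export
print.caste_comparison <- function(x, ...) {
  cat(sprintf("Caste comparison: %s\n", x$trait))
  cat(sprintf("  claustral  mean %.4g (sd %.3g, n %d)\n",
              x$claustral$mean, x$claustral$sd, x$claustral$n))
  cat(sprintf("  parasitic  mean %.4g (sd %.3g, n %d)\n",
              x$parasitic$mean, x$parasitic$sd, x$parasitic$n))
  cat(sprintf("  %s test: statistic %.4g, p = %.3g\n",
              if (x$test_used == "t") "t" else "Kruskal-Wallis",
              x$statistic, x$p_raw))
  cat(sprintf("  claustral vs parasitic: %+.1f%% (%.3g-fold)\n",
              x$percent_difference, x$fold_difference))
  invisible(x)
}

#' Average queens within colonies
#'
#' Collapses a per-queen table to one row per colony (each sampled colony
#' treated as a single data point), averaging every numeric column and
#' keeping the first value of character columns. Guards against
#' pseudoreplication from sister queens.
#'
#' @param df data.frame with a `colony_id` column.
#' @return data.frame with one row per colony.
#' @export
colony_averages <- function(df) {
  if (!"colony_id" %in% names(df)) stop_fof("colony_id column required")
  split_idx <- split(seq_len(nrow(df)), df$colony_id)
  rows <- lapply(names(split_idx), function(cid) {
    sub <- df[split_idx[[cid]], , drop = FALSE]
    out <- lapply(names(sub), function(col) {
      v <- sub[[col]]
      if (is.numeric(v)) mean(v, na.rm = TRUE) else v[1]
    })
    names(out) <- names(sub)
    out$colony_id <- cid
    out$n_queens <- nrow(sub)
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' OLS regression of a flight-morphology index on abdomen mass
#'
#' @param abdomen_mass predictor, dry mg.
#' @param response index values (same length, n >= 3).
#' @param response_name,group labels carried into the result.
#' @return object of class `fof_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_raw` (two-sided slope test), `p_corrected` (NA until a family
#'   correction is applied), `n`.
#' @export
regress_on_abdomen_mass <- function(abdomen_mass, response,
                                    response_name = "index", group = "") {
  ok <- is.finite(abdomen_mass) & is.finite(response)
  x <- abdomen_mass[ok]; y <- response[ok]
  if (length(x) < 3) stop_fof("regression needs >= 3 points")
  if (stats::sd(x) == 0) stop_fof("degenerate predictor: all abdomen masses equal")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1 && !is.nan(sm$coefficients[2, 4])) {
    sm$coefficients[2, 4]
  } else NA_real_
  structure(list(
    response = response_name, predictor = "abdomen_mass", group = group,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_raw = p, p_corrected = NA_real_,
    n = length(x)
  ), class = "fof_fit")
}

#' @export
print.fof_fit <- function(x, ...) {
  cat(sprintf("OLS %s ~ %s%s: slope %.4g, intercept %.4g, r^2 %.4f, p %.3g (n %d)\n",
              x$response, x$predictor,
              if (nzchar(x$group)) paste0(" [", x$group, "]") else "",
              x$slope, x$intercept, x$r_squared, x$p_raw, x$n))
  invisible(x)
}

#' Holm–Bonferroni step-down correction
#'
#' Step-down familywise error control: the i-th smallest of m p-values is
#' multiplied by (m - i + 1), monotonicity is enforced by a running maximum,
#' values are capped at 1 and returned in input order. Equals the Bonferroni
#' correction when all p-values are identical.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return corrected p-values, same order as the input.
#' @export
holm_correction <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_fof("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Table of index-on-abdomen-mass regressions with Holm correction
#'
#' Fits each requested index against abdomen mass separately within each
#' queen type, then applies the Holm correction per index across the queen
#' types (family size = number of types), mirroring the familywise scheme of
#' the published regression table.
#'
#' @param profiles profile data.frame from [profile_queens()] (must carry
#'   `abdomen_mass` and a queen-type label column).
#' @param indices index columns to regress (default FMR, wing loading, drag).
#' @param type_col column defining queen types (default species x caste).
#' @return data.frame with one row per index x type: slope, intercept, r^2,
#'   raw and Holm-corrected p, n.
#' @export
morphology_regression_table <- function(profiles,
                                        indices = c("fmr", "wing_loading", "drag_area"),
                                        type_col = NULL) {
  if (is.null(type_col)) {
    profiles$queen_type <- paste(profiles$species, profiles$caste, sep = "_")
    type_col <- "queen_type"
  }
  types <- unique(profiles[[type_col]])
  rows <- list()
  for (idx in indices) {
    fits <- lapply(types, function(tp) {
      sub <- profiles[profiles[[type_col]] == tp, ]
      regress_on_abdomen_mass(sub$abdomen_mass, sub[[idx]],
                              response_name = idx, group = tp)
    })
    p_corr <- holm_correction(vapply(fits, `[[`, numeric(1), "p_raw"))
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        response = idx, queen_type = types[i], n = f$n,
        slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
        p_raw = f$p_raw, p_corrected = p_corr[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Caste-comparison summary table for a set of traits
#'
#' Runs [compare_castes()] for each trait and stacks the results into a
#' result table (one row per trait per species).
#'
#' @param profiles data.frame with `species`, `caste` and the trait columns.
#' @param traits trait column names to compare.
#' @param ... passed to [compare_castes()].
#' @return data.frame with group means/SDs, test used, raw p, percent and
#'   fold differences.
#' @export
caste_comparison_table <- function(profiles,
                                   traits = c("abdomen_mass", "fmr", "wing_loading",
                                              "drag_area", "aspect_ratio",
                                              "wing_mass_density"),
                                   ...) {
  rows <- list()
  for (sp in unique(profiles$species)) {
    sub <- profiles[profiles$species == sp, ]
    for (tr in traits) {
      cmp <- compare_castes(sub[[tr]][sub$caste == "claustral"],
                            sub[[tr]][sub$caste == "parasitic"],
                            trait = tr, ...)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, trait = tr,
        n_claustral = cmp$claustral$n, n_parasitic = cmp$parasitic$n,
        mean_claustral = cmp$claustral$mean, sd_claustral = cmp$claustral$sd,
        mean_parasitic = cmp$parasitic$mean, sd_parasitic = cmp$parasitic$sd,
        test_used = cmp$test_used, statistic = cmp$statistic, p_raw = cmp$p_raw,
        percent_difference = cmp$percent_difference,
        fold_difference = cmp$fold_difference,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
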