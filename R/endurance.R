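# Live-flight endurance analysis.
#
# Total flight time per queen, outlier flagging, colony-homogeneity checks,
# upper-quartile (tau = 0.75) quantile regression of total flight time on
# abdomen mass / log FMR / wing loading, plus OLS and Spearman comparators.
#
# The quantile fit minimizes the check loss
#   sum_i rho_tau(y_i - b0 - b1 x_i),   rho_tau(u) = u * (tau - 1[u < 0]).
# For the straight-line model an optimal solution always interpolates at
# least two data points with distinct x (a basic solution of the equivalent
# linear program), so the solver enumerates every line through a pair of
# points and returns the global minimizer exactly. Datasets here are small
# (tens to a few hundred queens), where exhaustive search is both exact and
# fast.

#' Total flight time of one queen
#'
#' Sum of all tethered-flight bout durations (the queen's six consecutive
#' take-off trials, or fewer if she stopped flying).
#'
#' @param bouts numeric vector of bout durations in seconds (>= 1 bout), or a
#'   list of such vectors.
#' @return total seconds (vector if `bouts` is a list).
#' @export
total_flight_time <- function(bouts) {
  if (is.list(bouts)) return(vapply(bouts, total_flight_time, numeric(1)))
  if (!length(bouts) || any(!is.finite(bouts) | bouts <= 0)) {
    stop_fof("each flight record needs >= 1 strictly positive bout")
  }
  sum(bouts)
}

#' Assemble the endurance dataset
#'
#' Joins per-queen flight totals to post-flight morphometric profiles,
#' producing the analysis table: total flight time, abdomen mass, natural-log
#' flight muscle ratio, wing loading and colony identity.
#'
#' @param flights flight table ([read_flight_table()] / [generate_flights()]).
#' @param profiles profiles from [profile_queens()].
#' @return data.frame with one row per flown queen and columns
#'   `queen_id`, `colony_id`, `total_flight_time`, `abdomen_mass`, `log_fmr`,
#'   `wing_loading`, `excluded`, `exclusion_reason`.
#' @export
build_endurance_dataset <- function(flights, profiles) {
  idx <- match(flights$queen_id, profiles$queen_id)
  if (anyNA(idx)) {
    stop_fof("no morphometric profile for queen(s): %s",
             paste(flights$queen_id[is.na(idx)], collapse = ", "))
  }
  data.frame(
    queen_id = flights$queen_id,
    colony_id = flights$colony_id,
    total_flight_time = total_flight_time(flights$bouts),
    abdomen_mass = profiles$abdomen_mass[idx],
    log_fmr = log(profiles$fmr[idx]),
    wing_loading = profiles$wing_loading[idx],
    excluded = FALSE,
    exclusion_reason = "",
    stringsAsFactors = FALSE
  )
}

#' Flag (and optionally drop) abdomen-mass outliers
#'
#' Mirrors the handling of a just-eclosed queen with an anomalously light
#' abdomen: queens are flagged when their abdomen mass falls below an
#' absolute threshold or more than `k_sd` SDs from the cohort mean. The
#' default only flags; records are removed only with explicit
#' `apply = TRUE`, and every exclusion carries its reason.
#'
#' @param dataset endurance data.frame from [build_endurance_dataset()].
#' @param min_abdomen_mass absolute threshold in mg (NULL disables).
#' @param k_sd SD multiple for the distance rule (NULL disables; default 3).
#' @param apply drop flagged rows (`TRUE`) or just mark them (`FALSE`).
#' @return dataset with updated `excluded`/`exclusion_reason`; if `apply`,
#'   flagged rows removed and recorded in the `"exclusions"` attribute.
#' @export
exclude_outliers <- function(dataset, min_abdomen_mass = NULL, k_sd = 3,
                             apply = FALSE) {
  if (!nrow(dataset)) return(dataset)
  reason <- rep("", nrow(dataset))
  a <- dataset$abdomen_mass
  if (!is.null(min_abdomen_mass)) {
    hit <- a < min_abdomen_mass
    reason[hit] <- sprintf("abdomen mass %.3f mg below threshold %.3f mg",
                           a[hit], min_abdomen_mass)
  }
  if (!is.null(k_sd) && length(a) > 1 && stats::sd(a) > 0) {
    z <- abs(a - mean(a)) / stats::sd(a)
    hit <- z > k_sd & reason == ""
    reason[hit] <- sprintf("abdomen mass %.3f mg is %.1f SD from cohort mean",
                           a[hit], z[hit])
  }
  dataset$excluded <- reason != ""
  dataset$exclusion_reason <- reason
  if (apply) {
    dropped <- dataset[dataset$excluded, , drop = FALSE]
    dataset <- dataset[!dataset$excluded, , drop = FALSE]
    rownames(dataset) <- NULL
    attr(dataset, "exclusions") <- dropped
  }
  dataset
}

#' Colony-homogeneity checks for the flight experiment
#'
#' Tests whether queens from different colonies differ in the analysis
#' variables: Kruskal–Wallis across colonies for each variable, or a one-way
#' ANOVA for variables declared normal after transformation (by default the
#' log flight muscle ratio). Recommends pooling when no variable differs at
#' `alpha`.
#'
#' @param dataset endurance data.frame (>= 2 colonies).
#' @param variables variables to check.
#' @param normal_vars subset of `variables` tested by ANOVA instead.
#' @param alpha significance level for the pooling recommendation.
#' @return data.frame of per-variable tests with a `"recommendation"`
#'   attribute (`"pool"` or `"do_not_pool"`).
#' @export
colony_homogeneity <- function(dataset,
                               variables = c("total_flight_time", "abdomen_mass",
                                             "log_fmr", "wing_loading"),
                               normal_vars = "log_fmr",
                               alpha = 0.05) {
  g <- factor(dataset$colony_id)
  if (nlevels(g) < 2) stop_fof("colony_homogeneity needs >= 2 colonies")
  rows <- lapply(variables, function(v) {
    x <- dataset[[v]]
    if (v %in% normal_vars) {
      fit <- stats::aov(x ~ g)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      test <- "anova"
      statv <- summary(fit)[[1]][["F value"]][1]
    } else {
      ht <- stats::kruskal.test(x, g)
      p <- ht$p.value
      statv <- unname(ht$statistic)
      test <- "kruskal_wallis"
    }
    data.frame(variable = v, test = test, statistic = statv, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "recommendation") <-
    if (all(out$p >= alpha, na.rm = TRUE)) "pool" else "do_not_pool"
  out
}

rho_tau <- function(u, tau) u * (tau - (u < 0))

# Check-loss objective of a line over the data.
check_loss <- function(x, y, intercept, slope, tau) {
  sum(rho_tau(y - intercept - slope * x, tau))
}

#' Linear quantile regression by exact point-pair search
#'
#' Fits `y ~ intercept + slope * x` at quantile level `tau` by minimizing the
#' asymmetric check loss. Every line through two data points with distinct x
#' is evaluated (an optimal basic solution interpolates two such points), so
#' the returned fit is a global minimizer. Ties in the objective are broken
#' deterministically (smallest |slope|, then smallest intercept). Slope
#' inference uses a seeded xy-pairs bootstrap.
#'
#' @param x predictor values (not all equal, n >= 3).
#' @param y response values (total flight times, s).
#' @param tau quantile level in (0, 1); 0.75 targets the upper envelope of
#'   maximum performance.
#' @param n_boot bootstrap resamples for the slope p-value (default 9999;
#'   0 skips inference).
#' @param seed integer seed for the bootstrap.
#' @return object of class `quantile_fit`: `tau`, `intercept`, `slope`,
#'   `objective` (check loss at the optimum), `n`, `n_candidates`,
#'   `n_below`/`n_above` (residual sign counts), `p_raw` and `p_corrected`.
#' @export
fit_quantile <- function(x, y, tau = 0.75, n_boot = 9999, seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_fof("quantile regression needs >= 3 points")
  if (tau <= 0 || tau >= 1) stop_fof("tau must lie strictly in (0, 1)")
  if (max(x) == min(x)) stop_fof("degenerate predictor: all x equal")
  sol <- qr_pair_search(x, y, tau)
  p_raw <- NA_real_
  if (n_boot > 0) {
    bseed <- derive_seed(seed, sprintf("qrboot-%g", tau))
    slopes <- with_seed(bseed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (max(x[idx]) == min(x[idx])) return(NA_real_)
        qr_pair_search(x[idx], y[idx], tau)$slope
      }, numeric(1))
    })
    slopes <- slopes[!is.na(slopes)]
    B <- length(slopes)
    # two-sided bootstrap p for H0: slope = 0, with +1 continuity correction
    p_raw <- min(1, 2 * min((sum(slopes <= 0) + 1) / (B + 1),
                            (sum(slopes >= 0) + 1) / (B + 1)))
  }
  res <- y - sol$intercept - sol$slope * x
  # interpolated points carry O(eps)-scale round-off; count them as on-line
  on_tol <- 1e-8 * max(1, max(abs(y)))
  structure(list(
    tau = tau, intercept = sol$intercept, slope = sol$slope,
    objective = sol$objective, n = n, n_candidates = sol$n_candidates,
    n_below = sum(res < -on_tol), n_above = sum(res > on_tol),
    n_boot = if (n_boot > 0) n_boot else 0L,
    p_raw = p_raw, p_corrected = NA_real_
  ), class = "quantile_fit")
}

# Exhaustive search over lines through all point pairs with distinct x.
# Vectorized: candidate objectives are computed in chunks to bound memory.
qr_pair_search <- function(x, y, tau) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  dx <- x[pairs[2, ]] - x[pairs[1, ]]
  keep <- dx != 0
  if (!any(keep)) stop_fof("degenerate predictor: all x equal")
  i1 <- pairs[1, keep]; i2 <- pairs[2, keep]
  slope <- (y[i2] - y[i1]) / (x[i2] - x[i1])
  intercept <- y[i1] - slope * x[i1]
  m <- length(slope)
  obj <- numeric(m)
  chunk <- max(1L, floor(5e6 / n))
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    resid <- outer(y, rep(1, length(idx))) -
      outer(rep(1, n), intercept[idx]) - outer(x, slope[idx])
    obj[idx] <- colSums(resid * (tau - (resid < 0)))
  }
  best <- which(obj <= min(obj) + 1e-12)
  best <- best[order(abs(slope[best]), intercept[best])][1]
  list(intercept = intercept[best], slope = slope[best],
       objective = obj[best], n_candidates = m)
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression (tau = %.2f, n = %d)\n", x$tau, x$n))
  cat(sprintf("  intercept %.3f, slope %.3f (check loss %.4f)\n",
              x$intercept, x$slope, x$objective))
  cat(sprintf("  residuals below/above line: %d / %d\n", x$n_below, x$n_above))
  if (!is.na(x$p_raw)) {
    cat(sprintf("  bootstrap slope p = %.3g (%d resamples)\n", x$p_raw, x$n_boot))
  }
  invisible(x)
}

#' OLS and Spearman comparators for one predictor
#'
#' Central-tendency companions to the quantile fit: ordinary least squares
#' slope/intercept/r^2/p and Spearman's rank correlation for the same pairs.
#'
#' @param x predictor values. @param y total flight times.
#' @return list with `ols` (an `fof_fit`) and `spearman` (`rho`, `p_raw`).
#' @export
fit_ols_and_rank <- function(x, y) {
  ols <- regress_on_abdomen_mass(x, y, response_name = "total_flight_time")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(ols = ols,
       spearman = list(rho = unname(ct$estimate), p_raw = ct$p.value))
}

#' Endurance analysis table (quantile, OLS and rank methods)
#'
#' Runs, for each of the three predictors (abdomen mass, log flight muscle
#' ratio, wing loading), the tau-quantile regression, the OLS regression and
#' the Spearman correlation of total flight time, then applies the Holm
#' correction across the three predictors separately within each method
#' (family size 3).
#'
#' @param dataset endurance data.frame (excluded rows are dropped).
#' @param tau quantile level (default 0.75).
#' @param n_boot bootstrap resamples for quantile slope p-values.
#' @param seed integer master seed.
#' @return data.frame with one row per method x predictor.
#' @export
endurance_table <- function(dataset, tau = 0.75, n_boot = 9999, seed = 1L) {
  dataset <- dataset[!dataset$excluded, , drop = FALSE]
  predictors <- c("abdomen_mass", "log_fmr", "wing_loading")
  y <- dataset$total_flight_time
  qfits <- lapply(predictors, function(p) {
    fit_quantile(dataset[[p]], y, tau = tau, n_boot = n_boot,
                 seed = derive_seed(seed, p))
  })
  cfits <- lapply(predictors, function(p) fit_ols_and_rank(dataset[[p]], y))
  qp <- holm_correction(vapply(qfits, `[[`, numeric(1), "p_raw"))
  op <- holm_correction(vapply(cfits, function(f) f$ols$p_raw, numeric(1)))
  sp <- holm_correction(vapply(cfits, function(f) f$spearman$p_raw, numeric(1)))
  rows <- list()
  for (i in seq_along(predictors)) {
    rows[[length(rows) + 1]] <- data.frame(
      method = "quantile", predictor = predictors[i], tau = tau,
      intercept = qfits[[i]]$intercept, slope = qfits[[i]]$slope,
      r_squared = NA_real_, statistic = NA_real_,
      p_raw = qfits[[i]]$p_raw, p_corrected = qp[i],
      n = qfits[[i]]$n, stringsAsFactors = FALSE)
  }
  for (i in seq_along(predictors)) {
    f <- cfits[[i]]$ols
    rows[[length(rows) + 1]] <- data.frame(
      method = "ols", predictor = predictors[i], tau = NA_real_,
      intercept = f$intercept, slope = f$slope,
      r_squared = f$r_squared, statistic = NA_real_,
      p_raw = f$p_raw, p_corrected = op[i], n = f$n,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(predictors)) {
    s <- cfits[[i]]$spearman
    rows[[length(rows) + 1]] <- data.frame(
      method = "spearman", predictor = predictors[i], tau = NA_real_,
      intercept = NA_real_, slope = NA_real_,
      r_squared = NA_real_, statistic = s$rho,
      p_raw = s$p_raw, p_corrected = sp[i], n = nrow(dataset),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
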