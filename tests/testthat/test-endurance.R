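# Endurance analysis: totals, outlier flagging, colony checks, quantile fit.

test_that("total flight time sums bouts and rejects invalid records", {
  expect_equal(total_flight_time(60), 60)
  expect_equal(total_flight_time(rep(10, 6)), 60)
  six <- c(1000, 900, 800, 700, 600, 900)  # six bouts summing to 4900
  expect_equal(total_flight_time(six), 4900)
  expect_equal(total_flight_time(list(c(1, 2), c(3))), c(3, 3))
  expect_error(total_flight_time(numeric(0)), "bout")
  expect_error(total_flight_time(c(10, 0)), "positive")
})

test_that("outlier rule flags an anomalously light abdomen without dropping by default", {
  ds <- data.frame(queen_id = sprintf("q%d", 1:12), colony_id = "c1",
                   total_flight_time = 1000,
                   abdomen_mass = c(1.5, seq(5.0, 6.0, length.out = 11)),
                   log_fmr = -1.9, wing_loading = 0.27,
                   excluded = FALSE, exclusion_reason = "",
                   stringsAsFactors = FALSE)
  # the 1.5 mg queen is > 3 SD below the cohort mean of this constructed set
  z <- abs(1.5 - mean(ds$abdomen_mass)) / sd(ds$abdomen_mass)
  expect_gt(z, 3)
  flagged <- exclude_outliers(ds, k_sd = 3, apply = FALSE)
  expect_equal(sum(flagged$excluded), 1)
  expect_equal(flagged$queen_id[flagged$excluded], "q1")
  expect_match(flagged$exclusion_reason[1], "SD")
  expect_equal(nrow(flagged), 12)  # nothing dropped without assent
  applied <- exclude_outliers(ds, k_sd = 3, apply = TRUE)
  expect_equal(nrow(applied), 11)
  expect_equal(nrow(attr(applied, "exclusions")), 1)
  # rule off: identical dataset
  off <- exclude_outliers(ds, k_sd = NULL)
  expect_false(any(off$excluded))
  # absolute threshold route
  abs_rule <- exclude_outliers(ds, min_abdomen_mass = 2.0, k_sd = NULL)
  expect_equal(sum(abs_rule$excluded), 1)
  # empty dataset passes through
  expect_equal(nrow(exclude_outliers(ds[0, ])), 0)
})

test_that("colony homogeneity recommends pooling iff colonies are exchangeable", {
  set.seed(19)
  n <- 60
  same <- data.frame(colony_id = rep(c("a", "b", "c"), each = n / 3),
                     total_flight_time = rexp(n, 1 / 1000),
                     abdomen_mass = rnorm(n, 5.3, 0.9),
                     log_fmr = rnorm(n, -1.9, 0.15),
                     wing_loading = rnorm(n, 0.27, 0.03))
  hom <- colony_homogeneity(same)
  expect_equal(attr(hom, "recommendation"), "pool")
  expect_setequal(hom$test[hom$variable == "log_fmr"], "anova")
  expect_true(all(hom$test[hom$variable != "log_fmr"] == "kruskal_wallis"))

  apart <- same
  apart$total_flight_time <- apart$total_flight_time +
    rep(c(0, 5000, 10000), each = n / 3)  # disjoint supports
  hom2 <- colony_homogeneity(apart)
  expect_equal(attr(hom2, "recommendation"), "do_not_pool")
  expect_lt(hom2$p[hom2$variable == "total_flight_time"], 1e-6)

  expect_error(colony_homogeneity(same[same$colony_id == "a", ]), ">= 2")
})

test_that("quantile fit interpolates collinear data exactly for any tau", {
  x <- c(1, 2, 3, 4, 5); y <- 2 + 3 * x
  for (tau in c(0.25, 0.5, 0.75)) {
    f <- fit_quantile(x, y, tau, n_boot = 0)
    expect_equal(f$slope, 3); expect_equal(f$intercept, 2)
    expect_equal(f$objective, 0)
  }
})

test_that("quantile solver matches the brute-force point-pair oracle", {
  # the six-point heteroscedastic set with duplicated x values
  x <- c(1, 1, 2, 2, 3, 3); y <- c(1, 5, 2, 6, 3, 7)
  f <- fit_quantile(x, y, 0.75, n_boot = 0)
  expect_equal(f$objective, oracle_qr_objective(x, y, 0.75), tolerance = 1e-9)
  # 200 random small datasets, several quantile levels
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    x <- round(runif(n, 0, 10), 2)
    if (length(unique(x)) < 2) next
    y <- round(rnorm(n, 2 * x, 3), 2)
    tau <- sample(c(0.25, 0.5, 0.75, 0.9), 1)
    f <- fit_quantile(x, y, tau, n_boot = 0)
    expect_equal(f$objective, oracle_qr_objective(x, y, tau), tolerance = 1e-9)
  }
})

test_that("quantile fit beats the OLS line under the check loss and brackets tau*n", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    x <- runif(n, 3, 7)
    y <- 6000 - 1000 * x + rnorm(n, 0, 400) * runif(n)
    tau <- sample(c(0.5, 0.75), 1)
    f <- fit_quantile(x, y, tau, n_boot = 0)
    ols <- stats::lm(y ~ x)
    ols_obj <- sum((y - fitted(ols)) * (tau - ((y - fitted(ols)) < 0)))
    expect_lte(f$objective, ols_obj + 1e-9)
    # subgradient optimality: strict residual counts bracket tau * n
    expect_lte(f$n_below, tau * n)
    expect_lte(f$n_above, (1 - tau) * n)
  }
})

test_that("tau = 0.5 fit is the least-absolute-deviations solution", {
  set.seed(31)
  x <- runif(12, 0, 5); y <- 1 + 2 * x + rt(12, 3)
  f <- fit_quantile(x, y, 0.5, n_boot = 0)
  # LAD objective via the same brute-force oracle at tau = 0.5 equals
  # half the minimal absolute-residual sum
  expect_equal(f$objective, oracle_qr_objective(x, y, 0.5), tolerance = 1e-9)
  lad <- sum(abs(y - f$intercept - f$slope * x)) / 2
  expect_equal(f$objective, lad, tolerance = 1e-9)
})

test_that("degenerate predictors and bad tau are refused", {
  expect_error(fit_quantile(rep(1, 5), 1:5, 0.75, n_boot = 0), "degenerate")
  expect_error(fit_quantile(1:5, 1:5, 1.2, n_boot = 0), "tau")
  expect_error(fit_quantile(1:2, 1:2, 0.75, n_boot = 0), ">= 3")
})

test_that("bootstrap slope inference is seeded and detects a real envelope slope", {
  set.seed(37)
  x <- runif(40, 3.5, 6.5)
  q <- data.frame(queen_id = sprintf("q%d", 1:40), colony_id = "c1",
                  abdomen_mass = x, stringsAsFactors = FALSE)
  fl <- generate_flights(q, flight_gen_spec(), seed = 41)
  y <- total_flight_time(fl$bouts)
  f1 <- fit_quantile(x, y, 0.75, n_boot = 299, seed = 5)
  f2 <- fit_quantile(x, y, 0.75, n_boot = 299, seed = 5)
  expect_identical(f1$p_raw, f2$p_raw)  # determinism
  expect_lt(f1$p_raw, 0.10)             # negative envelope slope is detectable
  expect_lt(f1$slope, 0)
})

test_that("rank and OLS comparators distinguish monotone from linear structure", {
  x <- 1:10
  y <- exp(x / 2)  # perfectly monotone, curved
  f <- fit_ols_and_rank(x, y)
  expect_equal(f$spearman$rho, 1)
  expect_lt(f$ols$r_squared, 1)
  y2 <- 10 - 2 * x
  f2 <- suppressWarnings(fit_ols_and_rank(x, y2))  # exact-line fixture
  expect_equal(f2$spearman$rho, -1)
  expect_lt(f2$ols$slope, 0)
})

test_that("endurance table runs all three methods with per-method Holm families", {
  spec <- table2_specs()$IC
  m <- generate_morphometry(spec, seed = 43)
  fl <- generate_flights(m, flight_gen_spec(), seed = 43)
  ds <- build_endurance_dataset(fl, profile_queens(m))
  tab <- endurance_table(ds, tau = 0.75, n_boot = 99, seed = 8)
  expect_equal(nrow(tab), 9)  # 3 methods x 3 predictors
  for (meth in unique(tab$method)) {
    sub <- tab[tab$method == meth, ]
    expect_equal(sub$p_corrected, holm_correction(sub$p_raw))
  }
  # quantile and OLS slopes agree in sign for abdomen mass (negative)
  expect_lt(tab$slope[tab$method == "quantile" & tab$predictor == "abdomen_mass"], 0)
  expect_lt(tab$slope[tab$method == "ols" & tab$predictor == "abdomen_mass"], 0)
})
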