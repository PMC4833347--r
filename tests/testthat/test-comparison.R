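# Caste comparisons, colony averaging, OLS regressions, Holm correction.

test_that("summarize_group computes means, medians and interpolated IQR", {
  s <- summarize_group(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  expect_equal(s$iqr_low, 1.75)   # type-7 linear interpolation
  expect_equal(s$iqr_high, 3.25)
  s1 <- summarize_group(5)
  expect_equal(s1$sd, 0)
  expect_equal(s1$iqr_low, s1$iqr_high)
  expect_error(summarize_group(numeric(0)), "at least one")
})

test_that("compare_castes gates on normality and computes contrasts", {
  set.seed(4)
  cl <- rnorm(30, 5.3, 0.9); pa <- rnorm(30, 2.7, 0.7)
  cmp <- compare_castes(cl, pa, trait = "abdomen_mass")
  expect_equal(cmp$test_used, "t")
  expect_lt(cmp$p_raw, 1e-6)
  expect_equal(cmp$fold_difference, mean(cl) / mean(pa))
  # exponentiated data fails the gate and routes to Kruskal-Wallis
  cmp2 <- compare_castes(exp(rnorm(40, 0, 2)), exp(rnorm(40, 1, 2)))
  expect_equal(cmp2$test_used, "kruskal_wallis")
  # but passes under the log transform option
  cmp3 <- compare_castes(exp(rnorm(40, 0, 1)), exp(rnorm(40, 1, 1)),
                         transform = "log")
  expect_equal(cmp3$test_used, "t")
  expect_error(compare_castes(1:2, 1:5), ">= 3")
})

test_that("identical groups give zero percent and unit fold difference", {
  x <- c(1.2, 1.5, 1.9, 2.2)
  cmp <- compare_castes(x, x)
  expect_equal(cmp$percent_difference, 0)
  expect_equal(cmp$fold_difference, 1)
})

test_that("swap symmetry: percent difference changes reference, fold inverts", {
  set.seed(8)
  a <- rnorm(20, 10, 1); b <- rnorm(20, 7, 1)
  ab <- compare_castes(a, b); ba <- compare_castes(b, a)
  expect_equal(ab$fold_difference, 1 / ba$fold_difference)
  expect_equal(ab$p_raw, ba$p_raw, tolerance = 1e-12)
})

test_that("published group means reproduce the reported contrasts", {
  # degenerate cohorts carry the published means exactly
  specs <- lapply(table2_specs(), degenerate_spec)
  prof <- profile_queens(do.call(rbind, lapply(specs, generate_morphometry, seed = 1)))
  gem <- prof[prof$species == "geminata", ]
  cmp_fmr <- compare_castes(gem$fmr[gem$caste == "claustral"],
                            gem$fmr[gem$caste == "parasitic"], trait = "fmr")
  expect_equal(round(cmp_fmr$percent_difference), -32)  # FMR 32% lower
  cmp_abd <- compare_castes(gem$abdomen_mass[gem$caste == "claustral"],
                            gem$abdomen_mass[gem$caste == "parasitic"])
  expect_equal(round(cmp_abd$fold_difference, 1), 2.3)  # abdomens 2.3x heavier
  expect_equal(cmp_abd$fold_difference, 5.652 / 2.453, tolerance = 1e-12)
})

test_that("colony averaging collapses to one row per colony", {
  df <- data.frame(colony_id = c("a", "a", "b"), v = c(1, 3, 7),
                   species = "invicta", stringsAsFactors = FALSE)
  got <- colony_averages(df)
  expect_equal(nrow(got), 2)
  expect_equal(got$v[got$colony_id == "a"], 2)
  expect_equal(got$v[got$colony_id == "b"], 7)
  # colonies of one queen each: identity on the trait values
  df1 <- data.frame(colony_id = c("x", "y"), v = c(4, 9))
  expect_equal(sort(colony_averages(df1)$v), c(4, 9))
})

test_that("colony-mode group means track individual-mode means in balanced designs", {
  spec <- table2_specs()$IC
  spec$n_queens <- 120L; spec$n_colonies <- 6L
  prof <- profile_queens(generate_morphometry(spec, seed = 31))
  ind_mean <- mean(prof$fmr)
  col_mean <- mean(colony_averages(prof)$fmr)
  se <- sd(prof$fmr) / sqrt(nrow(prof))
  expect_lt(abs(ind_mean - col_mean), 3 * se)
})

test_that("OLS regression matches closed-form normal equations", {
  f <- suppressWarnings(regress_on_abdomen_mass(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  f0 <- suppressWarnings(regress_on_abdomen_mass(c(0, 1, 2), c(1, 1, 1)))
  expect_equal(f0$slope, 0); expect_equal(f0$r_squared, 0)
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(3); y <- rnorm(3)
    if (sd(x) == 0) next
    f <- regress_on_abdomen_mass(x, y)
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b0 <- mean(y) - b1 * mean(x)
    expect_equal(f$slope, b1, tolerance = 1e-10)
    expect_equal(f$intercept, b0, tolerance = 1e-10)
  }
})

test_that("synthetic claustral invicta cohort recovers the mechanistic wing-loading slope", {
  spec <- table2_specs()$IC
  spec$n_queens <- 200L
  prof <- profile_queens(generate_morphometry(spec, seed = 17))
  f <- regress_on_abdomen_mass(prof$abdomen_mass, prof$wing_loading)
  # mechanistic expectation: d(WL)/d(abdomen) ~ 1/mean wing area = 1/27.0,
  # the published fit for this cohort is 0.0367
  expect_gt(f$slope, 0.025); expect_lt(f$slope, 0.050)
  expect_gt(f$r_squared, 0.5)
  # FMR declines with abdomen mass
  ff <- regress_on_abdomen_mass(prof$abdomen_mass, prof$fmr)
  expect_lt(ff$slope, 0)
})

test_that("holm_correction reproduces published corrected p-value families", {
  # per-index family across the four queen types (m = 4)
  expect_equal(holm_correction(c(8.4e-6, 2.5e-4, 2.0e-16, 2.0e-16)),
               c(1.68e-5, 2.5e-4, 8.0e-16, 8.0e-16))
  # per-method family across the three endurance predictors (m = 3)
  expect_equal(holm_correction(c(0.024, 0.031, 0.018)),
               c(0.054, 0.054, 0.054))
  expect_equal(holm_correction(0.03), 0.03)  # single p unchanged
  expect_error(holm_correction(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("holm_correction matches the hand-rolled step-down and its properties", {
  set.seed(5)
  for (rep in 1:25) {
    p <- runif(sample(1:8, 1))
    got <- holm_correction(p)
    expect_equal(got, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(got >= p))
    expect_true(all(got <= 1))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(holm_correction(p[perm]), got[perm])
  }
  # equals Bonferroni when all p equal
  expect_equal(holm_correction(rep(0.01, 4)), rep(0.04, 4))
})

test_that("regression table applies Holm within each index family", {
  specs <- table2_specs()
  prof <- profile_queens(do.call(rbind, lapply(specs, generate_morphometry, seed = 2)))
  tab <- morphology_regression_table(prof)
  expect_equal(nrow(tab), 12)  # 3 indices x 4 queen types
  for (idx in unique(tab$response)) {
    sub <- tab[tab$response == idx, ]
    expect_equal(sub$p_corrected, holm_correction(sub$p_raw))
  }
  expect_true(all(tab$p_corrected >= tab$p_raw))
})
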