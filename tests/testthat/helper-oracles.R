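# Independent oracles, written deliberately as plain loops so they share no
# code path with the package implementations they check.

# Brute-force quantile-regression oracle: enumerate every line through two
# data points with distinct x, score the check loss with an explicit loop,
# return the best objective found.
oracle_qr_objective <- function(x, y, tau) {
  n <- length(x)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b1 <- (y[j] - y[i]) / (x[j] - x[i])
      b0 <- y[i] - b1 * x[i]
      obj <- 0
      for (k in 1:n) {
        u <- y[k] - b0 - b1 * x[k]
        obj <- obj + if (u >= 0) tau * u else (tau - 1) * u
      }
      if (obj < best) best <- obj
    }
  }
  best
}

# Hand-rolled Holm step-down (sort, multiply by decreasing factors, running
# maximum, cap at 1, restore order).
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    v <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, v)
    adj[ord[i]] <- running
  }
  adj
}

# Monte-Carlo volume of the prolate spheroid with diameters L (major) and H
# (minor): hit counting in the bounding box.
oracle_spheroid_volume_mc <- function(L, H, n_points, seed) {
  set.seed(seed)
  px <- runif(n_points, -L / 2, L / 2)
  py <- runif(n_points, -H / 2, H / 2)
  pz <- runif(n_points, -H / 2, H / 2)
  inside <- (px / (L / 2))^2 + (py / (H / 2))^2 + (pz / (H / 2))^2 <= 1
  mean(inside) * L * H * H
}

# Small fully-valid morphometry table used by the IO tests.
make_morph_fixture <- function(n = 4) {
  data.frame(
    queen_id = sprintf("q%02d", seq_len(n)),
    species = rep(c("geminata", "invicta"), length.out = n),
    caste = rep(c("claustral", "parasitic"), length.out = n),
    colony_id = rep(c("c1", "c2"), length.out = n),
    head_width = seq(1.4, 1.6, length.out = n),
    abdomen_length = seq(2.8, 3.2, length.out = n),
    abdomen_height = seq(1.8, 2.0, length.out = n),
    abdomen_mass = seq(5.0, 5.6, length.out = n),
    thorax_mass = rep(1.1, n),
    wing_mass = rep(0.13, n),
    body_mass = seq(5.0, 5.6, length.out = n) + 1.1 + 0.13 + 0.7,
    forewing_length = seq(6.4, 6.6, length.out = n),
    total_wing_area = seq(27, 28, length.out = n),
    stringsAsFactors = FALSE
  )
}

# Degenerate (all SDs zero) copy of a caste spec: every queen identical.
degenerate_spec <- function(spec) {
  for (nm in names(spec$traits)) spec$traits[[nm]][2] <- 0
  spec$colony_sd_fraction <- 0
  spec
}
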