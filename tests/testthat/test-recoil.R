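# Recoil kinetics: velocities, peak + QC, exponential fit, group comparison.

kv <- function(A = 1.2, tau = 4, noise = 0, L0 = 10, dt = 2, T = 8)
  list(L0_um = L0, A_um = A, tau_s = tau, dt_s = dt, T_s = T,
       noise_sd_um = noise)

test_that("instantaneous velocities: constant, linear, and the closed form", {
  tr0 <- simulate_recoil_trace(kv(A = 0), seed = 1)
  expect_true(all(recoil_velocities(tr0) == 0))
  expect_equal(peak_recoil_velocity(tr0)$peak_velocity_um_per_s, 0)
  expect_true(peak_recoil_velocity(tr0)$discard)  # A = 0: no measurable recoil

  lin <- structure(list(times_s = 0:5, distances_um = 10 + 0.1 * (0:5)),
                   class = "recoil_trace")
  expect_equal(recoil_velocities(lin), rep(0.1, 5))

  tr <- simulate_recoil_trace(kv(), seed = 1)
  v <- recoil_velocities(tr)
  expect_equal(v[1], 1.2 * (1 - exp(-0.5)) / 2, tolerance = 1e-12)
  expect_equal(round(v[1], 4), 0.2361)
  expect_true(all(diff(v) < 0))  # exponential decay: strictly decreasing
  # peak of a noiseless trace is the first-interval velocity
  expect_equal(peak_recoil_velocity(tr)$peak_velocity_um_per_s, v[1])
  expect_error(recoil_velocities(list(times_s = c(0, 2, 2),
                                      distances_um = c(1, 2, 3))),
               "strictly increasing")
})

test_that("peak velocity underestimates v0 by the discretization factor", {
  for (tau in c(2, 4, 8)) {
    tr <- simulate_recoil_trace(kv(A = 1.2, tau = tau), seed = 1)
    peak <- peak_recoil_velocity(tr)$peak_velocity_um_per_s
    v0 <- 1.2 / tau
    factor <- tau * (1 - exp(-2 / tau)) / 2
    expect_equal(peak, v0 * factor, tolerance = 1e-12)
    expect_lt(peak, v0)
  }
})

test_that("velocities are invariant to a constant distance offset", {
  tr <- simulate_recoil_trace(kv(noise = 0.05), seed = 3)
  tr2 <- tr; tr2$distances_um <- tr$distances_um + 5
  expect_equal(recoil_velocities(tr2), recoil_velocities(tr))
})

test_that("a shrinking trace is flagged for discard", {
  shrink <- structure(list(times_s = seq(0, 8, 2),
                           distances_um = 10 - 0.1 * seq(0, 8, 2)),
                      class = "recoil_trace")
  expect_true(peak_recoil_velocity(shrink)$discard)
})

test_that("exponential fit is exact on noiseless traces and sane under noise", {
  tr <- simulate_recoil_trace(kv(), seed = 1)
  fit <- fit_exponential_recoil(tr)
  expect_equal(fit$A_um, 1.2, tolerance = 1e-6)
  expect_equal(fit$tau_s, 4, tolerance = 1e-6)
  expect_equal(fit$d0, 10, tolerance = 1e-6)
  expect_equal(fit$v0_um_per_s, 0.3, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["A_um"]), fit$A_um)
  # A = 0 -> v0 = 0
  fit0 <- fit_exponential_recoil(simulate_recoil_trace(kv(A = 0), seed = 1))
  expect_equal(fit0$v0_um_per_s, 0, tolerance = 1e-8)
  # parameter recovery under measurement noise: mean estimates within 10%
  # (denser sampling than the 8-s acquisition, so tau is identifiable)
  est <- t(vapply(1:200, function(s) {
    tr <- simulate_recoil_trace(kv(noise = 0.05, T = 16), seed = s)
    f <- fit_exponential_recoil(tr)
    c(f$A_um, f$tau_s)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 1.2) / 1.2, 0.10)
  expect_lt(abs(stats::median(est[, 2]) - 4) / 4, 0.10)
})

test_that("group comparison uses Welch's test and handles discards", {
  # hand-computed Welch statistic on a 3 + 3 toy table
  mk <- function(d) structure(list(times_s = c(0, 2), distances_um = c(10, 10 + d)),
                              class = "recoil_trace")
  a <- lapply(c(0.2, 0.3, 0.4), mk)   # peaks 0.1, 0.15, 0.2
  b <- lapply(c(0.6, 0.8, 1.0), mk)   # peaks 0.3, 0.4, 0.5
  res <- compare_recoil_groups(a, b)
  va <- c(0.1, 0.15, 0.2); vb <- c(0.3, 0.4, 0.5)
  tstat <- (mean(va) - mean(vb)) /
    sqrt(stats::var(va) / 3 + stats::var(vb) / 3)
  expect_equal(res$t_statistic, tstat, tolerance = 1e-12)
  expect_equal(res$mean_a, 0.15)
  expect_equal(res$n_a, 3)
  # identical groups: mean difference 0, p = 1
  set.seed(10)
  g <- lapply(1:5, function(s) simulate_recoil_trace(kv(noise = 0.02), seed = s))
  same <- compare_recoil_groups(g, g)
  expect_equal(same$mean_a, same$mean_b)
  expect_gt(same$p_value, 0.99)
  # discarded traces are excluded and counted
  withdisc <- c(a, list(mk(-0.5)))
  res2 <- compare_recoil_groups(withdisc, b)
  expect_equal(res2$n_discarded, 1)
  expect_equal(res2$n_a, 3)
})

test_that("a twofold tension difference is detected at n = 16 per group", {
  detect <- vapply(1:100, function(rep) {
    set.seed(rep)
    a <- lapply(1:16, function(i)
      simulate_recoil_trace(kv(A = 1.2, tau = 4, noise = 0.05),
                            seed = rep * 100 + i))
    b <- lapply(1:16, function(i)
      simulate_recoil_trace(kv(A = 2.4, tau = 4, noise = 0.05),
                            seed = rep * 100 + 50 + i))
    compare_recoil_groups(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.9)
})
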