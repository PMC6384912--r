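test_that("single-pathway operational response matches hand arithmetic", {
  sys <- system_params(em = 100, basal = 10, n = 1)
  # A/KA = 0.01, R*A = 1 => E = 10 + 90 / (1 + 1.01)
  expect_equal(operational_response(1e-7, sys, log_ka = -5, log_r = 7),
               10 + 90 / 2.01, tolerance = 1e-12)
  # zero concentration returns the analytic limit, no NaN
  expect_identical(operational_response(0, sys, -5, 7), 10)
  # top plateau: Basal + (Em - Basal)/(1 + tau^-n), tau = 10^(7-5)
  expect_equal(operational_response(1e3, sys, -5, 7),
               10 + 90 / (1 + 1 / 100), tolerance = 1e-3)
  expect_error(operational_response(1e-7, sys, NA, 7), "finite")
  expect_error(operational_response(-1e-9, sys, -5, 7), "conc")
})

test_that("operational response is nondecreasing in concentration", {
  grid <- 10^seq(-12, -2, by = 0.25)
  for (n in c(0.5, 1, 2.3)) {
    sys <- system_params(100, 10, n)
    r <- operational_response(grid, sys, log_ka = -6, log_r = 6.5)
    expect_true(all(diff(r) >= -1e-12))
  }
})

test_that("intact response equals marginal response with the shared KA'", {
  sys2 <- list(p1 = system_params(100, 10, 1), p2 = system_params(80, 5, 1.4))
  lr <- c(p1 = 7, p2 = 5.5)
  a <- 10^seq(-10, -4)
  for (p in c("p1", "p2")) {
    expect_equal(intact_response(a, p, sys2, log_ka_prime = -5.2, log_r = lr),
                 operational_response(a, sys2[[p]], -5.2, lr[[p]]),
                 tolerance = 1e-15)
  }
  expect_equal(intact_response(1e-7, "p1",
                               list(p1 = system_params(100, 10, 1),
                                    p2 = system_params(100, 10, 1)),
                               -5, c(p1 = 7, p2 = 7)),
               10 + 90 / 2.01, tolerance = 1e-12)
  expect_error(intact_response(1e-7, "p3", sys2, -5, lr), "unknown pathway")
})

test_that("reparameterised intact model reproduces the direct form exactly", {
  expect_equal(implied_log_r2(6, 7, 7, 0), 6)
  expect_equal(implied_log_r2(6.5, 7, 7, 0.5), 6)
  sys2 <- list(`1` = system_params(100, 10, 1), `2` = system_params(100, 10, 1))
  a <- 10^seq(-11, -4, by = 0.5)
  set.seed(11)
  for (rep in 1:25) {
    lr1 <- runif(1, 4, 9); lr1r <- runif(1, 4, 9)
    lr2r <- runif(1, 4, 9); dd <- runif(1, -2, 2)
    kap <- runif(1, -8, -4)
    lr2 <- implied_log_r2(lr1, lr1r, lr2r, dd)
    for (p in c("1", "2")) {
      direct <- intact_response(a, p, sys2, kap, c(`1` = lr1, `2` = lr2))
      repar <- intact_response_reparam(a, p, sys2, kap, lr1, lr1r, lr2r, dd)
      expect_equal(repar, direct, tolerance = 1e-12)
    }
  }
})

test_that("apparent KA' is the reciprocal-sum of per-pathway KA values", {
  expect_equal(ka_prime(c(2e-5, 2e-5)), 1e-5)
  expect_equal(ka_prime(c(1e-5, 1e-3)), 1 / (1e5 + 1e3), tolerance = 1e-12)
  expect_equal(ka_prime(c(1e-5, 1e30)), 1e-5, tolerance = 1e-6)
  # generalises to k pathways and never exceeds the smallest input
  set.seed(2)
  for (k in 2:5) {
    kas <- 10^runif(k, -9, -3)
    expect_lte(ka_prime(kas), min(kas))
  }
  expect_equal(ka_prime(rep(3e-6, 3)), 1e-6)
  expect_error(ka_prime(c(1e-5, -1e-6)), "> 0")
})

test_that("C50 and the transducer ratio behave per their closed forms", {
  expect_equal(c50(1e-5, 0), 1e-5)
  expect_equal(c50(1e-5, 99), 1e-7)
  expect_equal(c50(2e-6, 1), 1e-6)
  expect_true(all(diff(c50(1e-5, c(0, 1, 10, 100))) < 0))
  expect_error(c50(1e-5, -0.1), "tau")
  expect_equal(tau_from(7, -5), 100)
  expect_equal(tau_from(0, 0), 1)
  expect_equal(tau_from(6, -6), 1)
})

test_that("midpoint crossing of a unit-slope intact curve equals KA'/(tau+1)", {
  kap <- -5.7; lr <- 6.9
  tau <- tau_from(lr, kap)
  sys <- list(p = system_params(100, 10, 1))
  f <- function(a) intact_response(a, "p", sys, kap, c(p = lr))
  plateau <- 10 + 90 / (1 + 1 / tau)  # analytic top-of-curve limit, n = 1
  expect_equal(c50_numeric(f, lower = -13, upper = -2, plateau = plateau),
               c50(10^kap, tau), tolerance = 1e-9)
})

test_that("receptor-density shift is the log10 density ratio", {
  expect_equal(receptor_density_shift(10, 1), 1)
  expect_equal(receptor_density_shift(1, 1), 0)
  expect_equal(receptor_density_shift(5, 1), log10(5), tolerance = 1e-9)
  expect_error(receptor_density_shift(-1, 1), "> 0")
})

test_that("opposing Gi/Gs model: basal at zero, density shift, U-shape", {
  spec <- opposing_spec(basal = 103, em_i = 49.2, n_i = 1.47,
                        em_s = 59.2, n_s = 2.27, log_ka_prime = -5.32,
                        log_r_i_low = 6.90, pref_i_s = 2.28,
                        density_log_shift = 1)
  expect_equal(opposing_response(0, "low", spec, "intact"), 103)
  expect_equal(opposing_response(0, "high", spec, "intact"), 103)

  # high-expression curve == low-expression curve with both logR values +1
  a <- 10^seq(-9, -3, by = 0.25)
  spec_up <- spec
  spec_up$log_r_i_low <- spec$log_r_i_low + 1
  spec_up$log_r_s_low <- spec$log_r_s_low + 1
  expect_equal(opposing_response(a, "high", spec, "intact"),
               opposing_response(a, "low", spec_up, "intact"),
               tolerance = 1e-12)

  # biphasic "U-shape" at high expression: decreases, then increases
  hi <- opposing_response(a, "high", spec, "intact")
  d <- diff(hi)
  expect_lt(min(d), 0)
  expect_gt(max(d), 0)
  expect_lt(which.min(hi), length(hi))  # trough is interior
  sign_changes <- sum(diff(sign(d[abs(d) > 1e-9])) != 0)
  expect_equal(sign_changes, 1)  # single trough, no extra wiggles

  # low-expression curve is dominated by inhibition: a deep drop with at
  # most a slight late rise from the weak stimulatory term
  lo <- opposing_response(a, "low", spec, "intact")
  expect_lt(min(lo), lo[1] - 30)
  expect_lt(lo[length(lo)] - min(lo), 5)

  # marginal variant needs per-pathway KA values
  expect_error(opposing_response(a, "high", spec, "marginal"), "marginal")
  expect_error(opposing_response(a, "mid", spec, "intact"), "expression")
})

test_that("marginal and intact coincide when marginal KA is shared", {
  # the intact model is the marginal model plus the shared-KA constraint
  sys2 <- list(`1` = system_params(100, 10, 1.2),
               `2` = system_params(90, 0, 0.8))
  a <- 10^seq(-11, -4, by = 0.5)
  kap <- -5.5
  lr <- c(`1` = 6.2, `2` = 7.1)
  for (p in c("1", "2")) {
    expect_equal(operational_response(a, sys2[[p]], kap, lr[[p]]),
                 intact_response(a, p, sys2, kap, lr), tolerance = 1e-15)
  }
})
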