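p_fit <- table2_params()

test_that("TIA contribution has the single-term form for fatal stays", {
  rec <- list(stroke_type = "tia", age = 78, los_days = 20, mode = "death")
  v <- p_fit$values
  p78 <- mild_tia_probability(78, p_fit)
  r3 <- v[["mu3"]] + v[["nu3"]] + v[["rho3"]]
  s <- 20 / 365.25
  expect_equal(contribution_tia(rec, p_fit),
               (1 - p78) * exp(-r3 * s) * v[["mu3"]], tolerance = 1e-14)
  # nursing-home exit likewise has no phase-4 term
  rec$mode <- "nursing_home"
  expect_equal(contribution_tia(rec, p_fit),
               (1 - p78) * exp(-r3 * s) * v[["nu3"]], tolerance = 1e-14)
  # home discharge adds the mild-TIA term
  rec$mode <- "usual_residence"
  expect_equal(contribution_tia(rec, p_fit),
               (1 - p78) * exp(-r3 * s) * v[["rho3"]] +
                 p78 * exp(-v[["rho4"]] * s) * v[["rho4"]],
               tolerance = 1e-14)
  expect_error(contribution_tia(
    list(stroke_type = "haemorrhagic", age = 78, los_days = 20,
         mode = "death"), p_fit), "tia")
})

test_that("closed-form contributions match the matrix-exponential oracle", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    pp <- random_params()
    rec <- random_record()
    cf <- contribution_of(rec, pp)
    oc <- oracle_density(rec, pp)
    expect_gt(cf, 0)
    rel <- abs(cf - oc) / max(oc, 1e-300)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-8)
})

test_that("contributions integrate to one over stay and modes", {
  set.seed(203)
  for (ty in c("haemorrhagic", "cerebral_infarction", "tia")) {
    pp <- random_params()
    age <- runif(1, 50, 90)
    total <- 0
    for (m in c("death", "nursing_home", "usual_residence")) {
      total <- total + integrate(function(s) {
        vapply(s, function(si) contribution_of(
          list(stroke_type = ty, age = age, los_days = si, mode = m), pp),
          numeric(1))
      }, 0, Inf, rel.tol = 1e-9)$value
    }
    # contributions are per-year densities; stays enter in days
    expect_equal(total / pp$days_per_year, 1, tolerance = 1e-5)
  }
})

test_that("near-tied exit rates are evaluated continuously", {
  # force r2 ~ r3 and check the limit form joins smoothly
  base <- stroke_params(gamma1 = 2, beta1 = 0, gamma2 = -30, beta2 = 0,
                        theta0 = -8, theta1 = 0.08,
                        mu1 = 10, mu2 = 2, mu3 = 1.5, nu3 = 1.3, nu2 = 0.5,
                        rho2 = 2.7, rho3 = 3.4, rho4 = 60, rho1 = 0.2,
                        nu1 = 0.1, zero_mask = character())
  # r3 = 6.2; r2 = 5.2 + lambda2 = 5.2 + exp(gamma2); steer lambda2 -> 1
  rec <- list(stroke_type = "cerebral_infarction", age = 70, los_days = 30,
              mode = "death")
  vals <- vapply(c(1 - 1e-6, 1 - 1e-8, 1, 1 + 1e-8, 1 + 1e-6), function(f) {
    pp <- base
    pp$values[["gamma2"]] <- log(f)  # lambda2 = f, so r2 - r3 = f - 1
    contribution_ci(rec, pp)
  }, numeric(1))
  expect_lt(max(abs(diff(vals))) / vals[3], 1e-6)
  # haemorrhagic three-way tie against the series oracle
  pp <- stroke_params(gamma1 = 0, beta1 = 0, gamma2 = 0, beta2 = 0,
                      theta0 = -8, theta1 = 0.08,
                      mu1 = 2, mu2 = 1, mu3 = 1.5, nu3 = 0.4, nu2 = 0.5,
                      rho2 = 0.5, rho3 = 1.1, rho4 = 60, rho1 = 0,
                      nu1 = 0, zero_mask = character())
  # r1 = r2 = r3 = 3 exactly
  rec <- list(stroke_type = "haemorrhagic", age = 70, los_days = 45,
              mode = "usual_residence")
  expect_equal(contribution_haem(rec, pp), oracle_density(rec, pp),
               tolerance = 1e-9)
})

test_that("degenerate progression reduces to a single-phase density", {
  # lambda1 ~ 0: a haemorrhagic stay is Exp(mu1 + nu1 + rho1) ending by mode
  pp <- stroke_params(gamma1 = -40, beta1 = 0, gamma2 = 0, beta2 = 0,
                      theta0 = -8, theta1 = 0.08,
                      mu1 = 3, mu2 = 1, mu3 = 1, nu3 = 1, nu1 = 0.5,
                      rho1 = 1.5, rho2 = 1, rho3 = 1, rho4 = 60,
                      nu2 = 0, zero_mask = character())
  rec <- list(stroke_type = "haemorrhagic", age = 70, los_days = 25,
              mode = "death")
  s <- 25 / 365.25
  expect_equal(contribution_haem(rec, pp), exp(-5 * s) * 3, tolerance = 1e-10)
})

test_that("log-likelihood sums contributions and flags underflow", {
  set.seed(204)
  cc <- cohort_config(n = 200, seed = 204, params = p_fit)
  sim <- simulate_cohort(cc)
  ll <- log_likelihood(sim, p_fit)
  by_hand <- sum(log(vapply(seq_len(nrow(sim)), function(i)
    contribution_of(as.list(sim[i, ]), p_fit), numeric(1))))
  expect_equal(as.numeric(ll), by_hand, tolerance = 1e-10)
  # invariant under record order
  perm <- sim[sample(nrow(sim)), ]
  expect_equal(as.numeric(log_likelihood(perm, p_fit)), by_hand,
               tolerance = 1e-10)
  # single record
  one <- sim[1, , drop = FALSE]
  expect_equal(as.numeric(log_likelihood(one, p_fit)),
               log(contribution_of(as.list(one), p_fit)), tolerance = 1e-12)
  expect_error(log_likelihood(sim[0, ], p_fit), "empty")
  # an impossible record (nursing-home exit with all nu masked) underflows
  bad <- data.frame(stroke_type = "haemorrhagic", age = 70, los_days = 10,
                    mode = "nursing_home")
  masked <- table2_params()
  masked$zero_mask <- c("nu1", "nu2", "nu3")
  masked$values[masked$zero_mask] <- 0
  ll_bad <- log_likelihood(bad, masked)
  expect_identical(as.numeric(ll_bad), -Inf)
  expect_true(attr(ll_bad, "underflow"))
})
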