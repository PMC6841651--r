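p_fit <- table2_params()

test_that("stay density is a proper density consistent with the CDF", {
  for (ty in c("haemorrhagic", "cerebral_infarction", "tia")) {
    g <- build_generator(ty, 75, p_fit)
    total <- integrate(function(y) los_density(y, g), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
    # CDF equals the integral of the density
    for (y in c(3, 25, 120)) {
      expect_equal(los_cdf(y, g),
                   integrate(function(s) los_density(s, g), 0, y,
                             rel.tol = 1e-10)$value,
                   tolerance = 1e-8)
    }
    expect_equal(los_cdf(0, g), 0)
    expect_gt(los_cdf(1e5, g), 1 - 1e-8)
    grid <- seq(0, 400, by = 5)
    expect_true(all(diff(los_cdf(grid, g)) >= 0))
    expect_true(all(los_density(grid, g) >= 0))
    # survival is the complement and the density its negative derivative
    expect_equal(los_survival(grid, g), 1 - los_cdf(grid, g))
    h <- 1e-4
    expect_equal(los_density(30, g),
                 -(los_survival(30 + h, g) - los_survival(30 - h, g)) / (2 * h),
                 tolerance = 1e-6)
  }
  expect_error(los_density(-1, build_generator("tia", 70, p_fit)),
               "non-negative")
})

test_that("pure phase-4 entry reduces to the exponential distribution", {
  # TIA with mild probability forced to ~1: stay ~ Exp(rho4)
  p4 <- stroke_params(gamma1 = 1, beta1 = 0, gamma2 = 1, beta2 = 0,
                      theta0 = -60, theta1 = 0, mu1 = 1, mu2 = 1, mu3 = 1,
                      nu3 = 1, rho2 = 1, rho3 = 1, rho4 = 63.92514,
                      zero_mask = character())
  g <- build_generator("tia", 70, p4)
  y <- c(0.5, 2, 10)
  rate_day <- 63.92514 / 365.25
  expect_equal(los_density(y, g), rate_day * exp(-rate_day * y),
               tolerance = 1e-9)
  expect_equal(mean_los(g), 365.25 / 63.92514, tolerance = 1e-9)
  expect_equal(unname(absorption_probs(g)[4, ]), c(0, 0, 1))
  # constant cause-specific intensity: model curve is linear in t
  mc <- model_cumulative_intensity("tia", 70, "usual_residence",
                                   c(1, 5, 10), p4)
  expect_equal(mc$estimate, rate_day * mc$time, tolerance = 1e-8)
})

test_that("occupancy matches an independent matrix exponential", {
  set.seed(101)
  for (i in 1:100) {
    pp <- random_params()
    g <- build_generator(sample(c("haemorrhagic", "cerebral_infarction",
                                  "tia"), 1), runif(1, 40, 100), pp)
    t <- rexp(1, 10)
    E <- series_expm(g$Tmat, t)
    expect_equal(unname(occupancy(g, t)[1, ]),
                 unname(as.vector(g$alpha %*% E)), tolerance = 1e-8)
  }
})

test_that("absorption matrix is row-stochastic with the phase-4 structure", {
  for (age in c(50, 65, 75, 85, 95)) {
    g <- build_generator("haemorrhagic", age, p_fit)
    P <- absorption_probs(g)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(P[4, ]), c(0, 0, 1))
  }
})

test_that("destination percentages reproduce the published table", {
  expect_equal(unname(destination_percentages(75, "haemorrhagic", p_fit)),
               c(45.1, 5.8, 49.1))
  expect_equal(unname(destination_percentages(65, "cerebral_infarction",
                                              p_fit)),
               c(19.4, 5.2, 75.5))
  expect_equal(unname(destination_percentages(85, "tia", p_fit)),
               c(6.6, 5.4, 88.0))
  t3 <- make_table3(params = p_fit, digits = NULL)
  expect_equal(rowSums(t3[, 3:5]), rep(100, 9), tolerance = 1e-10)
})

test_that("mean stays and conditional decomposition reproduce the table", {
  g65h <- build_generator("haemorrhagic", 65, p_fit)
  expect_equal(mean_los(g65h), 29.8, tolerance = 0.05)
  expect_equal(mean_los(build_generator("tia", 75, p_fit)), 12.0,
               tolerance = 0.05)
  expect_equal(mean_los_by_destination(
    build_generator("cerebral_infarction", 85, p_fit), "death"), 49.7,
    tolerance = 0.05)
  expect_equal(mean_los_by_destination(g65h, "death"), 18.6, tolerance = 0.05)
  # law of total expectation across all profiles
  for (age in c(65, 75, 85)) {
    for (ty in c("haemorrhagic", "cerebral_infarction", "tia")) {
      g <- build_generator(ty, age, p_fit)
      P <- absorption_probs(g)
      reach <- as.vector(g$alpha %*% P)
      cond <- vapply(c("death", "nursing_home", "usual_residence"),
                     function(m) mean_los_by_destination(g, m), numeric(1))
      expect_equal(sum(reach * cond), mean_los(g), tolerance = 1e-10)
    }
  }
})

test_that("mean residual stay starts at the mean and ends at the phase-3 mean", {
  r3 <- 1.56162 + 1.27849 + 3.41989
  for (ty in c("haemorrhagic", "cerebral_infarction", "tia")) {
    g <- build_generator(ty, 75, p_fit)
    expect_equal(mean_residual(0, g), mean_los(g), tolerance = 1e-10)
    expect_equal(mean_residual(2000, g), 365.25 / r3, tolerance = 1e-6)
  }
  # mild TIAs purge quickly, so the residual mean rises above its start
  g_tia <- build_generator("tia", 75, p_fit)
  expect_gt(mean_residual(10, g_tia), mean_residual(0, g_tia))
})

test_that("stay-conditional destination probabilities behave as expected", {
  g <- build_generator("haemorrhagic", 75, p_fit)
  P <- absorption_probs(g)
  expect_equal(unname(destination_probs_given_stay(0, g)[1, ]),
               unname(as.vector(g$alpha %*% P)), tolerance = 1e-12)
  grid <- seq(0, 600, by = 10)
  probs <- destination_probs_given_stay(grid, g)
  expect_equal(unname(rowSums(probs)), rep(1, length(grid)),
               tolerance = 1e-10)
  # the death outlook improves with stay: it falls steeply early on and
  # never exceeds its admission value (it is not globally monotone — after
  # the acute phases purge it climbs back toward the phase-3 share)
  expect_true(all(diff(probs[grid <= 30, "death"]) < 0))
  expect_true(all(probs[, "death"] <= probs[1, "death"]))
  # long-stay limit: occupancy concentrates in phase 3
  expect_equal(unname(destination_probs_given_stay(4000, g)[1, ]),
               unname(P[3, ]), tolerance = 1e-6)
})

test_that("cumulative discharge by mode sums to the CDF and has the right limit", {
  g <- build_generator("cerebral_infarction", 75, p_fit)
  grid <- c(0, 5, 20, 60, 200, 1000)
  modes <- c("death", "nursing_home", "usual_residence")
  by_mode <- sapply(modes, function(m)
    cumulative_discharge_by_mode(grid, g, m))
  expect_equal(unname(rowSums(by_mode)), los_cdf(grid, g), tolerance = 1e-10)
  expect_equal(unname(by_mode[1, ]), c(0, 0, 0))
  P <- absorption_probs(g)
  expect_equal(unname(cumulative_discharge_by_mode(1e5, g, "death")),
               sum(g$alpha * P[, "death"]), tolerance = 1e-8)
  # matches quadrature of the mode-specific density
  dens_death <- function(y) {
    t <- y / g$days_per_year
    as.vector(occupancy(g, t) %*% g$tA[, "death"]) / g$days_per_year
  }
  expect_equal(unname(cumulative_discharge_by_mode(40, g, "death")),
               integrate(dens_death, 0, 40, rel.tol = 1e-10)$value,
               tolerance = 1e-8)
  expect_true(all(diff(cumulative_discharge_by_mode(grid, g, "death")) >= 0))
})

test_that("report tables carry the full age-by-type layout", {
  t3 <- make_table3(c(65, 75, 85), p_fit)
  t4 <- make_table4(c(65, 75, 85), p_fit)
  expect_equal(nrow(t3), 9L)
  expect_equal(nrow(t4), 9L)
  expect_named(t3, c("age", "stroke_type", "death", "nursing_home",
                     "usual_residence"))
  expect_named(t4, c("age", "stroke_type", "death", "nursing_home",
                     "usual_residence", "all"))
  # TIA conditional death/nursing-home means equal the phase-3 mean at all ages
  tia_rows <- t4[t4$stroke_type == "tia", ]
  expect_equal(tia_rows$death, rep(58.3, 3))
  expect_equal(tia_rows$nursing_home, rep(58.3, 3))
})
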