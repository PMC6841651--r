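# Shared fixtures: the published estimate set, random valid parameter
# draws, random records, and an independent truncated-series matrix
# exponential used as the cross-route oracle.

table2_params <- function(days_per_year = 365.25) {
  stroke_params(
    gamma1 = 6.63570, beta1 = -0.03652, gamma2 = -3.06931, beta2 = 0.07153,
    theta0 = -8.66118, theta1 = 0.08801,
    mu1 = 22.10156, mu2 = 2.48820, mu3 = 1.56162, nu3 = 1.27849,
    rho2 = 11.76860, rho3 = 3.41989, rho4 = 63.92514,
    zero_mask = c("nu1", "nu2", "rho1"), days_per_year = days_per_year)
}

# Published parameter table (estimate, SE, Z) for regression checks.
table2_published <- data.frame(
  parameter = c("gamma1", "beta1", "gamma2", "beta2", "theta0", "theta1",
                "mu1", "mu2", "mu3", "nu3", "rho2", "rho3", "rho4"),
  estimate = c(6.63570, -0.03652, -3.06931, 0.07153, -8.66118, 0.08801,
               22.10156, 2.48820, 1.56162, 1.27849, 11.76860, 3.41989,
               63.92514),
  se = c(1.21893, 0.01631, 1.22697, 0.01667, 1.48644, 0.01828, 4.95434,
         0.37993, 0.20294, 0.17391, 0.99634, 0.38393, 4.11394),
  z = c(5.44388, -2.23902, -2.50153, 4.29057, -5.82680, 4.81391, 4.46105,
        6.54912, 7.69509, 7.35165, 11.81180, 8.90762, 15.53865))

# A random fully-parameterised (unmasked) model in a plausible rate range.
random_params <- function() {
  stroke_params(
    gamma1 = rnorm(1, 3, 1), beta1 = rnorm(1, 0, 0.03),
    gamma2 = rnorm(1, -2, 1), beta2 = rnorm(1, 0.05, 0.02),
    theta0 = rnorm(1, -8, 1), theta1 = abs(rnorm(1, 0.08, 0.02)),
    mu1 = rexp(1, 1 / 10), mu2 = rexp(1, 1 / 3), mu3 = rexp(1, 1 / 2),
    nu1 = rexp(1, 2), nu2 = rexp(1, 2), nu3 = rexp(1, 1),
    rho1 = rexp(1, 2), rho2 = rexp(1, 1 / 5), rho3 = rexp(1, 1 / 3),
    rho4 = rexp(1, 1 / 50), zero_mask = character())
}

random_record <- function() {
  list(stroke_type = sample(c("haemorrhagic", "cerebral_infarction", "tia"), 1),
       age = runif(1, 40, 100),
       los_days = rexp(1, 1 / 30) + 0.5,
       mode = sample(c("death", "nursing_home", "usual_residence"), 1))
}

contribution_of <- function(rec, params) {
  switch(rec$stroke_type,
         tia = contribution_tia(rec, params),
         cerebral_infarction = contribution_ci(rec, params),
         haemorrhagic = contribution_haem(rec, params))
}

# Plain truncated Taylor series exp(A t) (30+ terms with scaling), written
# here so the test oracle is independent of the package internals.
series_expm <- function(A, t) {
  M <- A * t
  k <- max(0L, ceiling(log2(max(1, max(abs(M))))))
  M <- M / 2^k
  E <- diag(nrow(A)); term <- diag(nrow(A))
  for (j in 1:30) {
    term <- term %*% M / j
    E <- E + term
  }
  for (j in seq_len(k)) E <- E %*% E
  E
}
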