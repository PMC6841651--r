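## Closed-form likelihood of the observed (type, age, stay, mode) records.
##
## Each patient contributes the sub-density of a stay of length s ending in
## the observed discharge mode, which for this upper-bidiagonal generator is
## a short sum of exponential terms in the cumulative exit rates
##   r1 = mu1 + nu1 + rho1 + lambda1(x),
##   r2 = mu2 + nu2 + rho2 + lambda2(x),
##   r3 = mu3 + nu3 + rho3,
## i.e. divided differences of exp(-r s).  Stays are stored in days and
## converted to years exactly once, here.

## Per-year cumulative exit rates for a vector of ages.
rate_bundle <- function(age, params) {
  v <- params$values
  v[params$zero_mask] <- 0
  lam1 <- exp(v["gamma1"] + v["beta1"] * age)
  lam2 <- exp(v["gamma2"] + v["beta2"] * age)
  list(lam1 = unname(lam1), lam2 = unname(lam2),
       r1 = unname(v["mu1"] + v["nu1"] + v["rho1"] + lam1),
       r2 = unname(v["mu2"] + v["nu2"] + v["rho2"] + lam2),
       r3 = unname(v["mu3"] + v["nu3"] + v["rho3"]),
       p = mild_tia_probability(age, params))
}

## Exit rate from phase k to the observed mode, for mode index vector m.
.exit_rate <- function(v, phase, m) {
  rates <- switch(phase,
    `1` = c(v["mu1"], v["nu1"], v["rho1"]),
    `2` = c(v["mu2"], v["nu2"], v["rho2"]),
    `3` = c(v["mu3"], v["nu3"], v["rho3"]),
    `4` = c(0, 0, v["rho4"]))
  unname(rates[m])
}

## Vectorised contribution for all records of one stroke type.
## age, s_years, mode_idx are parallel vectors; returns the likelihood values.
contributions_by_type <- function(type, age, s_years, mode_idx, params) {
  v <- params$values
  v[params$zero_mask] <- 0
  rb <- rate_bundle(age, params)
  if (type == "tia") {
    term3 <- (1 - rb$p) * exp(-rb$r3 * s_years) * .exit_rate(v, 3, mode_idx)
    term4 <- ifelse(mode_idx == 3L,
                    rb$p * exp(-v[["rho4"]] * s_years) * v[["rho4"]], 0)
    term3 + term4
  } else if (type == "cerebral_infarction") {
    exp(-rb$r2 * s_years) * .exit_rate(v, 2, mode_idx) +
      rb$lam2 * dd1(rb$r3, rb$r2, s_years) * .exit_rate(v, 3, mode_idx)
  } else {
    exp(-rb$r1 * s_years) * .exit_rate(v, 1, mode_idx) +
      rb$lam1 * dd1(rb$r1, rb$r2, s_years) * .exit_rate(v, 2, mode_idx) +
      rb$lam1 * rb$lam2 * dd2(rb$r1, rb$r2, rb$r3, s_years) *
        .exit_rate(v, 3, mode_idx)
  }
}

.check_record <- function(rec, type = NULL) {
  stopifnot(is.list(rec),
            all(c("stroke_type", "age", "los_days", "mode") %in% names(rec)))
  if (!is.null(type) && rec$stroke_type != type)
    stop("record has stroke type '", rec$stroke_type,
         "'; this contribution applies to '", type, "' records")
  if (rec$los_days <= 0) stop("length of stay must be positive")
  if (rec$age < 0 || rec$age > 120) stop("age outside [0, 120]")
  if (!rec$mode %in% .modes) stop("unknown discharge mode: ", rec$mode)
  invisible(rec)
}

.contribution_one <- function(rec, params, type) {
  .check_record(rec, type)
  contributions_by_type(type, rec$age, rec$los_days / params$days_per_year,
                        match(rec$mode, .modes), params)
}

#' Likelihood contribution of one TIA patient
#'
#' Mixture of the severe (phase 3) sub-density with weight \eqn{1 - p(x)}
#' and the mild (phase 4) sub-density with weight \eqn{p(x)}; the phase-4
#' term appears only for discharge to the usual residence, since phase 4 has
#' no death or nursing-home exit (the \eqn{0^0 = 1} convention).
#'
#' @param rec list or one-row data.frame with \code{stroke_type}, \code{age},
#'   \code{los_days}, \code{mode}.
#' @param params a \code{stroke_params} object.
#' @return the likelihood contribution (positive).
#' @export
contribution_tia <- function(rec, params)
  .contribution_one(rec, params, "tia")

#' Likelihood contribution of one cerebral infarction patient
#'
#' Two terms: discharge directly from phase 2, and discharge from phase 3
#' after progression, the latter carrying the first divided difference of
#' \eqn{\exp(-r s)} between the phase-2 and phase-3 cumulative exit rates
#' (evaluated by its limit form when the rates nearly tie).
#'
#' @inheritParams contribution_tia
#' @return the likelihood contribution (positive).
#' @export
contribution_ci <- function(rec, params)
  .contribution_one(rec, params, "cerebral_infarction")

#' Likelihood contribution of one haemorrhagic stroke patient
#'
#' Three terms for stays ending from phase 1, 2 or 3; the phase-3 term is the
#' second divided difference of \eqn{\exp(-r s)} over the three cumulative
#' exit rates, evaluated tie-stably.
#'
#' @inheritParams contribution_tia
#' @return the likelihood contribution (positive).
#' @export
contribution_haem <- function(rec, params)
  .contribution_one(rec, params, "haemorrhagic")

#' Dataset log-likelihood
#'
#' Sum of the log likelihood contributions over all patient records.
#'
#' @param records data.frame with columns \code{stroke_type}, \code{age},
#'   \code{los_days}, \code{mode} (as produced by [read_patient_csv()] or
#'   [simulate_cohort()]).
#' @param params a \code{stroke_params} object.
#' @return scalar log-likelihood, with attribute \code{underflow = TRUE} and
#'   value \code{-Inf} if any contribution underflows to zero.
#' @export
log_likelihood <- function(records, params) {
  if (NROW(records) == 0L) stop("empty dataset")
  ll <- 0
  underflow <- FALSE
  s_years <- records$los_days / params$days_per_year
  mode_idx <- match(records$mode, .modes)
  if (anyNA(mode_idx)) stop("unknown discharge mode in records")
  for (type in unique(records$stroke_type)) {
    i <- records$stroke_type == type
    L <- contributions_by_type(type, records$age[i], s_years[i],
                               mode_idx[i], params)
    if (any(L <= 0 | !is.finite(L))) { underflow <- TRUE; ll <- -Inf; break }
    ll <- ll + sum(log(L))
  }
  structure(ll, underflow = underflow)
}

#' Matrix-exponential likelihood oracle
#'
#' The mode-specific stay density \eqn{\alpha' \exp(Ts) t_A e_m} evaluated
#' through a truncated uniformization series for the matrix exponential —
#' an independent route to the same quantity as the closed-form
#' contributions, intended for verification.
#'
#' @inheritParams contribution_tia
#' @return the likelihood contribution (per year scale, matching the
#'   closed-form contributions).
#' @export
oracle_density <- function(rec, params) {
  .check_record(rec)
  gen <- build_generator(rec$stroke_type, rec$age, params)
  s <- rec$los_days / params$days_per_year
  E <- expm_series(gen$Tmat, s)
  sum((gen$alpha %*% E) * gen$tA[, match(rec$mode, .modes)])
}

## Uniformization (scaled Taylor series) matrix exponential; independent of
## the closed-form divided-difference route.  A is a generator-like matrix.
expm_series <- function(A, t) {
  n <- nrow(A)
  M <- A * t
  ## scale so the series converges quickly, then square back
  k <- max(0L, ceiling(log2(max(1, max(abs(M))))))
  M <- M / 2^k
  E <- diag(n); term <- diag(n)
  for (j in 1:40) {
    term <- term %*% M / j
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (j in seq_len(k)) E <- E %*% E
  E
}
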