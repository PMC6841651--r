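## Key performance indicators of the fitted phase-type recovery model.
## All user-facing times are lengths of stay in DAYS; internally the
## generator carries per-year rates and times are converted once via
## gen$days_per_year.

.days_to_years <- function(gen, y) y / gen$days_per_year

#' Length-of-stay density
#'
#' \eqn{f_X(y) = \alpha' \exp(Ty) t_A 1_3}, the probability density of the
#' total in-patient stay, per day.
#'
#' @param y length of stay in days (vectorised, non-negative).
#' @param gen a \code{stroke_generator} from [build_generator()].
#' @return density values per day.
#' @export
los_density <- function(y, gen) {
  if (any(y < 0)) stop("length of stay must be non-negative")
  t <- .days_to_years(gen, y)
  occ <- occupancy(gen, t)
  as.vector(occ %*% rowSums(gen$tA)) / gen$days_per_year
}

#' Length-of-stay distribution function
#'
#' \eqn{F_X(y) = 1 - \alpha' \exp(Ty) 1_4}.
#'
#' @inheritParams los_density
#' @return probabilities in [0, 1].
#' @export
los_cdf <- function(y, gen) {
  if (any(y < 0)) stop("length of stay must be non-negative")
  1 - los_survival(y, gen)
}

#' Probability of remaining in hospital
#'
#' \eqn{P(X > y) = \alpha' \exp(Ty) 1_4}.
#'
#' @inheritParams los_density
#' @return survival probabilities.
#' @export
los_survival <- function(y, gen) {
  if (any(y < 0)) stop("length of stay must be non-negative")
  rowSums(occupancy(gen, .days_to_years(gen, y)))
}

#' Absorption (ultimate destination) probabilities by starting phase
#'
#' The 4x3 matrix \eqn{P = (-T)^{-1} t_A}; entry (i, j) is the probability
#' that a patient currently in phase i is eventually discharged by mode j.
#' Computed by back-substitution on the upper-triangular system.
#'
#' @param gen a \code{stroke_generator}.
#' @return 4x3 row-stochastic matrix (rows phases, columns death,
#'   nursing home, usual residence).
#' @export
absorption_probs <- function(gen) {
  if (any(gen$Lambda <= 0))
    stop("degenerate model: a phase has no exit (singular T)")
  P <- backsolve(-gen$Tmat, gen$tA)
  dimnames(P) <- dimnames(gen$tA)
  P
}

#' Ultimate destination percentages for a patient profile
#'
#' \eqn{\alpha' P} expressed in percent: the chance that a patient of the
#' given age and stroke type is ultimately discharged by death, to a nursing
#' home, or to the usual residence.
#'
#' @param age age at admission in years.
#' @param stroke_type stroke type label.
#' @param params a \code{stroke_params} object.
#' @param digits decimal places for reporting (default 1, as conventionally
#'   tabulated); use \code{NULL} for unrounded values.
#' @return named length-3 vector of percentages.
#' @export
destination_percentages <- function(age, stroke_type, params, digits = 1) {
  gen <- build_generator(stroke_type, age, params)
  pct <- 100 * as.vector(gen$alpha %*% absorption_probs(gen))
  names(pct) <- .modes
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  pct
}

#' Mean length of stay
#'
#' \eqn{E\{X\} = \alpha' (-T)^{-1} 1_4}, in days.
#'
#' @param gen a \code{stroke_generator}.
#' @return mean stay in days.
#' @export
mean_los <- function(gen) {
  sum(gen$alpha * neg_T_solve(gen, rep(1, 4))) * gen$days_per_year
}

#' Mean length of stay conditional on discharge mode
#'
#' \eqn{E\{X \mid \mathrm{mode}\} = \alpha'(-T)^{-1} P_m / (\alpha' P_m)}
#' where \eqn{P_m} is the mode's column of the absorption matrix.
#'
#' @param gen a \code{stroke_generator}.
#' @param mode one of \code{"death"}, \code{"nursing_home"},
#'   \code{"usual_residence"}.
#' @return conditional mean stay in days.
#' @export
mean_los_by_destination <- function(gen, mode) {
  mode <- match.arg(mode, .modes)
  P <- absorption_probs(gen)
  reach <- sum(gen$alpha * P[, mode])
  if (reach <= 0)
    stop("conditional mean undefined: mode '", mode,
         "' has zero reach probability")
  num <- sum(gen$alpha * neg_T_solve(gen, P[, mode]))
  num / reach * gen$days_per_year
}

#' Mean residual length of stay
#'
#' \eqn{E\{X - y \mid X > y\}}: the expected further stay of a patient who
#' has already been in hospital y days.  As y grows this tends to the mean
#' sojourn of the last common recovery phase,
#' \eqn{\mathrm{days\_per\_year}/(\mu_3+\nu_3+\rho_3)}.
#'
#' @inheritParams los_density
#' @return expected residual stay in days.
#' @export
mean_residual <- function(y, gen) {
  surv <- los_survival(y, gen)
  if (any(surv <= 0)) stop("mean residual stay undefined: survival is zero")
  occ <- occupancy(gen, .days_to_years(gen, y))
  m <- neg_T_solve(gen, rep(1, 4))
  as.vector(occ %*% m) / surv * gen$days_per_year
}

#' Destination probabilities given an incurred stay
#'
#' \eqn{P(y) = \alpha' \exp(Ty) P / (\alpha' \exp(Ty) 1_4)}: how the
#' likely discharge destination shifts after y days in hospital.
#'
#' @inheritParams los_density
#' @return length(y) x 3 matrix of probabilities, rows summing to 1.
#' @export
destination_probs_given_stay <- function(y, gen) {
  surv <- los_survival(y, gen)
  if (any(surv <= 0)) stop("undefined: survival is zero at some y")
  occ <- occupancy(gen, .days_to_years(gen, y))
  out <- (occ %*% absorption_probs(gen)) / surv
  colnames(out) <- .modes
  out
}

#' Cumulative probability of discharge by mode
#'
#' The sub-distribution function
#' \eqn{\alpha' (I - \exp(Ty)) (-T)^{-1} t_A e_m}: the probability of having
#' been discharged by mode m within y days.  Summed over modes it equals the
#' overall stay distribution function; its y to infinity limit is the
#' ultimate destination probability.
#'
#' @inheritParams los_density
#' @param mode discharge mode label.
#' @return nondecreasing probabilities.
#' @export
cumulative_discharge_by_mode <- function(y, gen, mode) {
  mode <- match.arg(mode, .modes)
  if (any(y < 0)) stop("length of stay must be non-negative")
  P <- absorption_probs(gen)
  occ <- occupancy(gen, .days_to_years(gen, y))
  ultimate <- sum(gen$alpha * P[, mode])
  ultimate - as.vector(occ %*% P[, mode])
}

#' Ultimate destination percentage table
#'
#' Destination percentages for each requested age and stroke type; the
#' standard three-age report has rows for ages 65, 75 and 85.
#'
#' @param ages ages in years.
#' @param params a \code{stroke_params} object.
#' @param digits reporting decimal places (default 1); \code{NULL} for raw.
#' @return data.frame with columns age, stroke_type, death, nursing_home,
#'   usual_residence.
#' @export
make_table3 <- function(ages = c(65, 75, 85), params, digits = 1) {
  grid <- expand.grid(stroke_type = .stroke_types, age = ages,
                      stringsAsFactors = FALSE)
  pct <- t(mapply(function(a, ty)
    destination_percentages(a, ty, params, digits = digits),
    grid$age, grid$stroke_type))
  out <- data.frame(age = grid$age, stroke_type = grid$stroke_type, pct)
  names(out)[3:5] <- .modes
  rownames(out) <- NULL
  out
}

#' Mean length-of-stay table by destination
#'
#' Conditional mean stays (days) by discharge mode plus the overall mean,
#' for each requested age and stroke type.
#'
#' @inheritParams make_table3
#' @return data.frame with columns age, stroke_type, death, nursing_home,
#'   usual_residence, all.
#' @export
make_table4 <- function(ages = c(65, 75, 85), params, digits = 1) {
  grid <- expand.grid(stroke_type = .stroke_types, age = ages,
                      stringsAsFactors = FALSE)
  rows <- t(mapply(function(a, ty) {
    gen <- build_generator(ty, a, params)
    c(vapply(.modes, function(m) mean_los_by_destination(gen, m), numeric(1)),
      all = mean_los(gen))
  }, grid$age, grid$stroke_type))
  if (!is.null(digits)) rows <- round_half_up(rows, digits)
  out <- data.frame(age = grid$age, stroke_type = grid$stroke_type, rows)
  names(out)[3:6] <- c(.modes, "all")
  rownames(out) <- NULL
  out
}

## Round half away from zero (tables use conventional half-up rounding,
## not banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
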