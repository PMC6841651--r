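#' @importFrom stats optim pnorm rexp runif rnorm rmultinom integrate setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

## Canonical orderings used throughout the package.
.stroke_types <- c("haemorrhagic", "cerebral_infarction", "tia")
.modes <- c("death", "nursing_home", "usual_residence")

## The 16 estimable parameters, in reporting order.  mu4 and nu4 are
## structural zeros (phase 4 can only discharge home) and are not counted.
.param_names <- c("gamma1", "beta1", "gamma2", "beta2", "theta0", "theta1",
                  "mu1", "mu2", "mu3", "nu1", "nu2", "nu3",
                  "rho1", "rho2", "rho3", "rho4")
.rate_names <- c("mu1", "mu2", "mu3", "nu1", "nu2", "nu3",
                 "rho1", "rho2", "rho3", "rho4")

#' Stroke recovery model parameters
#'
#' Container for the 16 parameters of the four-phase stroke recovery model:
#' log-link coefficients \code{gamma1, beta1} and \code{gamma2, beta2} for the
#' age-dependent phase-progression intensities
#' \eqn{\lambda_i(x) = \exp(\gamma_i + \beta_i x)} (\eqn{i = 1, 2}),
#' complementary log-log coefficients \code{theta0, theta1} for the
#' probability \eqn{p(x) = \exp\{-\exp(\theta_0 + \theta_1 x)\}} that a TIA
#' patient of age \eqn{x} enters the mild phase 4, and per-year exit rates
#' \code{mu1..mu3} (death), \code{nu1..nu3} (nursing home) and
#' \code{rho1..rho4} (usual residence) by phase.  Phase 4 has no death or
#' nursing-home exit (\eqn{\mu_4 = \nu_4 = 0}, structural).
#'
#' @param gamma1,beta1,gamma2,beta2 log-link coefficients (age in years).
#' @param theta0,theta1 complementary log-log coefficients for the mild-TIA
#'   probability.
#' @param mu1,mu2,mu3 death rates per year from phases 1-3.
#' @param nu1,nu2,nu3 nursing-home discharge rates per year from phases 1-3.
#' @param rho1,rho2,rho3,rho4 usual-residence discharge rates per year from
#'   phases 1-4.
#' @param zero_mask character vector of rate names fixed at exactly zero.
#'   The default revised model masks \code{nu1}, \code{nu2} and \code{rho1}.
#' @param days_per_year conversion constant between the per-year rate scale
#'   and lengths of stay reported in days.
#'
#' @return An object of class \code{stroke_params}.
#' @seealso [fitted_params()] for the published estimate set,
#'   [build_generator()] for the age-specific generator.
#' @export
stroke_params <- function(gamma1, beta1, gamma2, beta2, theta0, theta1,
                          mu1, mu2, mu3, nu1 = 0, nu2 = 0, nu3,
                          rho1 = 0, rho2, rho3, rho4,
                          zero_mask = c("nu1", "nu2", "rho1"),
                          days_per_year = 365.25) {
  values <- c(gamma1 = gamma1, beta1 = beta1, gamma2 = gamma2, beta2 = beta2,
              theta0 = theta0, theta1 = theta1,
              mu1 = mu1, mu2 = mu2, mu3 = mu3,
              nu1 = nu1, nu2 = nu2, nu3 = nu3,
              rho1 = rho1, rho2 = rho2, rho3 = rho3, rho4 = rho4)
  zero_mask <- as.character(zero_mask)
  values[zero_mask] <- 0
  obj <- structure(
    list(values = values, zero_mask = zero_mask,
         days_per_year = days_per_year),
    class = "stroke_params")
  validate_params(obj)
  obj
}

validate_params <- function(p) {
  stopifnot(inherits(p, "stroke_params"))
  v <- p$values
  if (!identical(names(v), .param_names))
    stop("parameter vector must contain exactly the 16 model parameters")
  if (any(!is.finite(v)))
    stop("non-finite parameter value")
  bad <- setdiff(p$zero_mask, .rate_names)
  if (length(bad))
    stop("zero_mask may only contain rate parameters, not: ",
         paste(bad, collapse = ", "))
  if (any(v[.rate_names] < 0))
    stop("rate parameters must be non-negative")
  if (any(v[p$zero_mask] != 0))
    stop("masked parameters must be exactly 0")
  if (!is.numeric(p$days_per_year) || p$days_per_year <= 0)
    stop("days_per_year must be positive")
  invisible(p)
}

#' @export
print.stroke_params <- function(x, ...) {
  cat("Stroke phase-type model parameters (",
      length(free_param_names(x)), " free)\n", sep = "")
  print(round(x$values, 5))
  cat("zero mask:", if (length(x$zero_mask)) paste(x$zero_mask, collapse = ", ")
      else "(none)", "\n")
  cat("days per year:", x$days_per_year, "\n")
  invisible(x)
}

#' Names of the freely estimable parameters
#'
#' The 16 model parameters minus those in the zero mask (13 in the default
#' revised model).
#'
#' @param params a \code{stroke_params} object.
#' @return character vector in reporting order.
#' @export
free_param_names <- function(params) {
  setdiff(.param_names, params$zero_mask)
}

## Replace a named subset of parameter values, re-validating.
set_params <- function(params, new_values) {
  stopifnot(all(names(new_values) %in% .param_names))
  params$values[names(new_values)] <- new_values
  params$values[params$zero_mask] <- 0
  validate_params(params)
  params
}

#' Published parameter estimates for the revised model
#'
#' The 13 maximum-likelihood estimates of the revised model (nursing-home
#' exits from phases 1-2 and home discharge from phase 1 removed), as fitted
#' to the Belfast City Hospital stroke cohort.  Shipped as a YAML fixture in
#' \code{inst/extdata/params_fitted.yaml}; this helper loads it.
#'
#' @param days_per_year day-count constant; default 365.25.
#' @return A \code{stroke_params} object.
#' @export
fitted_params <- function(days_per_year = 365.25) {
  path <- system.file("extdata", "params_fitted.yaml", package = "phrex",
                      mustWork = TRUE)
  p <- read_params(path)
  p$days_per_year <- days_per_year
  p
}

#' Read model parameters from a YAML config file
#'
#' The file holds the 16 parameter names with numeric values, plus optional
#' \code{zero_mask} (list of rate names) and \code{days_per_year} entries.
#'
#' @param path file path.
#' @return A \code{stroke_params} object.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(.param_names, names(cfg))
  if (length(missing))
    stop("parameter file is missing: ", paste(missing, collapse = ", "))
  vals <- vapply(cfg[.param_names], as.numeric, numeric(1))
  do.call(stroke_params, c(
    as.list(vals),
    list(zero_mask = as.character(unlist(cfg$zero_mask %||% character())),
         days_per_year = as.numeric(cfg$days_per_year %||% 365.25))))
}

#' Write model parameters to a YAML config file
#'
#' @param params a \code{stroke_params} object.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- c(as.list(params$values),
           list(zero_mask = as.list(params$zero_mask),
                days_per_year = params$days_per_year))
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
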