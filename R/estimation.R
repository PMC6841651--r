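## Staged backward maximum-likelihood estimation.
##
## The phases are aligned with diagnosis labels, so the data can be fitted
## backwards through the severity pathway: TIA records inform the phase-3/4
## parameters, infarction records add phase 2, haemorrhagic records add
## phase 1, and a final joint fit frees everything.  Optimization runs on a
## transformed scale (log for rates, identity for the link coefficients);
## standard errors are mapped back to the natural scale by the delta method.

.link_names <- c("gamma1", "beta1", "gamma2", "beta2", "theta0", "theta1")
.log_rate_floor <- log(1e-8)

.to_trans <- function(values, names) {
  ifelse(names %in% .rate_names, log(pmax(values, 1e-8)), values)
}
.from_trans <- function(theta, names) {
  ifelse(names %in% .rate_names, exp(theta), theta)
}

.negll_factory <- function(records, params, free_names) {
  s_years <- records$los_days / params$days_per_year
  mode_idx <- match(records$mode, .modes)
  types <- unique(records$stroke_type)
  idx <- lapply(types, function(ty) records$stroke_type == ty)
  names(idx) <- types
  function(theta) {
    pp <- set_params(params,
                     setNames(.from_trans(theta, free_names), free_names))
    ll <- 0
    for (ty in types) {
      i <- idx[[ty]]
      L <- contributions_by_type(ty, records$age[i], s_years[i],
                                 mode_idx[i], pp)
      if (any(L <= 0 | !is.finite(L))) return(1e10)
      ll <- ll + sum(log(L))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

.optimize_free <- function(records, params, free_names, control = list()) {
  negll <- .negll_factory(records, params, free_names)
  start <- .to_trans(params$values[free_names], free_names)
  lower <- ifelse(free_names %in% .rate_names, .log_rate_floor, -50)
  upper <- ifelse(free_names %in% .rate_names, log(1e4), 50)
  clamp <- function(th) pmin(pmax(th, lower), upper)
  run_lbfgsb <- function(th) optim(
    clamp(th), negll, method = "L-BFGS-B", lower = lower, upper = upper,
    control = modifyList(list(maxit = 500, factr = 1e7,
                              ndeps = rep(1e-6, length(th))), control))
  fit <- run_lbfgsb(start)
  ## line-search failures on flat ridges: alternate a simplex polish with a
  ## fresh quasi-Newton pass (the log transform already enforces positivity)
  tries <- 0L
  while (fit$convergence != 0 && tries < 2L) {
    nm <- optim(fit$par, function(th) negll(clamp(th)),
                method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
    cand <- run_lbfgsb(nm$par)
    best <- if (cand$value <= min(fit$value, nm$value)) cand
            else { nm$par <- clamp(nm$par); nm }
    if (best$value > fit$value - 1e-9) { fit <- best; break }
    fit <- best
    tries <- tries + 1L
  }
  converged <- fit$convergence == 0
  if (!converged) {
    ## accept a stationary point the line search could not certify:
    ## projected finite-difference gradient on the transformed scale
    h <- 1e-5
    g <- vapply(seq_along(fit$par), function(i) {
      e <- numeric(length(fit$par)); e[i] <- h
      (negll(fit$par + e) - negll(fit$par - e)) / (2 * h)
    }, numeric(1))
    at_lo <- fit$par <= lower + 1e-10
    at_hi <- fit$par >= upper - 1e-10
    g[at_lo & g > 0] <- 0
    g[at_hi & g < 0] <- 0
    converged <- max(abs(g)) < 0.5
  }
  est <- setNames(.from_trans(fit$par, free_names), free_names)
  list(params = set_params(params, est), loglik = -fit$value,
       converged = converged, theta = fit$par,
       message = fit$message)
}

## Parameter groups per stage of the backward procedure.
.stage_free <- list(
  tia  = c("theta0", "theta1", "mu3", "nu3", "rho3", "rho4"),
  ci   = c("gamma2", "beta2", "mu2", "nu2", "rho2"),
  joint11 = c("theta0", "theta1", "mu3", "nu3", "rho3", "rho4",
              "gamma2", "beta2", "mu2", "nu2", "rho2"),
  haem = c("gamma1", "beta1", "mu1", "nu1", "rho1"))

## Method-of-moments starting values from the data, used when no prior
## stage supplies them: exit rates from 1/mean sojourn split by observed
## mode fractions, the mild-TIA mixing probability from the share of short
## home discharges, and flat age slopes.
moment_start <- function(records, params) {
  dpy <- params$days_per_year
  upd <- c()
  tia <- records[records$stroke_type == "tia", , drop = FALSE]
  if (nrow(tia)) {
    short <- tia$mode == "usual_residence" & tia$los_days < 7
    p_hat <- min(max(mean(short), 0.05), 0.95)
    mean_age <- mean(tia$age)
    long <- tia[!short, , drop = FALSE]
    r3 <- 1 / max(mean(long$los_days) / dpy, 1e-3)
    frac <- (table(factor(long$mode, levels = .modes)) + 0.5) /
      (nrow(long) + 1.5)
    rho4 <- 1 / max(mean(tia$los_days[short]) / dpy, 1e-3)
    upd <- c(upd, theta0 = log(-log(p_hat)) - 0.05 * mean_age, theta1 = 0.05,
             mu3 = r3 * frac[[1]], nu3 = r3 * frac[[2]],
             rho3 = r3 * frac[[3]], rho4 = rho4)
  }
  ci <- records[records$stroke_type == "cerebral_infarction", , drop = FALSE]
  if (nrow(ci)) {
    r2 <- 1 / max(mean(ci$los_days) / dpy, 1e-3)
    frac <- (table(factor(ci$mode, levels = .modes)) + 0.5) / (nrow(ci) + 1.5)
    upd <- c(upd, gamma2 = log(r2 / 2), beta2 = 0,
             mu2 = r2 * frac[[1]], nu2 = r2 * frac[[2]],
             rho2 = r2 * frac[[3]])
  }
  haem <- records[records$stroke_type == "haemorrhagic", , drop = FALSE]
  if (nrow(haem)) {
    r1 <- 1 / max(mean(haem$los_days) / dpy, 1e-3)
    frac <- (table(factor(haem$mode, levels = .modes)) + 0.5) /
      (nrow(haem) + 1.5)
    upd <- c(upd, gamma1 = log(r1 / 2), beta1 = 0,
             mu1 = r1 * frac[[1]], nu1 = r1 * frac[[2]],
             rho1 = r1 * frac[[3]])
  }
  upd <- upd[!names(upd) %in% params$zero_mask]
  is_rate <- names(upd) %in% .rate_names
  upd[is_rate] <- pmax(upd[is_rate], 1e-3)
  set_params(params, upd)
}

#' Staged backward maximum-likelihood fit
#'
#' Runs the five-stage backward procedure: (1) TIA records alone estimate
#' the phase-3/4 parameters; (2) with those fixed, cerebral infarction
#' records estimate the phase-2 parameters; (3) TIA and infarction records
#' jointly update all 11; (4) with those fixed, haemorrhagic records
#' estimate the phase-1 parameters; (5) all records jointly free every
#' unmasked parameter, restarting from jittered copies of the staged
#' estimates and keeping the best log-likelihood.
#'
#' @param records patient records data.frame (columns \code{stroke_type},
#'   \code{age}, \code{los_days}, \code{mode}).
#' @param params template \code{stroke_params} supplying the zero mask and
#'   day-count constant; its values are ignored unless
#'   \code{init = "params"}.
#' @param init \code{"moments"} (default) derives stage-1 starting values
#'   from the data; \code{"params"} starts from \code{params} itself.
#' @param n_restarts jittered restarts at the final stage.
#' @param seed integer seed controlling the jitter.
#' @return A \code{stroke_fit}: estimates, covariance, standard errors,
#'   Z statistics, p-values, log-likelihood and the per-stage trace.
#' @export
fit_staged <- function(records, params = fitted_params(), init = "moments",
                       n_restarts = 3L, seed = 1L) {
  init <- match.arg(init, c("moments", "params"))
  present <- intersect(.stroke_types, unique(records$stroke_type))
  if (length(present) < 3L)
    warning("running a partial pipeline: missing ",
            paste(setdiff(.stroke_types, present), collapse = ", "))
  cur <- if (init == "moments") moment_start(records, params) else params
  mask <- params$zero_mask
  trace <- list()
  run_stage <- function(stage, data, free) {
    free <- setdiff(free, c(mask, "mu4", "nu4"))
    if (!nrow(data) || !length(free)) return(invisible(NULL))
    res <- .optimize_free(data, cur, free)
    if (!res$converged)
      stop("stage '", stage, "' did not converge: ", res$message,
           call. = FALSE)
    trace[[stage]] <<- list(free = free, loglik = res$loglik,
                            converged = res$converged,
                            values = res$params$values)
    cur <<- res$params
    invisible(res)
  }
  sub <- function(types) records[records$stroke_type %in% types, , drop = FALSE]
  run_stage("tia", sub("tia"), .stage_free$tia)
  run_stage("ci", sub("cerebral_infarction"), .stage_free$ci)
  run_stage("joint11", sub(c("tia", "cerebral_infarction")),
            .stage_free$joint11)
  run_stage("haem", sub("haemorrhagic"), .stage_free$haem)
  ## final joint stage with jittered restarts
  free <- setdiff(.param_names, c(mask, "mu4", "nu4"))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    start <- cur
    if (r > 1L) {
      th <- .to_trans(cur$values[free], free)
      th <- th + rnorm(length(th), 0, 0.05)
      start <- set_params(cur, setNames(.from_trans(th, free), free))
    }
    res <- tryCatch(.optimize_free(records, start, free),
                    error = function(e) NULL)
    if (!is.null(res) && res$converged &&
        (is.null(best) || res$loglik > best$loglik))
      best <- res
  }
  if (is.null(best))
    stop("final joint stage did not converge; trace: ",
         paste(names(trace), collapse = " -> "))
  trace[["all"]] <- list(free = free, loglik = best$loglik, converged = TRUE)
  fit <- structure(
    list(params = best$params, free_names = free,
         estimate = setNames(best$params$values[free], free),
         loglik = best$loglik, stage_trace = trace,
         n = nrow(records), seed = seed, schema_version = 1L),
    class = "stroke_fit")
  info <- observed_information(records, best$params, free)
  fit$cov <- info$cov
  fit$cov_flag <- info$flag
  fit$se <- sqrt(pmax(diag(info$cov), 0))
  fit$z <- fit$estimate / fit$se
  fit$p <- 2 * pnorm(-abs(fit$z))
  fit
}

#' Observed information and asymptotic covariance
#'
#' Negative Hessian of the log-likelihood at the supplied estimates,
#' computed by central finite differences on the transformed scale (log for
#' rates), inverted, and mapped to the natural scale by the delta method.
#'
#' @param records patient records data.frame.
#' @param params \code{stroke_params} at the maximum-likelihood estimates.
#' @param free_names parameters to differentiate (default: all unmasked).
#' @return list with \code{cov} (natural-scale covariance, named),
#'   \code{info} (transformed-scale observed information) and \code{flag}
#'   (\code{"ok"} or \code{"pseudo_inverse"} when the information is not
#'   positive definite).
#' @export
observed_information <- function(records, params,
                                 free_names = free_param_names(params)) {
  negll <- .negll_factory(records, params, free_names)
  theta <- .to_trans(params$values[free_names], free_names)
  k <- length(theta)
  h <- pmax(1e-4, 1e-4 * abs(theta))
  H <- matrix(0, k, k)
  f0 <- negll(theta)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (negll(theta + ei) - 2 * f0 + negll(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (negll(theta + ei + ej) - negll(theta + ei - ej) -
             negll(theta - ei + ej) + negll(theta - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  info <- (H + t(H)) / 2   # observed information on the transformed scale
  ed <- eigen(info, symmetric = TRUE)
  thr <- max(abs(ed$values), 1e-300) * 1e-10
  if (all(ed$values > thr)) {
    cov_t <- chol2inv(chol(info))
    flag <- "ok"
  } else {
    ## flat or boundary directions (e.g. a rate pinned at zero) carry no
    ## information: give them a very large variance rather than collapsing
    ## them, so their Z statistics correctly shrink to zero
    warning("observed information is not positive definite; ",
            "flat directions mapped to large variances")
    inv_ev <- ifelse(ed$values > thr, 1 / ed$values, 1 / thr)
    cov_t <- ed$vectors %*% (inv_ev * t(ed$vectors))
    flag <- "pseudo_inverse"
  }
  ## delta method: d(natural)/d(transformed) = rate for log-scale parameters
  nat <- params$values[free_names]
  D <- ifelse(free_names %in% .rate_names, nat, 1)
  cov_n <- t(cov_t * D) * D
  dimnames(cov_n) <- list(free_names, free_names)
  dimnames(info) <- list(free_names, free_names)
  list(cov = cov_n, info = info, flag = flag)
}

#' Z statistics and p-values for a fit
#'
#' Each Z statistic is the natural-scale estimate divided by its standard
#' error; p-values are two-sided normal tails.
#'
#' @param fit a \code{stroke_fit}.
#' @return data.frame with columns parameter, estimate, std_error, z_stat,
#'   p_value, laid out like a published parameter table.
#' @export
z_tests <- function(fit) {
  stopifnot(inherits(fit, "stroke_fit"))
  data.frame(parameter = fit$free_names,
             estimate = unname(fit$estimate),
             std_error = unname(fit$se),
             z_stat = unname(fit$z),
             p_value = unname(fit$p),
             row.names = NULL)
}

#' Prune rates indistinguishable from zero and refit
#'
#' Rates whose two-sided p-value exceeds the threshold and whose estimate
#' lies below the rate floor are added to the zero mask, and the model is
#' refitted without them — the model-revision step that removes transitions
#' the data cannot support.  Pruning that would leave a phase with no exit
#' at all is refused.
#'
#' @param fit a \code{stroke_fit} from the full (unpruned) model.
#' @param records the records the fit was computed on.
#' @param p_threshold p-value above which a rate is a candidate (default 0.90).
#' @param rate_floor natural-scale magnitude below which a candidate is
#'   considered negligible (default 0.05 per year).
#' @param seed seed for the refit.
#' @return the revised \code{stroke_fit}, with \code{pruned} listing the
#'   removed parameters.
#' @export
prune_rates <- function(fit, records, p_threshold = 0.90, rate_floor = 0.05,
                        seed = 1L) {
  stopifnot(inherits(fit, "stroke_fit"))
  cand <- fit$free_names[fit$free_names %in% .rate_names &
                           fit$p > p_threshold &
                           abs(fit$estimate) < rate_floor]
  if (!length(cand)) {
    fit$pruned <- character()
    return(fit)
  }
  new_mask <- union(fit$params$zero_mask, cand)
  ## phases 1-2 keep their onward progression, but phase 3 must retain at
  ## least one absorption rate and phase 4 its home discharge
  if (all(c("mu3", "nu3", "rho3") %in% new_mask))
    stop("refusing to prune ", paste(cand, collapse = ", "),
         ": phase 3 would be disconnected from absorption")
  if ("rho4" %in% new_mask)
    stop("refusing to prune rho4: phase 4 would have no exit")
  template <- fit$params
  template$zero_mask <- new_mask
  template$values[new_mask] <- 0
  refit <- fit_staged(records, params = template, init = "params",
                      n_restarts = 1L, seed = seed)
  refit$pruned <- cand
  refit
}

#' @export
print.stroke_fit <- function(x, ...) {
  cat("Phase-type stroke recovery model fit\n")
  cat("  records:", x$n, "  log-likelihood:", format(x$loglik), "\n")
  cat("  free parameters:", length(x$free_names), "\n")
  if (!is.null(x$pruned) && length(x$pruned))
    cat("  pruned:", paste(x$pruned, collapse = ", "), "\n")
  print(z_tests(x), digits = 5)
  invisible(x)
}
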