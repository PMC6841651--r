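#' Phase-progression intensity
#'
#' The age-dependent rate \eqn{\lambda_i(x) = \exp(\gamma_i + \beta_i x)} of
#' moving from recovery phase \eqn{i} to phase \eqn{i+1}, \eqn{i \in \{1,2\}}.
#'
#' @param phase 1 or 2 (phases 3 and 4 have no onward progression).
#' @param age age in years (vectorised).
#' @param params a \code{stroke_params} object.
#' @return rate per year, same length as \code{age}.
#' @export
progression_rate <- function(phase, age, params) {
  if (!(length(phase) == 1L && phase %in% c(1, 2)))
    stop("phase must be 1 or 2")
  stopifnot(all(is.finite(age)))
  v <- params$values
  if (phase == 1) unname(exp(v["gamma1"] + v["beta1"] * age))
  else unname(exp(v["gamma2"] + v["beta2"] * age))
}

#' Probability of a mild TIA
#'
#' Probability \eqn{p(x) = \exp\{-\exp(\theta_0 + \theta_1 x)\}} that a TIA
#' patient of age \eqn{x} starts in the mild phase 4 rather than phase 3.
#'
#' @param age age in years (vectorised).
#' @param params a \code{stroke_params} object.
#' @return probability in (0, 1).
#' @export
mild_tia_probability <- function(age, params) {
  stopifnot(all(is.finite(age)))
  v <- params$values
  unname(exp(-exp(v["theta0"] + v["theta1"] * age)))
}

#' Build the age-specific generator of the recovery process
#'
#' Assembles the 4x4 transient rate matrix \eqn{T}, the 4x3 absorption rate
#' matrix \eqn{t_A} (columns death, nursing home, usual residence) and the
#' initial phase distribution \eqn{\alpha} for one patient profile.
#' Haemorrhagic strokes enter phase 1, cerebral infarctions phase 2, and TIA
#' patients enter phase 3 with probability \eqn{1 - p(x)} and phase 4 with
#' probability \eqn{p(x)}.
#'
#' @param stroke_type one of \code{"haemorrhagic"}, \code{"cerebral_infarction"},
#'   \code{"tia"}.
#' @param age age at admission in years.
#' @param params a \code{stroke_params} object.
#' @return A \code{stroke_generator}: list with \code{Tmat}, \code{tA},
#'   \code{alpha}, \code{Lambda} (total exit rates per phase), \code{age},
#'   \code{stroke_type}, \code{days_per_year}.
#' @export
build_generator <- function(stroke_type, age, params) {
  stroke_type <- match.arg(stroke_type, .stroke_types)
  stopifnot(length(age) == 1L, is.finite(age))
  v <- params$values
  v[params$zero_mask] <- 0   # masked rates never leak into the generator
  if (any(v[.rate_names] < 0)) stop("rate parameters must be non-negative")
  lam1 <- unname(exp(v["gamma1"] + v["beta1"] * age))
  lam2 <- unname(exp(v["gamma2"] + v["beta2"] * age))
  tA <- rbind(c(v["mu1"], v["nu1"], v["rho1"]),
              c(v["mu2"], v["nu2"], v["rho2"]),
              c(v["mu3"], v["nu3"], v["rho3"]),
              c(0,        0,        v["rho4"]))
  dimnames(tA) <- list(phase = paste0("phase", 1:4), mode = .modes)
  Lambda <- rowSums(tA) + c(lam1, lam2, 0, 0)
  Tmat <- diag(-Lambda)
  Tmat[1, 2] <- lam1
  Tmat[2, 3] <- lam2
  dimnames(Tmat) <- list(paste0("phase", 1:4), paste0("phase", 1:4))
  alpha <- switch(stroke_type,
    haemorrhagic = c(1, 0, 0, 0),
    cerebral_infarction = c(0, 1, 0, 0),
    tia = {
      p <- mild_tia_probability(age, params)
      c(0, 0, 1 - p, p)
    })
  names(alpha) <- paste0("phase", 1:4)
  structure(list(Tmat = Tmat, tA = tA, alpha = alpha, Lambda = Lambda,
                 age = age, stroke_type = stroke_type,
                 days_per_year = params$days_per_year),
            class = "stroke_generator")
}

#' @export
print.stroke_generator <- function(x, ...) {
  cat("Stroke recovery generator:", x$stroke_type, "at age", x$age, "\n")
  cat("alpha:", paste(signif(x$alpha, 4), collapse = " "), "\n")
  cat("total exit rates (per year):",
      paste(signif(x$Lambda, 5), collapse = " "), "\n")
  invisible(x)
}

## ---- matrix exponential for the upper-bidiagonal T ----
##
## exp(T t) is computed in closed form via divided differences of
## phi(r) = exp(-r t) over the total exit rates: the (i, j >= i) entry of
## exp(T t) is prod(lambda_i..lambda_{j-1}) times the (j - i)-th divided
## difference of phi at (Lambda_i, ..., Lambda_j).  Near-tied rates fall
## back to stable limit forms; the fully general fallback is a
## uniformization series (used only when rates tie to ~1e-9 relative).

.tie_tol <- 1e-7

## First divided difference, negated: (exp(-a t) - exp(-b t)) / (b - a) >= 0.
## Stable via expm1; near ties -> t * exp(-a t).
dd1 <- function(a, b, t) {
  n <- max(length(a), length(b), length(t))
  a <- rep_len(a, n); b <- rep_len(b, n); t <- rep_len(t, n)
  lo <- pmin(a, b); hi <- pmax(a, b)   # symmetric; anchor on the smaller rate
  gap <- hi - lo
  big <- gap > .tie_tol * pmax(abs(lo), abs(hi), 1)
  out <- numeric(n)
  if (any(big))
    out[big] <- exp(-lo[big] * t[big]) *
      (-expm1(-gap[big] * t[big])) / gap[big]
  if (any(!big)) {
    m <- (lo[!big] + hi[!big]) / 2
    out[!big] <- t[!big] * exp(-m * t[!big])
  }
  out
}

## Second divided difference of phi(r) = exp(-r t) at (a, b, c), which is
## symmetric and positive.  Arguments are recycled to the length of t.
dd2 <- function(a, b, c, t) {
  n <- max(length(a), length(b), length(c), length(t))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  t <- rep_len(t, n)
  scale <- pmax(abs(a), abs(b), abs(c), 1)
  ## order each triple so the closest pair is (a, b)
  gab <- abs(a - b); gbc <- abs(b - c); gac <- abs(a - c)
  swap_bc <- gac < gab & gac <= gbc        # closest pair (a, c) -> move c to b
  tmp <- b[swap_bc]; b[swap_bc] <- c[swap_bc]; c[swap_bc] <- tmp
  gab <- abs(a - b); gbc <- abs(b - c)
  swap_ab <- gbc < gab                     # closest pair (b, c) -> move to front
  tmp <- a[swap_ab]; a[swap_ab] <- c[swap_ab]; c[swap_ab] <- tmp
  out <- numeric(n)
  tied_ab <- abs(a - b) <= .tie_tol * scale
  tied_all <- tied_ab & abs(a - c) <= .tie_tol * scale
  reg <- !tied_ab
  if (any(reg))        # (dd1(a,c) - dd1(b,c)) / (b - a), all gaps resolvable
    out[reg] <- (dd1(a[reg], c[reg], t[reg]) - dd1(b[reg], c[reg], t[reg])) /
      (b[reg] - a[reg])
  two <- tied_ab & !tied_all
  if (any(two)) {      # phi[a, a, c] = (t e^{-at} - dd1(a, c, t)) / (c - a)
    m <- (a[two] + b[two]) / 2
    out[two] <- (t[two] * exp(-m * t[two]) - dd1(m, c[two], t[two])) /
      (c[two] - m)
  }
  if (any(tied_all)) {
    m <- (a[tied_all] + b[tied_all] + c[tied_all]) / 3
    out[tied_all] <- t[tied_all]^2 / 2 * exp(-m * t[tied_all])
  }
  out
}

## exp(Tmat * t) for a single time t (years).  Closed form; uniformization
## fallback when the three active exit rates are nearly indistinguishable.
expT <- function(gen, t) {
  L <- gen$Lambda
  lam1 <- gen$Tmat[1, 2]; lam2 <- gen$Tmat[2, 3]
  E <- diag(exp(-L * t))
  E[1, 2] <- lam1 * dd1(L[1], L[2], t)
  E[2, 3] <- lam2 * dd1(L[2], L[3], t)
  E[1, 3] <- lam1 * lam2 * dd2(L[1], L[2], L[3], t)
  dimnames(E) <- dimnames(gen$Tmat)
  E
}

## alpha' exp(T t) for a vector of times t (years); returns length(t) x 4.
occupancy <- function(gen, t) {
  L <- unname(gen$Lambda)
  lam1 <- gen$Tmat[1, 2]; lam2 <- gen$Tmat[2, 3]
  a <- unname(gen$alpha)
  cbind(a[1] * exp(-L[1] * t),
        a[2] * exp(-L[2] * t) + a[1] * lam1 * dd1(L[1], L[2], t),
        a[3] * exp(-L[3] * t) + a[2] * lam2 * dd1(L[2], L[3], t) +
          a[1] * lam1 * lam2 * dd2(L[1], L[2], L[3], t),
        a[4] * exp(-L[4] * t))
}

## (-T)^{-1} applied on the right to a vector v (solve (-T) x = v) by
## back-substitution on the upper-triangular system.
neg_T_solve <- function(gen, v) {
  backsolve(-gen$Tmat, v)
}
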