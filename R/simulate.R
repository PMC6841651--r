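## Seeded forward simulation of the recovery process: patient phase paths
## are drawn by competing exponentials, so estimation and the KPI formulas
## can be exercised without access to hospital data.

#' Cohort simulation configuration
#'
#' Defaults emulate the profile of the motivating hospital cohort: 1,234
#' patients with a type mix proportional to 139 haemorrhagic : 707 cerebral
#' infarction : 410 TIA, ages drawn from a normal distribution (mean 75,
#' sd 10) truncated to [40, 100].
#'
#' @param n number of patients.
#' @param type_mix probabilities over (haemorrhagic, cerebral_infarction, tia).
#' @param age_model list: \code{mean}, \code{sd}, \code{lower}, \code{upper}
#'   of the truncated normal admission-age distribution.
#' @param params a \code{stroke_params} object.
#' @param seed integer RNG seed.
#' @param round_days round stays to whole days (administrative granularity);
#'   default keeps fractional days.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n = 1234,
                          type_mix = c(139, 707, 410) / 1256,
                          age_model = list(mean = 75, sd = 10,
                                           lower = 40, upper = 100),
                          params = fitted_params(),
                          seed = 1L,
                          round_days = FALSE) {
  stopifnot(n > 0, length(type_mix) == 3, abs(sum(type_mix) - 1) < 1e-8)
  structure(list(n = as.integer(n), type_mix = setNames(type_mix, .stroke_types),
                 age_model = age_model, params = params, seed = as.integer(seed),
                 round_days = round_days),
            class = "cohort_config")
}

## Truncated-normal ages by inversion (deterministic given the RNG stream).
.draw_ages <- function(n, am) {
  lo <- pnorm(am$lower, am$mean, am$sd)
  hi <- pnorm(am$upper, am$mean, am$sd)
  stats::qnorm(lo + runif(n) * (hi - lo), am$mean, am$sd)
}

#' Simulate one patient record
#'
#' Draws the phase path of a single patient by competing exponentials: the
#' sojourn in phase i is Exp(total exit rate), the exit cause is categorical
#' over (progression, death, nursing home, usual residence) rates, and the
#' stay is the total time to absorption, in days.
#'
#' @param stroke_type stroke type label.
#' @param age age at admission in years.
#' @param params a \code{stroke_params} object.
#' @return list with \code{stroke_type}, \code{age}, \code{los_days},
#'   \code{mode}.
#' @export
simulate_patient <- function(stroke_type, age, params) {
  df <- simulate_records(rep(stroke_type, 1L), age, params)
  as.list(df[1L, ])
}

## Vectorised path simulation for parallel vectors of types and ages.
simulate_records <- function(stroke_type, age, params) {
  n <- length(stroke_type)
  age <- rep_len(age, n)
  v <- params$values
  v[params$zero_mask] <- 0
  lam1 <- exp(v["gamma1"] + v["beta1"] * age)
  lam2 <- exp(v["gamma2"] + v["beta2"] * age)
  p4 <- mild_tia_probability(age, params)
  phase <- integer(n)
  phase[stroke_type == "haemorrhagic"] <- 1L
  phase[stroke_type == "cerebral_infarction"] <- 2L
  tia <- stroke_type == "tia"
  phase[tia] <- ifelse(runif(sum(tia)) < p4[tia], 4L, 3L)
  los <- numeric(n)
  mode <- integer(n)      # 0 = still in hospital
  active <- rep(TRUE, n)
  while (any(active)) {
    i <- which(active)
    ph <- phase[i]
    prog <- numeric(length(i))
    prog[ph == 1L] <- lam1[i][ph == 1L]
    prog[ph == 2L] <- lam2[i][ph == 2L]
    ex <- cbind(prog,
                c(v["mu1"], v["mu2"], v["mu3"], 0)[ph],
                c(v["nu1"], v["nu2"], v["nu3"], 0)[ph],
                c(v["rho1"], v["rho2"], v["rho3"], v["rho4"])[ph])
    tot <- rowSums(ex)
    los[i] <- los[i] + rexp(length(i), tot)
    u <- runif(length(i)) * tot
    cum <- ex[, 1]
    moved <- u <= cum
    phase[i][moved] <- ph[moved] + 1L
    for (m in 1:3) {
      cum2 <- cum + ex[, m + 1]
      hit <- !moved & u <= cum2
      mode[i][hit] <- m
      moved <- moved | hit
      cum <- cum2
    }
    active[i] <- mode[i] == 0L
  }
  data.frame(stroke_type = stroke_type, age = age,
             los_days = los * params$days_per_year,
             mode = .modes[mode], stringsAsFactors = FALSE)
}

#' Simulate a patient cohort
#'
#' Draws stroke types from the configured mix, ages from the truncated
#' normal age model, and stays/destinations by forward simulation of the
#' recovery process.  Fully reproducible under the configured seed.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame of patient records with attributes \code{seed} and
#'   \code{config} recording provenance.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  types <- sample(.stroke_types, cfg$n, replace = TRUE, prob = cfg$type_mix)
  ages <- .draw_ages(cfg$n, cfg$age_model)
  df <- simulate_records(types, ages, cfg$params)
  if (cfg$round_days) df$los_days <- pmax(1, round(df$los_days))
  attr(df, "seed") <- cfg$seed
  attr(df, "config") <- cfg
  df
}

#' Summarise a cohort by stroke type and discharge mode
#'
#' Discharge counts and average lengths of stay (days) in the standard
#' type-by-mode layout.
#'
#' @param records patient records data.frame.
#' @return list with matrices \code{counts} and \code{mean_los} (modes by
#'   types; empty cells have count 0 and mean \code{NA}).
#' @export
summarize_cohort <- function(records) {
  f_mode <- factor(records$mode, levels = .modes)
  f_type <- factor(records$stroke_type, levels = .stroke_types)
  counts <- table(mode = f_mode, stroke_type = f_type)
  means <- tapply(records$los_days, list(f_mode, f_type), mean)
  dimnames(means) <- dimnames(counts)
  list(counts = unclass(counts), mean_los = means, n = nrow(records))
}
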