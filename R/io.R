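## File-format plumbing: the patient CSV dialect and JSON fit serialization.

#' Read patient records from CSV
#'
#' Expects the header \code{type,age,los_days,mode} with
#' \code{type} in haemorrhagic / cerebral_infarction / tia and \code{mode}
#' in death / nursing_home / usual_residence.  Lines starting with \code{#}
#' (provenance headers) are skipped.  Malformed rows are collected and
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{stroke_type}, \code{age},
#'   \code{los_days}, \code{mode}.
#' @export
read_patient_csv <- function(path) {
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty patient file: ", path)
  need <- c("type", "age", "los_days", "mode")
  if (!all(need %in% names(raw)))
    stop("patient CSV must have header 'type,age,los_days,mode'; found: ",
         paste(names(raw), collapse = ","))
  age <- suppressWarnings(as.numeric(raw$age))
  los <- suppressWarnings(as.numeric(raw$los_days))
  problems <- character()
  flag <- function(bad, msg) {
    msg <- rep_len(msg, length(bad))
    if (any(bad))
      problems <<- c(problems,
                     paste0("row ", which(bad), ": ", msg[bad]))
  }
  flag(!raw$type %in% .stroke_types,
       paste0("unknown stroke type '", raw$type, "'"))
  flag(!raw$mode %in% .modes, paste0("unknown discharge mode '", raw$mode, "'"))
  flag(is.na(age) | age < 0 | age > 120, "age missing or outside [0, 120]")
  flag(is.na(los) | los <= 0, "length of stay must be positive")
  if (length(problems))
    stop("invalid patient records in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  data.frame(stroke_type = raw$type, age = age, los_days = los,
             mode = raw$mode, stringsAsFactors = FALSE)
}

#' Write patient records to CSV
#'
#' Emits the \code{type,age,los_days,mode} dialect, preceded by \code{#}
#' provenance comment lines recording the seed and package version when the
#' records carry them (as those from [simulate_cohort()] do).
#'
#' @param records patient records data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_patient_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# phrex patient records; n=%d; package=%s",
                     nrow(records),
                     as.character(utils::packageVersion("phrex"))), con)
  if (!is.null(attr(records, "seed")))
    writeLines(sprintf("# seed=%d", attr(records, "seed")), con)
  out <- data.frame(type = records$stroke_type, age = records$age,
                    los_days = records$los_days, mode = records$mode)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

.fit_schema <- 1L

#' Serialize a fit result to JSON
#'
#' Lossless, schema-versioned round trip of a \code{stroke_fit}: estimates,
#' free-parameter order, covariance, standard errors, Z statistics,
#' p-values, log-likelihood, stage trace and zero mask.
#'
#' @param fit a \code{stroke_fit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "stroke_fit"))
  obj <- list(schema_version = .fit_schema,
              free_names = fit$free_names,
              values = as.list(fit$params$values),
              zero_mask = fit$params$zero_mask,
              days_per_year = fit$params$days_per_year,
              cov = fit$cov, se = fit$se, z = fit$z, p = fit$p,
              loglik = fit$loglik, n = fit$n, seed = fit$seed,
              cov_flag = fit$cov_flag,
              pruned = fit$pruned,
              stage_trace = fit$stage_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit result from JSON
#'
#' @param path path written by [write_fit_json()].
#' @return a \code{stroke_fit}.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != .fit_schema)
    stop("unsupported fit schema version: ",
         obj$schema_version %||% "(missing)")
  vals <- unlist(obj$values)[.param_names]
  params <- do.call(stroke_params, c(
    as.list(vals),
    list(zero_mask = as.character(obj$zero_mask %||% character()),
         days_per_year = obj$days_per_year)))
  free <- obj$free_names
  cov <- matrix(unlist(obj$cov), length(free), length(free),
                dimnames = list(free, free))
  structure(
    list(params = params, free_names = free,
         estimate = setNames(params$values[free], free),
         loglik = obj$loglik,
         stage_trace = obj$stage_trace,
         n = obj$n, seed = obj$seed, schema_version = obj$schema_version,
         cov = cov, cov_flag = obj$cov_flag,
         se = setNames(obj$se, free), z = setNames(obj$z, free),
         p = setNames(obj$p, free),
         pruned = obj$pruned),
    class = "stroke_fit")
}
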