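#' Fit an exponential storage-viability decay
#'
#' Models the relative growth rate of cultures revived after cold storage as
#' \deqn{RGR(t) = r_0 e^{-k t}} where `t` is the storage duration in days.
#' The viability limit is the storage time at which the fitted curve crosses
#' `viability_threshold` (default 1: final area equals initial area, i.e. no
#' net growth): `ln(r0 / threshold) / k` when `r0` exceeds the threshold,
#' otherwise 0; unbounded (`Inf`) when the data show no decay (`k` clipped
#' at 0, with a warning).
#'
#' @param data optional tibble; then `storage_days` and `rgr` are column
#'   names (defaults `storage_days`, `rgr`).
#' @param storage_days numeric storage durations (>= 3 distinct values).
#' @param rgr non-negative relative growth rates, same length.
#' @param viability_threshold RGR defining loss of viability (default 1.0).
#' @param offset if `TRUE`, fit `r0 * exp(-k t) + c` instead (an asymptotic
#'   floor; default `FALSE`, i.e. RGR tends to 0 for long storage).
#'
#' @return An object of class `decay_fit`: `estimates` (`term`, `estimate`,
#'   `std.error`), `viability_limit_days`, `viability_threshold`, `rss`,
#'   `data`, `model` (`NULL` for the degenerate clipped case).
#' @export
fit_storage_decay <- function(data = NULL, storage_days = "storage_days",
                              rgr = "rgr", viability_threshold = 1.0,
                              offset = FALSE) {
  if (!is.null(data)) {
    d <- as_tibble(data)
    storage_days <- d[[if (is.character(storage_days)) storage_days else "storage_days"]]
    rgr <- d[[if (is.character(rgr)) rgr else "rgr"]]
  }
  t <- as.numeric(storage_days); y <- as.numeric(rgr)
  if (length(t) != length(y)) {
    stop_frondkit("storage_days and rgr differ in length", "frondkit_input_error")
  }
  if (length(unique(t)) < 3) {
    stop_frondkit("need >= 3 distinct storage durations", "frondkit_input_error")
  }
  if (any(y < 0)) stop_frondkit("rgr must be >= 0", "frondkit_input_error")
  if (!is_scalar_pos(viability_threshold)) {
    stop_frondkit("`viability_threshold` must be positive", "frondkit_input_error")
  }
  df <- tibble(storage_days = t, rgr = y)

  # log-linear initialisation on the strictly positive points
  pos <- y > 0
  ll <- lm(log(y[pos]) ~ t[pos])
  slope <- coef(ll)[[2]]

  if (slope >= 0) {
    warn("RGR does not decrease with storage time; decay rate clipped at 0")
    r0 <- exp(mean(log(y[pos])))
    est <- tibble(term = c("r0", "k"), estimate = c(r0, 0),
                  std.error = c(NA_real_, NA_real_))
    lim <- if (r0 > viability_threshold) Inf else 0
    return(structure(
      list(estimates = est, viability_limit_days = lim,
           viability_threshold = viability_threshold,
           rss = sum((y - r0)^2), data = df, offset = offset, model = NULL),
      class = "decay_fit"
    ))
  }

  start <- list(r0 = exp(coef(ll)[[1]]), k = -slope)
  form <- rgr ~ r0 * exp(-k * storage_days)
  lower <- c(r0 = 0, k = 0)
  if (offset) {
    start$c0 <- max(min(y), 1e-8)
    form <- rgr ~ r0 * exp(-k * storage_days) + c0
    lower <- c(r0 = 0, k = 0, c0 = 0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop_frondkit(paste0("decay fit did not converge: ", conditionMessage(e)),
                    "frondkit_fit_error")
    }
  )
  sm <- summary(fit)$coefficients
  estimates <- tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                      std.error = sm[, "Std. Error"])
  co <- coef(fit)
  lim <- if (co[["r0"]] > viability_threshold && co[["k"]] > 0) {
    log(co[["r0"]] / viability_threshold) / co[["k"]]
  } else if (co[["r0"]] <= viability_threshold) 0 else Inf
  structure(
    list(estimates = estimates, viability_limit_days = lim,
         viability_threshold = viability_threshold,
         rss = sum(resid(fit)^2), data = df, offset = offset, model = fit),
    class = "decay_fit"
  )
}

#' @export
coef.decay_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$term)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  co <- coef(object)
  t <- if (is.null(newdata)) object$data$storage_days else {
    if (is.data.frame(newdata)) newdata$storage_days else as.numeric(newdata)
  }
  out <- co[["r0"]] * exp(-co[["k"]] * t)
  if (object$offset) out <- out + co[["c0"]]
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  co <- coef(x)
  cat(sprintf(paste0("<decay_fit> r0 %.3g, k %.4g /day; viability limit ",
                     "%.1f days at RGR threshold %g\n"),
              co[["r0"]], co[["k"]], x$viability_limit_days,
              x$viability_threshold))
  invisible(x)
}
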