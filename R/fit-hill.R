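#' Fit a Hill dose-response curve
#'
#' Least-squares fit of the four-parameter Hill (log-logistic) model
#' \deqn{R(c) = bottom + \frac{top - bottom}{1 + (c / ec50)^{n}}}
#' to dose/response pairs, e.g. NaCl concentration in mM against day-10
#' normalized growth. The zero dose is handled by evaluating the limit
#' (`R(0) = top` for a decreasing curve with `n > 0`). Starting values:
#' `top` = mean response at dose 0, `bottom` = minimum response,
#' `ec50` = median positive dose, `n` = 1.
#'
#' @param data optional tibble; if given, `doses` and `responses` are column
#'   names (defaults `dose` and `response`), so the function pipes.
#' @param doses numeric doses (must include 0 and >= 4 distinct values) or a
#'   column name when `data` is supplied.
#' @param responses positive numeric responses, same length.
#' @param direction `"decreasing"` (inhibition, the supported case).
#'
#' @return An object of class `hill_fit` with elements `estimates` (tibble
#'   `term`, `estimate`, `std.error`), `rss`, `data`, and the underlying
#'   `nls` model. [tidy()], [glance()], `predict()` and [autoplot()] methods
#'   are available.
#' @export
fit_hill <- function(data = NULL, doses = "dose", responses = "response",
                     direction = "decreasing") {
  if (!is.null(data)) {
    d <- as_tibble(data)
    doses <- d[[if (is.character(doses)) doses else "dose"]]
    responses <- d[[if (is.character(responses)) responses else "response"]]
  }
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses)) {
    stop_frondkit("doses and responses differ in length", "frondkit_input_error")
  }
  if (length(unique(doses)) < 4 || !any(doses == 0)) {
    stop_frondkit("need >= 4 distinct doses including a zero dose",
                  "frondkit_input_error")
  }
  if (any(responses <= 0)) {
    stop_frondkit("responses must be positive", "frondkit_input_error")
  }
  if (sd(responses) == 0) {
    stop_frondkit("all responses identical: dose-response fit is degenerate",
                  "frondkit_degenerate_fit")
  }
  df <- tibble(dose = doses, response = responses)
  start <- list(top = mean(responses[doses == 0]), bottom = min(responses),
                ec50 = median(doses[doses > 0]), hill_n = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + (dose / ec50)^hill_n),
      data = df, start = start,
      lower = c(top = -Inf, bottom = -Inf, ec50 = 1e-9, hill_n = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop_frondkit(paste0("Hill fit did not converge: ", conditionMessage(e),
                           " (n = ", nrow(df), " points, start ec50 = ",
                           signif(start$ec50, 3), ")"),
                    "frondkit_fit_error")
    }
  )
  est <- summary(fit)$coefficients
  estimates <- tibble(term = rownames(est), estimate = est[, "Estimate"],
                      std.error = est[, "Std. Error"])
  co <- coef(fit)
  if (direction == "decreasing" && co[["top"]] < co[["bottom"]]) {
    warn("fitted top < bottom: data do not look like an inhibition curve")
  }
  structure(
    list(estimates = estimates, rss = sum(resid(fit)^2), data = df,
         direction = direction, model = fit),
    class = "hill_fit"
  )
}

#' @export
coef.hill_fit <- function(object, ...) coef(object$model)

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  co <- coef(object)
  dose <- if (is.null(newdata)) object$data$dose else {
    if (is.data.frame(newdata)) newdata$dose else as.numeric(newdata)
  }
  co[["bottom"]] + (co[["top"]] - co[["bottom"]]) /
    (1 + (dose / co[["ec50"]])^co[["hill_n"]])
}

#' @export
print.hill_fit <- function(x, ...) {
  co <- coef(x)
  cat(sprintf(paste0("<hill_fit> top %.3g, bottom %.3g, ec50 %.4g, ",
                     "hill_n %.3g (rss %.3g, n %d)\n"),
              co[["top"]], co[["bottom"]], co[["ec50"]], co[["hill_n"]],
              x$rss, nrow(x$data)))
  invisible(x)
}
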