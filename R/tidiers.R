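#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per model term (estimate and standard error);
#' `glance()` returns a one-row model summary.
#'
#' @param x a `hill_fit`, `decay_fit` or `tukey_grouping`.
#' @param ... unused.
#' @return A tibble.
#' @name frondkit-tidiers
NULL

#' @rdname frondkit-tidiers
#' @export
tidy.hill_fit <- function(x, ...) x$estimates

#' @rdname frondkit-tidiers
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data),
         ec50 = coef(x)[["ec50"]], hill_n = coef(x)[["hill_n"]])
}

#' @rdname frondkit-tidiers
#' @export
tidy.decay_fit <- function(x, ...) x$estimates

#' @rdname frondkit-tidiers
#' @export
glance.decay_fit <- function(x, ...) {
  co <- coef(x)
  tibble(rss = x$rss, n = nrow(x$data), r0 = co[["r0"]], k = co[["k"]],
         viability_limit_days = x$viability_limit_days,
         viability_threshold = x$viability_threshold)
}

#' @rdname frondkit-tidiers
#' @export
tidy.tukey_grouping <- function(x, ...) as_tibble(x)

#' @rdname frondkit-tidiers
#' @export
glance.tukey_grouping <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"), anova_p = attr(x, "anova_p"),
         n_groups = nrow(x),
         n_letters = length(unique(unlist(strsplit(x$letters, "")))))
}
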