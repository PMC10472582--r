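#' One-way ANOVA with Tukey HSD significance letters
#'
#' Fits a one-way ANOVA across treatment groups, runs Tukey's honest
#' significant difference test over all pairs, and summarises the result as
#' a compact letter display: two treatments share a letter iff their
#' Tukey-adjusted comparison is non-significant at `alpha`. Letters are
#' built by the insert-and-absorb sweep, so they form a minimal cover.
#'
#' @param data a tibble with columns `treatment` and `value`, or a named
#'   list of numeric vectors (one per treatment).
#' @param value,treatment column names when `data` is a data frame.
#' @param alpha significance level (default 0.05).
#'
#' @return A tibble of class `tukey_grouping`: `treatment`, `n`, `mean`,
#'   `letters`; attributes `alpha`, `anova_p` and `tukey` (the adjusted
#'   p-value table).
#' @export
anova_tukey <- function(data, value = "value", treatment = "treatment",
                        alpha = 0.05) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data))) {
      stop_frondkit("group list must be named", "frondkit_input_error")
    }
    data <- imap(data, ~ tibble(treatment = .y, value = as.numeric(.x))) |>
      list_rbind()
  }
  d <- tibble(treatment = as.character(data[[treatment]]),
              value = as.numeric(data[[value]]))
  counts <- count(d, .data$treatment)
  if (nrow(counts) < 2) {
    stop_frondkit("need >= 2 treatment groups", "frondkit_input_error")
  }
  if (any(counts$n < 2)) {
    stop_frondkit("every group needs >= 2 values", "frondkit_input_error")
  }
  lv <- unique(d$treatment)             # keep insertion order
  d$treatment <- factor(d$treatment, levels = lv)
  fit <- aov(value ~ treatment, data = d)
  p_anova <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$treatment
  pairs <- tibble(
    a = sub("-.*$", "", rownames(tk)),
    b = sub("^[^-]*-", "", rownames(tk)),
    p_adj = tk[, "p adj"]
  )
  # significant means p decisively below alpha; NaN (zero variance) is not
  sig <- pairs[!is.na(pairs$p_adj) & pairs$p_adj < alpha, , drop = FALSE]
  sets <- cld_insert_absorb(lv, sig)
  letter_of <- map_chr(lv, function(g) {
    paste0(letters[which(map_lgl(sets, ~ g %in% .x))], collapse = "")
  })
  out <- d |>
    group_by(.data$treatment) |>
    summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop") |>
    mutate(treatment = as.character(.data$treatment)) |>
    left_join(tibble(treatment = lv, letters = letter_of), by = "treatment")
  out <- out[match(lv, out$treatment), ]
  attr(out, "alpha") <- alpha
  attr(out, "anova_p") <- p_anova
  attr(out, "tukey") <- pairs
  class(out) <- c("tukey_grouping", class(out))
  out
}

# insert-and-absorb compact letter display: start from one set holding all
# treatments; for each significant pair split every set containing both;
# absorb sets that became subsets of others; order sets by first member
cld_insert_absorb <- function(groups, sig_pairs) {
  sets <- list(groups)
  if (nrow(sig_pairs)) {
    for (i in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$a[i]; b <- sig_pairs$b[i]
      hit <- which(map_lgl(sets, ~ a %in% .x && b %in% .x))
      for (j in hit) {
        s <- sets[[j]]
        sets[[j]] <- setdiff(s, a)
        sets[[length(sets) + 1]] <- setdiff(s, b)
      }
      # absorb subsets
      drop <- rep(FALSE, length(sets))
      for (p in seq_along(sets)) for (q in seq_along(sets)) {
        if (p != q && !drop[p] && !drop[q] &&
            all(sets[[p]] %in% sets[[q]]) &&
            (length(sets[[p]]) < length(sets[[q]]) || p > q)) {
          drop[p] <- TRUE
        }
      }
      sets <- sets[!drop]
    }
  }
  sets <- sets[order(map_int(sets, ~ min(match(.x, groups))))]
  sets
}

#' @export
print.tukey_grouping <- function(x, ...) {
  cat(sprintf("<tukey_grouping> alpha = %g, ANOVA p = %.3g\n",
              attr(x, "alpha"), attr(x, "anova_p")))
  print(as_tibble(x))
  invisible(x)
}
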