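meas_tbl <- function(item = 1L, days, areas, d0 = as.Date("2024-06-01")) {
  tibble::tibble(item_id = item, date = d0 + days, area_mm2 = areas)
}

test_that("growth curves re-base time, average same-day duplicates, reject bad input", {
  cv <- build_growth_curve(meas_tbl(days = seq(0, 10, 2), areas = 100 * 2^(0:5)))
  expect_equal(cv$t, seq(0, 10, 2))
  expect_equal(cv$area_mm2[1], 100)

  dup <- build_growth_curve(meas_tbl(days = c(0, 0, 2), areas = c(100, 110, 150)))
  expect_equal(dup$area_mm2, c(105, 150))

  expect_error(build_growth_curve(meas_tbl(days = 0, areas = 100)),
               class = "frondkit_input_error")
  mixed <- dplyr::bind_rows(meas_tbl(1L, 0:1, c(1, 2)), meas_tbl(2L, 0:1, c(1, 2)))
  expect_error(build_growth_curve(mixed), class = "frondkit_input_error")
})

test_that("normalized growth is final over initial area", {
  expect_equal(normalized_growth(build_growth_curve(
    meas_tbl(days = c(0, 10), areas = c(100, 400)))), 4.0)
  expect_equal(normalized_growth(build_growth_curve(
    meas_tbl(days = c(0, 5, 10), areas = c(80, 80, 80)))), 1.0)
  # noiseless exponential, rate 0.2/day over 10 days -> e^2
  days <- seq(0, 10, 2)
  cv <- build_growth_curve(meas_tbl(days = days, areas = 100 * exp(0.2 * days)))
  expect_equal(normalized_growth(cv), exp(2), tolerance = 1e-10)
})

test_that("RGR uses the time point nearest the window, later on ties", {
  expect_equal(compute_rgr(build_growth_curve(
    meas_tbl(days = c(0, 10), areas = c(50, 300)))), 6.0)
  expect_equal(compute_rgr(build_growth_curve(
    meas_tbl(days = c(0, 5, 10), areas = c(70, 70, 70)))), 1.0)
  # schedule slipped to day 11: nearest point wins
  cv <- build_growth_curve(meas_tbl(days = c(0, 2, 4, 6, 8, 11),
                                    areas = c(100, 1, 1, 1, 1, 700)))
  expect_equal(compute_rgr(cv, window_days = 10), 7.0)
  # exact tie between 8 and 12 resolves to the later point
  tie <- build_growth_curve(meas_tbl(days = c(0, 8, 12), areas = c(100, 200, 900)))
  expect_equal(compute_rgr(tie, window_days = 10), 9.0)
  expect_error(compute_rgr(build_growth_curve(
    meas_tbl(days = c(0, 4), areas = c(1, 2))), 10), class = "frondkit_window_error")
})

test_that("normalized growth and RGR are scale invariant", {
  days <- c(0, 2, 5, 8, 10)
  set.seed(7)
  areas <- 100 * exp(0.15 * days) * exp(rnorm(5, 0, 0.05))
  for (k in c(0.1, 3, 1000)) {
    a <- build_growth_curve(meas_tbl(days = days, areas = areas))
    b <- build_growth_curve(meas_tbl(days = days, areas = k * areas))
    expect_equal(normalized_growth(b), normalized_growth(a))
    expect_equal(compute_rgr(b), compute_rgr(a))
  }
})

test_that("replicate series average across replicates with n-1 sd", {
  m <- tidyr::expand_grid(treatment = "0 mM", replicate = 1:3, day = c(0, 2)) |>
    dplyr::mutate(item_id = as.integer(interaction(treatment, replicate)),
                  area_mm2 = c(100, 200, 110, 220, 120, 240))
  rs <- replicate_series(m)
  expect_equal(rs$mean_area, c(110, 220))
  expect_equal(rs$sd_area, c(sd(c(100, 110, 120)), sd(c(200, 220, 240))))
  # a lone replicate has undefined spread
  solo <- replicate_series(dplyr::mutate(meas_tbl(days = c(0, 2), areas = c(1, 2)),
                                         treatment = "x"))
  expect_true(all(is.na(solo$sd_area)))
})

test_that("Hill fit recovers noiseless parameters and flags degenerate input", {
  doses <- c(0, 50, 100, 150, 300)
  truth <- c(bottom = 1, top = 7, ec50 = 100, hill_n = 2)
  resp <- truth[["bottom"]] + (truth[["top"]] - truth[["bottom"]]) /
    (1 + (doses / truth[["ec50"]])^truth[["hill_n"]])
  fit <- fit_hill(tibble::tibble(dose = doses, response = resp))
  est <- coef(fit)
  for (p in names(truth)) {
    expect_lt(abs(est[[p]] - truth[[p]]) / truth[[p]], 0.01)
  }
  expect_lt(fit$rss, 1e-12)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 4)

  expect_error(fit_hill(tibble::tibble(dose = doses, response = rep(3, 5))),
               class = "frondkit_degenerate_fit")
  expect_error(fit_hill(tibble::tibble(dose = c(0, 1, 2), response = c(3, 2, 1))),
               class = "frondkit_input_error")
})

test_that("median ec50 over 100 noisy refits stays within 15% of truth", {
  doses <- rep(c(0, 50, 100, 150, 300), each = 3)
  resp0 <- 1 + 6 / (1 + (doses / 100)^2)
  set.seed(2024)
  ec50s <- purrr::map_dbl(1:100, function(i) {
    y <- resp0 * exp(rnorm(length(doses), 0, 0.05))
    coef(fit_hill(tibble::tibble(dose = doses, response = y)))[["ec50"]]
  })
  expect_lt(abs(median(ec50s) - 100) / 100, 0.15)
})

test_that("storage decay recovers k and the viability limit on the reference storage grid", {
  t <- c(0, 6, 28, 232, 310)
  fit <- fit_storage_decay(tibble::tibble(storage_days = t, rgr = 6 * exp(-0.06 * t)))
  expect_lt(abs(coef(fit)[["k"]] - 0.06) / 0.06, 0.01)
  expect_lt(abs(fit$viability_limit_days - log(6) / 0.06) / (log(6) / 0.06), 0.01)
  expect_equal(glance(fit)$viability_limit_days, fit$viability_limit_days)

  # everything below threshold from the start: limit 0
  dead <- fit_storage_decay(tibble::tibble(storage_days = c(0, 10, 20),
                                           rgr = c(0.9, 0.5, 0.3)))
  expect_equal(dead$viability_limit_days, 0)

  # increasing RGR: warning, k clipped, unbounded limit
  expect_warning(
    up <- fit_storage_decay(tibble::tibble(storage_days = c(0, 10, 20),
                                           rgr = c(2, 3, 4))),
    "clipped")
  expect_equal(coef(up)[["k"]], 0)
  expect_equal(up$viability_limit_days, Inf)

  expect_error(fit_storage_decay(tibble::tibble(storage_days = c(0, 1), rgr = c(2, 1))),
               class = "frondkit_input_error")
})

test_that("decay slope matches an independent log-linear oracle", {
  t <- c(0, 3, 7, 14, 21, 28)
  y <- 5.5 * exp(-0.08 * t)
  fit <- fit_storage_decay(tibble::tibble(storage_days = t, rgr = y))
  oracle_k <- -coef(lm(log(y) ~ t))[[2]]
  expect_lt(abs(coef(fit)[["k"]] - oracle_k) / oracle_k, 0.01)
})

test_that("Tukey letters separate well-spaced groups and merge identical ones", {
  set.seed(11)
  d <- tibble::tibble(treatment = rep(c("g1", "g2", "g3"), each = 5),
                      value = c(rnorm(5, 1, 0.01), rnorm(5, 10, 0.01),
                                rnorm(5, 100, 0.01)))
  tk <- anova_tukey(d)
  expect_equal(tk$letters, c("a", "b", "c"))

  same <- tibble::tibble(treatment = rep(c("x", "y", "z"), each = 3),
                         value = rep(c(1, 2, 3), 3))
  expect_equal(unique(anova_tukey(same)$letters), "a")

  expect_error(anova_tukey(tibble::tibble(treatment = c("a", "a", "b"),
                                          value = c(1, 2, 3))),
               class = "frondkit_input_error")
})

test_that("three-regime doses reproduce the a / b / ccc grouping pattern", {
  set.seed(21)
  means <- c("0" = 3.0, "50" = 2.0, "100" = 1.0, "150" = 1.0, "300" = 1.0)
  d <- purrr::imap(means, ~ tibble::tibble(treatment = .y,
                                           value = rnorm(5, .x, 0.02))) |>
    purrr::list_rbind()
  tk <- anova_tukey(d)
  expect_equal(tk$letters, c("a", "b", "c", "c", "c"))
})

test_that("Tukey grouping is relabeling-symmetric and a duplicate group shares letters", {
  set.seed(31)
  base <- list(a = rnorm(5, 1, 0.05), b = rnorm(5, 5, 0.05), c = rnorm(5, 5.2, 2))
  tk1 <- anova_tukey(base)
  perm <- base[c(3, 1, 2)]
  names(perm) <- c("zz", "pp", "qq")
  tk2 <- anova_tukey(perm)
  # the partition structure (who shares with whom) is label independent
  shares1 <- outer(tk1$letters, tk1$letters,
                   Vectorize(function(x, y) any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])))
  ord <- match(c("c", "a", "b"), tk1$treatment)
  shares2 <- outer(tk2$letters, tk2$letters,
                   Vectorize(function(x, y) any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])))
  expect_equal(unname(shares2), unname(shares1[ord, ord]))

  dup <- c(base, list(d = base$b))
  tkd <- anova_tukey(dup)
  lb <- tkd$letters[tkd$treatment == "b"]
  ld <- tkd$letters[tkd$treatment == "d"]
  expect_true(any(strsplit(lb, "")[[1]] %in% strsplit(ld, "")[[1]]))
})

test_that("letter display agrees with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(41)
  d <- tibble::tibble(treatment = rep(c("t1", "t2", "t3", "t4"), each = 6),
                      value = c(rnorm(6, 0), rnorm(6, 0.2), rnorm(6, 3), rnorm(6, 3.1)))
  tk <- anova_tukey(d)
  d$treatment <- factor(d$treatment)
  fit <- stats::aov(value ~ treatment, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(treatment = "Tukey"))
  ref <- multcomp::cld(gl, level = 0.05)$mcletters$Letters
  # same partition: two groups share a letter in ours iff they do in multcomp
  for (i in 1:3) for (j in (i + 1):4) {
    ours <- any(strsplit(tk$letters[i], "")[[1]] %in% strsplit(tk$letters[j], "")[[1]])
    theirs <- any(strsplit(ref[[i]], "")[[1]] %in% strsplit(ref[[j]], "")[[1]])
    expect_equal(ours, theirs)
  }
})
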