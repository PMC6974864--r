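test_that("the hierarchical model family enumerates correctly", {
  specs <- crc_model_specs()
  expect_length(specs, 8)
  expect_identical(specs[[1]]$interactions, character(0))
  expect_identical(specs[[8]]$interactions, c("AB", "AC", "BC"))
  expect_identical(vapply(specs, `[[`, integer(1), "n_params"),
                   setNames(c(4L, 5L, 5L, 5L, 6L, 6L, 6L, 7L),
                            names(specs)))
})

test_that("the saturated model reproduces a symmetric table exactly", {
  tab <- as_incomplete_table(setNames(rep(12, 7),
                                      recap3:::.CELL_NAMES))
  fit <- fit_crc(tab, c("AB", "AC", "BC"))
  expect_equal(unname(fit$fitted_means), rep(12, 7), tolerance = 1e-8)
  expect_lt(fit$g2, 1e-8)
  expect_equal(fit$x000_hat, 12, tolerance = 1e-6)
})

test_that("closed forms evaluate their textbook expressions", {
  t1 <- incomplete_table(6, 4, 1, 8, 1, 1, 1)
  expect_equal(closed_form_x000(t1, c("AC", "BC")), 6 * 4 / 8) # = 3
  t2 <- incomplete_table(2, 3, 4, 1, 2, 3, 6)
  expect_equal(closed_form_x000(t2, c("AB", "AC", "BC")),
               2 * 3 * 4 * 6 / (1 * 2 * 3)) # = 24
  expect_true(is.na(closed_form_x000(t2, character(0))))
  t3 <- incomplete_table(2, 3, 4, 0, 2, 3, 6)
  expect_error(closed_form_x000(t3, c("AC", "BC")), "zero denominator")
})

test_that("IRLS and closed forms agree on random strictly positive tables", {
  dependent <- crc_model_specs()[-1]
  for (s in 1:60) {
    tab <- random_table(s)
    for (m in dependent) {
      cf <- closed_form_x000(tab, m)
      fit <- fit_crc(tab, m)
      expect_lt(abs(fit$x000_hat - cf) / cf, 1e-6)
    }
  }
})

test_that("deviance follows its closed form", {
  expect_equal(g2_statistic(c(3, 5), c(3, 5)), 0)
  expect_equal(g2_statistic(c(2, 0), c(1, 1)), 4 * log(2)) # ~2.7726
  expect_error(g2_statistic(c(1, 1), c(1, 0)), "positive")
})

test_that("deviance never increases when an interaction is added", {
  chains <- list(
    c("A/B/C", "AB", "AB/AC", "AB/AC/BC"),
    c("A/B/C", "BC", "AC/BC", "AB/AC/BC")
  )
  for (s in c(3, 11, 27)) {
    tab <- random_table(s)
    fits <- fit_all_models(tab)
    for (chain in chains) {
      g2s <- vapply(fits[chain], `[[`, numeric(1), "g2")
      expect_true(all(diff(g2s) <= 1e-8))
    }
    # score identity: fitted means resum to the observed total
    for (f in fits) {
      expect_equal(sum(f$fitted_means), n_obs(tab), tolerance = 1e-6)
    }
  }
})

test_that("information criteria use the deviance-based formulas", {
  tab <- random_table(5)
  fit <- fit_crc(tab, "AC")
  ic <- information_criteria(fit)
  expect_equal(unname(ic["aic"]), fit$g2 + 2 * 5)
  expect_equal(unname(ic["bic"]), fit$g2 + 5 * log(n_obs(tab)))
  expect_equal(fit$aic, unname(ic["aic"]))
})

test_that("the log-normal interval is asymmetric and degenerates correctly", {
  tab <- random_table(19)
  fit <- fit_crc(tab, c("AB", "AC"))
  expect_lte(fit$ci_n[["low"]], fit$n_hat)
  expect_gte(fit$ci_n[["high"]], fit$n_hat)
  # log-normal: more room above the point estimate than below
  expect_gt(fit$ci_n[["high"]] - fit$n_hat, fit$n_hat - fit$ci_n[["low"]])

  degenerate <- fit
  degenerate$se_log_x000 <- 0
  expect_equal(unname(ci_for_n(degenerate)),
               rep(fit$n_obs + fit$x000_hat, 2))
})

test_that("model selection minimises AIC with BIC tie-break", {
  tab <- random_table(23)
  fits <- fit_all_models(tab)
  sel <- select_model(fits)
  expect_equal(sel$aic, min(vapply(fits, `[[`, numeric(1), "aic")))
  expect_identical(select_model(fits[2]), fits[[2]])

  f1 <- fits[[1]]; f2 <- fits[[2]]
  f1$aic <- f2$aic <- 10
  f1$bic <- 12; f2$bic <- 10
  expect_identical(select_model(list(f1, f2))$bic, 10)
})

test_that("inestimable parameters are reported by cell", {
  tab <- incomplete_table(5, 4, 3, 0, 2, 1, 0)
  expect_error(fit_crc(tab, "AB"), "inestimable")
})

test_that("completeness and rates implement their ratio definitions", {
  expect_equal(round(completeness(27048, 53630), 1), 50.4)
  expect_equal(completeness(100, 100), 100)
  expect_equal(round(rate_per_1000(53630, 70565789), 2), 0.76)
  expect_equal(rate_per_1000(0, 1000), 0)
  expect_equal(rate_per_1000(500, 2e6), rate_per_1000(500, 1e6) / 2)
  expect_error(rate_per_1000(1, 0), "positive")
})

test_that("collapsing to two lists recovers Lincoln-Petersen", {
  # only lists A and B capture anyone; the AC/BC closed form on the
  # three-list table must equal the two-list Lincoln-Petersen estimate
  n10 <- 120; n01 <- 80; n11 <- 40
  tab <- incomplete_table(n10, n01, 0, n11, 0, 0, 0)
  x00 <- closed_form_x000(tab, c("AC", "BC"))
  lp_total <- (n10 + n11) * (n01 + n11) / n11
  expect_equal(n_obs(tab) + x00, lp_total)
})

test_that("generating under the fitted model recovers N", {
  reps <- 100
  N <- 50000
  rel <- vapply(seq_len(reps), function(r) {
    truth <- build_truth(population_size = N, seed = 1000 + r)
    h <- sample_histories(truth)
    counts <- table(factor(h$pattern, levels = recap3:::.PATTERNS_OBS))
    tab <- as_incomplete_table(setNames(as.numeric(counts),
                                        recap3:::.CELL_NAMES))
    fit <- fit_crc(tab, c("AB", "AC", "BC"))
    abs(fit$n_hat - N) / N
  }, numeric(1))
  expect_lte(median(rel), 0.02)
})

test_that("stratified fitting isolates strata and stays consistent", {
  tab <- random_table(31)
  single <- stratified_fit(list(s1 = tab), model_policy = "global",
                           global_model = crc_model(c("AB", "AC", "BC")))
  direct <- fit_crc(tab, c("AB", "AC", "BC"))
  expect_equal(single$s1$n_hat, direct$n_hat)

  # uniform split of one population: stratum estimates re-add
  truth <- build_truth(population_size = 100000, seed = 55)
  h <- sample_histories(truth)
  strata <- recap3:::with_seed(56, sample(1:4, nrow(h), replace = TRUE))
  tables <- lapply(split(h$pattern, strata), function(p) {
    counts <- table(factor(p, levels = recap3:::.PATTERNS_OBS))
    as_incomplete_table(setNames(as.numeric(counts), recap3:::.CELL_NAMES))
  })
  fits <- stratified_fit(tables, model_policy = "global",
                         global_model = crc_model(c("AB", "AC", "BC")))
  pooled <- fit_crc(as_incomplete_table(
    setNames(Reduce(`+`, lapply(tables, as.numeric)),
             recap3:::.CELL_NAMES)), c("AB", "AC", "BC"))
  total <- sum(vapply(fits, `[[`, numeric(1), "n_hat"))
  expect_lt(abs(total - pooled$n_hat) / pooled$n_hat, 0.05)

  # empty stratum skipped with a warning
  zero <- as_incomplete_table(setNames(rep(0, 7), recap3:::.CELL_NAMES))
  expect_warning(
    out <- stratified_fit(list(ok = tab, none = zero),
                          model_policy = "global",
                          global_model = crc_model("AC")),
    "empty")
  expect_named(out, "ok")
})

test_that("stratified report combines completeness and rates", {
  tab <- random_table(41)
  fits <- stratified_fit(list(s1 = tab), model_policy = "global",
                         global_model = crc_model(c("AB", "AC", "BC")))
  rep1 <- stratified_report(fits, population = c(s1 = 1e6))
  expect_equal(rep1$completeness_pct,
               100 * rep1$reported / rep1$n_hat)
  expect_equal(rep1$rate_per_1000, 1000 * rep1$n_hat / 1e6)
  expect_warning(rep2 <- stratified_report(fits), NA)
  expect_true(is.na(rep2$rate_per_1000))
})
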