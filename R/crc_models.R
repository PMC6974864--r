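# Hierarchical log-linear capture-recapture models for three lists.
#
# Each model is a Poisson log-linear model for the SEVEN observed cells
# of the incomplete 2^3 table, with intercept, the three main effects,
# and a subset of the three pairwise interactions {AB, AC, BC}. The
# three-way term is never included (it is inestimable from 7 cells).
# Under treatment (0/1) coding every non-intercept covariate vanishes at
# pattern 000, so the unobserved cell is projected as exp(intercept).

#' Enumerate the eight hierarchical capture-recapture models
#'
#' All subsets of the pairwise interactions \{AB, AC, BC\}; the intercept
#' and the three main effects are always present. Canonical order: by
#' number of interactions, then lexicographically. The empty set is the
#' mutual-independence model; the full set is the saturated model (7
#' parameters for 7 cells).
#'
#' @return A list of 8 `crc_model` objects, named by their labels
#'   (e.g. `"A/B/C"` for independence, `"AB/AC/BC"` for saturated).
#' @export
crc_model_specs <- function() {
  pairs <- c("AB", "AC", "BC")
  subsets <- unlist(lapply(0:3, function(k) {
    utils::combn(pairs, k, simplify = FALSE)
  }), recursive = FALSE)
  specs <- lapply(subsets, crc_model)
  names(specs) <- vapply(specs, function(m) m$label, character(1))
  specs
}

#' Define one hierarchical capture-recapture model
#'
#' @param interactions character subset of `c("AB", "AC", "BC")`.
#' @return A `crc_model`: list with `interactions`, `label` and
#'   `n_params` (4 main-structure parameters plus one per interaction).
#' @export
crc_model <- function(interactions = character(0)) {
  interactions <- sort(unique(as.character(interactions)))
  if (!all(interactions %in% c("AB", "AC", "BC"))) {
    stop("interactions must be a subset of AB, AC, BC")
  }
  label <- if (length(interactions) == 0) "A/B/C" else
    paste(interactions, collapse = "/")
  structure(list(interactions = interactions,
                 label = label,
                 n_params = 4L + length(interactions)),
            class = "crc_model")
}

#' @export
print.crc_model <- function(x, ...) {
  cat("Capture-recapture log-linear model:", x$label,
      sprintf("(%d parameters)\n", x$n_params))
  invisible(x)
}

# 7 x p design matrix for the observed cells, in .PATTERNS_OBS order.
.design_matrix <- function(model) {
  bits <- .pattern_bits(.PATTERNS_OBS)
  X <- cbind(intercept = 1, bits)
  for (term in model$interactions) {
    s1 <- substr(term, 1, 1)
    s2 <- substr(term, 2, 2)
    X <- cbind(X, bits[, s1] * bits[, s2])
    colnames(X)[ncol(X)] <- term
  }
  X
}

#' Likelihood-ratio goodness-of-fit statistic
#'
#' \eqn{G^2 = 2 \sum_i y_i \log(y_i / \hat\mu_i)} over the seven observed
#' cells, with the convention that a term is 0 when \eqn{y_i = 0}.
#'
#' @param observed observed cell counts (non-negative).
#' @param fitted fitted cell means (strictly positive).
#' @return Non-negative deviance.
#' @export
g2_statistic <- function(observed, fitted) {
  if (any(fitted <= 0)) stop("fitted means must be strictly positive")
  pos <- observed > 0
  2 * sum(observed[pos] * log(observed[pos] / fitted[pos]))
}

#' Fit one log-linear model to an incomplete capture-history table
#'
#' Poisson maximum likelihood on the seven observed cells (IRLS with
#' step-halving; convergence when the relative deviance change falls
#' below `epsilon`). The unobserved-cell estimate is
#' \eqn{\hat x_{000} = e^{\hat\beta_0}} and the population estimate is
#' \eqn{\hat N = \hat x_{000} + n_{obs}}. The confidence interval for
#' \eqn{\hat N} is log-normal on \eqn{\hat x_{000}} via the delta
#' method (see [ci_for_n()]).
#'
#' @param table an [incomplete_table()].
#' @param model a [crc_model()] (or character vector of interactions).
#' @param confidence confidence level for the interval on N.
#' @param epsilon relative-deviance convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return A `crc_fit`: list with elements `model`, `coefficients`,
#'   `fitted_means`, `x000_hat`, `n_hat`, `g2`, `pearson_x2`,
#'   `n_params`, `aic`, `bic`, `ci_n`, `se_log_x000`, `n_obs`,
#'   `converged`, `iterations`.
#' @export
fit_crc <- function(table, model = crc_model(), confidence = 0.95,
                    epsilon = 1e-10, maxit = 100L) {
  table <- as_incomplete_table(table)
  if (!inherits(model, "crc_model")) model <- crc_model(model)
  y <- as.numeric(table)
  nobs <- sum(y)
  if (nobs <= 0) stop("observed total must be positive")

  X <- .design_matrix(model)
  # a parameter is inestimable when every cell contributing to its
  # sufficient statistic is zero
  for (j in 2:ncol(X)) {
    if (sum(y[X[, j] == 1]) == 0) {
      stop("parameter ", colnames(X)[j], " is inestimable: cells ",
           paste(.CELL_NAMES[X[, j] == 1], collapse = ", "),
           " are all zero")
    }
  }

  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::poisson(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  mu <- fit$fitted.values
  beta <- fit$coefficients

  g2 <- g2_statistic(y, mu)
  pearson <- sum((y - mu)^2 / mu)
  x000 <- exp(beta[["intercept"]])

  info <- crossprod(X, mu * X)
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  se_log_x000 <- if (is.null(vcov)) NA_real_ else sqrt(vcov[1, 1])

  out <- structure(list(
    model = model,
    coefficients = beta,
    fitted_means = setNames(mu, .CELL_NAMES),
    x000_hat = unname(x000),
    n_hat = unname(x000 + nobs),
    g2 = g2,
    pearson_x2 = pearson,
    n_params = model$n_params,
    aic = g2 + 2 * model$n_params,
    bic = g2 + model$n_params * log(nobs),
    se_log_x000 = se_log_x000,
    n_obs = nobs,
    vcov = vcov,
    converged = isTRUE(fit$converged),
    iterations = fit$iter
  ), class = "crc_fit")
  out$ci_n <- ci_for_n(out, confidence)
  if (!out$converged) {
    warning("model ", model$label, " did not converge in ", maxit,
            " iterations")
  }
  out
}

#' @export
print.crc_fit <- function(x, ...) {
  cat("Log-linear CRC fit:", x$model$label, "\n")
  cat(sprintf("  x000 = %.2f  N = %.2f  (95%% CI %.2f-%.2f)\n",
              x$x000_hat, x$n_hat, x$ci_n[1], x$ci_n[2]))
  cat(sprintf("  G2 = %.4f  params = %d  AIC = %.2f  BIC = %.2f\n",
              x$g2, x$n_params, x$aic, x$bic))
  invisible(x)
}

#' Deviance-based information criteria of a fit
#'
#' `aic = G2 + 2p` and `bic = G2 + p log(n_obs)`, where `p` is the
#' number of estimated parameters. These differ from the full
#' log-likelihood versions by a model-independent constant, so model
#' ranking is unchanged.
#'
#' @param fit a `crc_fit`.
#' @return Named numeric `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  c(aic = fit$g2 + 2 * fit$n_params,
    bic = fit$g2 + fit$n_params * log(fit$n_obs))
}

#' Log-normal confidence interval for the population size
#'
#' The delta-method standard error of \eqn{\log \hat x_{000}} is the
#' intercept entry of the inverse Fisher information of the Poisson fit.
#' With \eqn{C = \exp(z \cdot se)} the interval is
#' \eqn{(n_{obs} + \hat x_{000}/C,\; n_{obs} + \hat x_{000} \cdot C)} —
#' asymmetric around \eqn{\hat N}, wider above, as a log-scale interval
#' on a positive estimate should be.
#'
#' @param fit a `crc_fit`.
#' @param confidence confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @export
ci_for_n <- function(fit, confidence = 0.95) {
  if (is.na(fit$se_log_x000)) {
    warning("singular information matrix; interval unavailable")
    return(c(low = NA_real_, high = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  C <- exp(z * fit$se_log_x000)
  c(low = fit$n_obs + fit$x000_hat / C,
    high = fit$n_obs + fit$x000_hat * C)
}

#' Closed-form unobserved-cell estimators
#'
#' For every model except mutual independence, the Poisson MLE of the
#' unobserved cell has a closed form in the seven observed cells
#' (writing a = n100, b = n010, c = n001, d = n110, e = n101, f = n011,
#' g = n111):
#' \itemize{
#'   \item \{AC\}: \eqn{b(a+c+e)/(d+f+g)}
#'   \item \{BC\}: \eqn{a(b+c+f)/(d+e+g)}
#'   \item \{AB\}: \eqn{c(a+b+d)/(e+f+g)}
#'   \item \{AC,BC\}: \eqn{ab/d}
#'   \item \{AB,AC\}: \eqn{bc/f}
#'   \item \{AB,BC\}: \eqn{ac/e}
#'   \item \{AB,AC,BC\}: \eqn{abcg/(def)}
#' }
#' The independence model has no closed form (iterative only) and
#' returns `NA`. These expressions are the independent cross-check for
#' the iterative fit (the two agree to numerical precision).
#'
#' @param table an [incomplete_table()].
#' @param model a [crc_model()] or character vector of interactions.
#' @return The closed-form estimate of the unobserved cell, or `NA` for
#'   the independence model.
#' @export
closed_form_x000 <- function(table, model) {
  table <- as_incomplete_table(table)
  if (!inherits(model, "crc_model")) model <- crc_model(model)
  a <- table[["n100"]]; b <- table[["n010"]]; c <- table[["n001"]]
  d <- table[["n110"]]; e <- table[["n101"]]; f <- table[["n011"]]
  g <- table[["n111"]]

  key <- paste(model$interactions, collapse = "/")
  if (key == "") {
    return(NA_real_) # independence: iterative fit only
  }
  expr <- switch(
    key,
    "AC" = list(num = b * (a + c + e), den = d + f + g),
    "BC" = list(num = a * (b + c + f), den = d + e + g),
    "AB" = list(num = c * (a + b + d), den = e + f + g),
    "AC/BC" = list(num = a * b, den = d),
    "AB/AC" = list(num = b * c, den = f),
    "AB/BC" = list(num = a * c, den = e),
    "AB/AC/BC" = list(num = a * b * c * g, den = d * e * f),
    stop("unknown model: ", key)
  )
  if (expr$den <= 0) {
    stop("closed form for model ", model$label,
         " has a zero denominator: estimate is infinite")
  }
  expr$num / expr$den
}

#' Fit all eight models to one table
#'
#' @param table an [incomplete_table()].
#' @param ... passed to [fit_crc()].
#' @return Named list of 8 `crc_fit` objects in canonical model order.
#' @export
fit_all_models <- function(table, ...) {
  lapply(crc_model_specs(), function(m) fit_crc(table, m, ...))
}

#' Select the best-fitting model
#'
#' Minimum AIC; ties broken by minimum BIC, then by fewer parameters.
#' Unconverged fits are excluded.
#'
#' @param fits list of `crc_fit` objects (e.g. from [fit_all_models()]).
#' @return The selected `crc_fit`.
#' @export
select_model <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("no converged fits to select from")
  ord <- order(vapply(fits, `[[`, numeric(1), "aic"),
               vapply(fits, `[[`, numeric(1), "bic"),
               vapply(fits, `[[`, numeric(1), "n_params"))
  fits[[ord[1]]]
}

#' Completeness of registration
#'
#' Percentage of the estimated population present in the combined
#' observed lists: `100 * n_obs_reported / n_hat`.
#'
#' @param n_obs_reported observed (reported) count.
#' @param n_hat estimated total population.
#' @return Percentage.
#' @export
completeness <- function(n_obs_reported, n_hat) {
  if (any(n_hat <= 0)) stop("n_hat must be positive")
  100 * n_obs_reported / n_hat
}

#' Practitioners per 1,000 population
#'
#' @param n_hat estimated number of practitioners.
#' @param population denominator population.
#' @return `1000 * n_hat / population`.
#' @export
rate_per_1000 <- function(n_hat, population) {
  if (any(population <= 0)) stop("population must be positive")
  1000 * n_hat / population
}

#' Fit capture-recapture models per stratum
#'
#' @param tables named list of [incomplete_table()] objects, one per
#'   stratum (e.g. province).
#' @param model_policy `"global"` fits `global_model` in every stratum;
#'   `"per-stratum"` fits all eight models and selects per stratum.
#' @param global_model the [crc_model()] used under the `"global"`
#'   policy (default: selected on the pooled table of all strata).
#' @param ... passed to [fit_crc()].
#' @return Named list of `crc_fit` objects; strata whose fit fails (or
#'   whose table is empty) are skipped with a warning.
#' @export
stratified_fit <- function(tables, model_policy = c("global", "per-stratum"),
                           global_model = NULL, ...) {
  model_policy <- match.arg(model_policy)
  tables <- lapply(tables, as_incomplete_table)
  if (model_policy == "global" && is.null(global_model)) {
    pooled <- as_incomplete_table(Reduce(`+`, lapply(tables, as.numeric)) |>
                                    setNames(.CELL_NAMES))
    global_model <- select_model(fit_all_models(pooled, ...))$model
  }
  out <- list()
  for (s in names(tables)) {
    tab <- tables[[s]]
    if (sum(tab) == 0) {
      warning("stratum ", s, " has an empty table; skipped")
      next
    }
    fit <- tryCatch({
      if (model_policy == "global") {
        fit_crc(tab, global_model, ...)
      } else {
        select_model(fit_all_models(tab, ...))
      }
    }, error = function(e) {
      warning("stratum ", s, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) out[[s]] <- fit
  }
  out
}
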