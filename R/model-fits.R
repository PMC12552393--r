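#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Welch two-sample t-test
#'
#' Two-tailed t-test with unequal variances and Welch-Satterthwaite
#' (fractional) degrees of freedom, returned as a one-row tibble.
#'
#' @param x,y Numeric vectors, each with at least two values and positive
#'   variance.
#' @return Tibble: `mean_x`, `mean_y`, `statistic`, `df`, `p_value`,
#'   `conf_low`, `conf_high` (95% CI of the mean difference).
#' @examples
#' welch_t_test(rnorm(10), rnorm(12, 1))
#' @export
welch_t_test <- function(x, y) {
  for (s in list(x = x, y = y)) {
    if (length(s) < 2 || !is.finite(stats::sd(s)) || stats::sd(s) == 0) {
      abort("each sample needs >= 2 values with positive variance")
    }
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  tibble(
    mean_x = unname(ht$estimate[1]),
    mean_y = unname(ht$estimate[2]),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    conf_low = ht$conf.int[1],
    conf_high = ht$conf.int[2]
  )
}

#' Fit an ordinary least-squares model for the AICc selection layer
#'
#' Fits `formula` by OLS with treatment contrasts (first factor level as
#' reference: AGE1, female) and computes the quantities the selection layer
#' needs: Gaussian log-likelihood with the maximum-likelihood variance
#' (RSS/n), AICc counting the residual variance as a parameter, and adjusted
#' R-squared.  Rows with missing values in any model variable are dropped
#' listwise with a message.
#'
#' @param data A data frame; character columns used by the model are converted
#'   to factors (with conventional level orders for `sex`, `age_group`,
#'   `tissue`).
#' @param formula Model formula.
#' @return Object of class `epirad_fit`; see [tidy()], [glance()],
#'   [estimated_means()], [term_f_tests()], [qq_normality_check()].
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + rnorm(10))
#' glance(fit_linear_model(d, y ~ x))
#' @export
fit_linear_model <- function(data, formula) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("variables not in `data`: ", paste(missing_vars, collapse = ", ")))
  }
  data <- canonical_factors(data[vars])
  keep <- stats::complete.cases(data)
  if (any(!keep)) {
    inform(paste0("dropping ", sum(!keep), " row(s) with missing values"))
    data <- data[keep, , drop = FALSE]
  }
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(paste0("rank-deficient design; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }
  ll <- stats::logLik(fit)
  n <- length(stats::residuals(fit))
  k <- attr(ll, "df")  # regression coefficients + residual variance
  structure(
    list(
      lm = fit,
      formula = formula,
      data = data,
      n = n,
      k = k,
      log_lik = as.numeric(ll),
      r_squared = summary(fit)$r.squared,
      adj_r_squared = summary(fit)$adj.r.squared,
      sigma = summary(fit)$sigma
    ),
    class = "epirad_fit"
  )
}

canonical_factors <- function(data) {
  known <- list(sex = SEX_LEVELS, age_group = AGE_LEVELS,
                tissue = TISSUE_LEVELS)
  for (nm in names(data)) {
    if (is.character(data[[nm]])) {
      lv <- known[[nm]]
      data[[nm]] <- if (!is.null(lv) && all(stats::na.omit(data[[nm]]) %in% lv)) {
        factor(data[[nm]], levels = lv)
      } else {
        factor(data[[nm]])
      }
    }
  }
  data
}

#' @export
print.epirad_fit <- function(x, ...) {
  cat("<epirad_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f, adj R2 = %.3f\n",
              x$n, x$k, x$log_lik, aicc(x), x$adj_r_squared))
  invisible(x)
}

#' @export
tidy.epirad_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  s <- summary(x$lm)$coefficients
  out <- tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
  if (conf.int) {
    ci <- stats::confint(x$lm, level = conf.level)
    out$conf_low <- ci[, 1]
    out$conf_high <- ci[, 2]
  }
  out
}

#' @export
glance.epirad_fit <- function(x, ...) {
  tibble(
    n = x$n, k = x$k,
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
    sigma = x$sigma, log_lik = x$log_lik, aicc = aicc(x),
    df_residual = stats::df.residual(x$lm)
  )
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 log L + 2k + 2k(k+1)/(n - k - 1)`, with the log-likelihood
#' evaluated at the maximum-likelihood variance and `k` counting every
#' estimated parameter including the residual variance.  Undefined (an error)
#' when `n <= k + 1`.
#'
#' @param fit An [fit_linear_model()] object or a plain `lm`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  if (inherits(fit, "epirad_fit")) {
    n <- fit$n; k <- fit$k; ll <- fit$log_lik
  } else if (inherits(fit, "lm")) {
    llo <- stats::logLik(fit)
    n <- length(stats::residuals(fit)); k <- attr(llo, "df")
    ll <- as.numeric(llo)
  } else {
    abort("`fit` must be an epirad_fit or lm")
  }
  if (n - k - 1 <= 0) {
    abort(paste0("AICc undefined: n - k - 1 = ", n - k - 1, " <= 0"))
  }
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' Fits every candidate formula to the same rows (complete cases over the
#' union of all model variables, so likelihoods are comparable) and ranks them
#' by AICc; ties are broken in favour of fewer parameters.
#'
#' @param data Data frame shared by all candidates.
#' @param models Named list of formulas.
#' @return Tibble ordered by AICc: `model`, `formula`, `k`, `log_lik`,
#'   `aicc`, `delta_aicc`, `weight` (Akaike weights); the fitted
#'   `epirad_fit` objects are kept in attribute `"fits"`.
#' @examples
#' d <- data.frame(x = rep(1:8, 4), y = rep(1:8, 4) * 3 + rnorm(32))
#' select_model(d, list(empty = y ~ 1, slope = y ~ x))
#' @export
select_model <- function(data, models) {
  if (!length(models)) abort("no candidate models supplied")
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model", seq_along(models))
  }
  all_vars <- unique(unlist(lapply(models, all.vars)))
  missing_vars <- setdiff(all_vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("variables not in `data`: ",
                 paste(missing_vars, collapse = ", ")))
  }
  shared <- as.data.frame(data)[stats::complete.cases(
    as.data.frame(data)[all_vars]), , drop = FALSE]
  fits <- purrr::map(models, function(f) fit_linear_model(shared, f))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    abort("candidates were fitted on differing row subsets; AICc values are not comparable")
  }
  out <- tibble(
    model = names(models),
    formula = vapply(models, function(f) paste(deparse(f), collapse = " "),
                     character(1)),
    k = unname(vapply(fits, function(f) f$k, numeric(1))),
    log_lik = unname(vapply(fits, function(f) f$log_lik, numeric(1))),
    aicc = unname(vapply(fits, aicc, numeric(1)))
  )
  ord <- order(out$aicc, out$k)
  out <- out[ord, ]
  out$delta_aicc <- out$aicc - out$aicc[1]
  w <- exp(-out$delta_aicc / 2)
  out$weight <- w / sum(w)
  attr(out, "fits") <- fits[ord]
  out
}

#' @rdname select_model
#' @param ranking Output of [select_model()].
#' @export
best_model <- function(ranking) attr(ranking, "fits")[[1]]

#' Model-estimated means with 95% confidence intervals
#'
#' Evaluates the fitted model over a grid of factor combinations (all factor
#' predictors' crossed levels by default); numeric covariates not supplied in
#' the grid are held at their sample mean.  The CI uses the t quantile at the
#' model's residual degrees of freedom.
#'
#' @param fit An [fit_linear_model()] object.
#' @param grid Optional data frame of predictor combinations.
#' @param level Confidence level (default 0.95).
#' @return Tibble: the grid plus `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
estimated_means <- function(fit, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "epirad_fit"))
  data <- fit$data
  preds <- all.vars(fit$formula)[-1]
  fac <- preds[vapply(data[preds], is.factor, logical(1))]
  num <- setdiff(preds, fac)
  if (is.null(grid)) {
    grid <- if (length(fac)) {
      expand.grid(lapply(data[fac], levels), stringsAsFactors = FALSE)
    } else {
      data.frame(row.names = 1)
    }
  }
  grid <- as.data.frame(grid)
  for (v in intersect(fac, names(grid))) {
    bad <- setdiff(unique(as.character(grid[[v]])), levels(data[[v]]))
    if (length(bad)) {
      abort(paste0("grid level(s) outside the design for `", v, "`: ",
                   paste(bad, collapse = ", ")))
    }
    grid[[v]] <- factor(grid[[v]], levels = levels(data[[v]]))
  }
  for (v in setdiff(fac, names(grid))) {
    abort(paste0("grid must supply factor `", v, "`"))
  }
  for (v in setdiff(num, names(grid))) grid[[v]] <- mean(data[[v]])
  pr <- stats::predict(fit$lm, newdata = grid, se.fit = TRUE)
  tcrit <- stats::qt(1 - (1 - level) / 2, stats::df.residual(fit$lm))
  dplyr::bind_cols(
    as_tibble(grid),
    tibble(estimate = as.numeric(pr$fit),
           std_error = as.numeric(pr$se.fit),
           conf_low = as.numeric(pr$fit) - tcrit * as.numeric(pr$se.fit),
           conf_high = as.numeric(pr$fit) + tcrit * as.numeric(pr$se.fit))
  )
}

#' Marginal (Type II) F tests per model term
#'
#' Each term is tested by comparing the residual sum of squares with and
#' without it, respecting marginality: a main effect is tested in a model
#' from which its interactions have been removed (a message notes when this
#' happens).  The error mean square and denominator degrees of freedom come
#' from the full model, so an AGE + SEX model on 32 individuals yields the
#' conventional F(2, 28) for AGE.
#'
#' @param fit An [fit_linear_model()] object.
#' @return Tibble: `term`, `df1`, `df2`, `statistic`, `p_value`.
#' @export
term_f_tests <- function(fit) {
  stopifnot(inherits(fit, "epirad_fit"))
  full <- fit$lm
  labels <- attr(stats::terms(full), "term.labels")
  if (!length(labels)) abort("intercept-only model has no terms to test")
  rss_full <- sum(stats::residuals(full)^2)
  df2 <- stats::df.residual(full)
  ms_error <- rss_full / df2
  data <- fit$data

  refit <- function(keep) {
    f <- if (length(keep)) {
      stats::reformulate(keep, response = all.vars(fit$formula)[1])
    } else {
      stats::as.formula(paste(all.vars(fit$formula)[1], "~ 1"))
    }
    stats::lm(f, data = data)
  }

  rows <- lapply(labels, function(tm) {
    tm_vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    contains <- vapply(labels, function(other) {
      other != tm && all(tm_vars %in% strsplit(other, ":", fixed = TRUE)[[1]])
    }, logical(1))
    base <- labels[!contains]
    if (any(contains)) {
      inform(paste0("testing `", tm, "` with its interaction(s) ",
                    paste(labels[contains], collapse = ", "),
                    " excluded from both models (marginality)"))
    }
    with_tm <- refit(base)
    without_tm <- refit(setdiff(base, tm))
    df1 <- stats::df.residual(without_tm) - stats::df.residual(with_tm)
    ss <- sum(stats::residuals(without_tm)^2) - sum(stats::residuals(with_tm)^2)
    f_stat <- (ss / df1) / ms_error
    tibble(term = tm, df1 = df1, df2 = df2, statistic = f_stat,
           p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Q-Q normality check of model residuals
#'
#' Pairs the ordered standardized residuals with Normal quantiles at plotting
#' positions `(i - 0.5)/n`, as a table ready for plotting.
#'
#' @param fit An [fit_linear_model()] object.
#' @return Tibble: `theoretical`, `sample` (ordered standardized residuals).
#' @export
qq_normality_check <- function(fit) {
  stopifnot(inherits(fit, "epirad_fit"))
  r <- stats::residuals(fit$lm)
  n <- length(r)
  std <- if (n > 1 && stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else r * 0
  tibble(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = unname(sort(std))
  )
}

#' Candidate model sets for age/sex and fin-gonad analyses
#'
#' `candidate_age_models()` builds the conventional ladder for a response
#' measured in one tissue: intercept-only, additive AGE + SEX, the AGE x SEX
#' interaction, and (optionally) the interaction model plus body size.
#' `candidate_fin_gonad_models()` builds the ladder for predicting the gonad
#' value from the fin value: intercept-only, fin + SEX, and fin x SEX.
#'
#' @param response Response variable name.
#' @param body_size Include the body-size candidate (telomere analyses).
#' @return Named list of formulas for [select_model()].
#' @export
candidate_age_models <- function(response, body_size = FALSE) {
  f <- function(rhs) stats::as.formula(paste(response, "~", rhs))
  out <- list(
    empty = f("1"),
    additive = f("age_group + sex"),
    interaction = f("age_group * sex")
  )
  if (body_size) out$interaction_body <- f("age_group * sex + body_size_mm")
  out
}

#' @rdname candidate_age_models
#' @param fin Fin predictor variable name.
#' @export
candidate_fin_gonad_models <- function(response, fin) {
  f <- function(rhs) stats::as.formula(paste(response, "~", rhs))
  list(
    empty = f("1"),
    additive = f(paste(fin, "+ sex")),
    interaction = f(paste(fin, "* sex"))
  )
}
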