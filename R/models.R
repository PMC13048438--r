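#' Fit a (generalized) linear mixed model
#'
#' Fits the requested fixed-effect structure with independent random
#' intercepts for each grouping column, by REML/Laplace maximum likelihood
#' via lme4. Rows with missing values in any model column are dropped (with
#' a message). If the mixed fit fails or does not converge, the function
#' falls back to a fixed-effects-only fit whose covariance is
#' cluster-robust by the first grouping column, and flags the fallback.
#'
#' @param data A data frame of observations (e.g. an event table).
#' @param formula Fixed-effects formula, e.g.
#'   `switch ~ delta_social * difficulty + on_correct`.
#' @param random Character vector of grouping columns for random intercepts
#'   (may be empty for an ordinary GLM/LM fit).
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @param nAGQ Passed to [lme4::glmer()] (0 = fast penalized least squares,
#'   1 = Laplace approximation; binomial only).
#' @return An object of class `arena_fit`: a list with `model` (the fitted
#'   engine object), `engine` (`"lmer"`, `"glmer"`, `"lm"`, `"glm"`),
#'   `coefficients`, `vcov`, `re_var` (named random-intercept variances),
#'   `logLik`, `converged`, `fallback`, `formula`, `family`, `random`,
#'   `n_dropped`, `data` (the complete-case model frame).
#' @export
fit_model <- function(data, formula, random = character(),
                      family = c("gaussian", "binomial"), nAGQ = 1) {
  family <- match.arg(family)
  vars <- unique(c(all.vars(formula), random))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cc <- stats::complete.cases(data[vars])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(n_dropped, " incomplete rows dropped before fitting")
  }
  df <- as.data.frame(data[cc, vars])
  resp <- all.vars(formula)[1]
  if (family == "binomial" && !all(df[[resp]] %in% c(0, 1))) {
    stop("binomial response must be coded 0/1", call. = FALSE)
  }
  fit <- NULL
  fallback <- FALSE
  converged <- FALSE
  engine <- NA_character_
  if (length(random) > 0) {
    re_terms <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    full_formula <- stats::as.formula(
      paste(deparse(formula), "+", re_terms)
    )
    fit <- tryCatch({
      m <- if (family == "gaussian") {
        lme4::lmer(full_formula, data = df)
      } else {
        lme4::glmer(full_formula, data = df, family = stats::binomial(),
                    nAGQ = nAGQ)
      }
      msgs <- m@optinfo$conv$lme4$messages
      bad <- !is.null(msgs) && any(grepl("failed to converge", msgs))
      if (bad) stop("lme4 reported non-convergence")
      m
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      engine <- if (family == "gaussian") "lmer" else "glmer"
      converged <- TRUE
    }
  }
  if (is.null(fit)) {
    fallback <- length(random) > 0
    fit <- stats::glm(formula, data = df,
                      family = if (family == "gaussian") {
                        stats::gaussian()
                      } else {
                        stats::binomial()
                      })
    engine <- if (family == "gaussian") "glm" else "glm"
    converged <- fit$converged
  }
  if (engine %in% c("lmer", "glmer")) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- stats::setNames(vc$vcov[vc$grp %in% random], vc$grp[vc$grp %in% random])
  } else {
    beta <- stats::coef(fit)
    V <- if (fallback) {
      # cluster-robust by the first grouping column; degenerate clusterings
      # (a single cluster) fall back to the model-based covariance
      tryCatch(as.matrix(sandwich::vcovCL(fit, cluster = df[[random[1]]])),
               error = function(e) as.matrix(stats::vcov(fit)))
    } else {
      as.matrix(stats::vcov(fit))
    }
    re_var <- stats::setNames(numeric(0), character(0))
  }
  dimnames(V) <- list(names(beta), names(beta))
  structure(
    list(model = fit, engine = engine, coefficients = beta, vcov = V,
         re_var = re_var, logLik = as.numeric(stats::logLik(fit)),
         converged = converged || fallback, fallback = fallback,
         formula = formula, family = family, random = random,
         n_dropped = n_dropped, data = df),
    class = "arena_fit"
  )
}

#' @export
print.arena_fit <- function(x, ...) {
  cat("<arena_fit> ", x$engine, " (", x$family, "), ",
      nrow(x$data), " obs", if (x$fallback) ", FALLBACK (cluster-robust)",
      "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of an `arena_fit`
#'
#' @param x An `arena_fit`.
#' @param ... Unused.
#' @return A tibble with `term, estimate, std_error, statistic, p_value`
#'   (Wald z/t against a normal reference).
#' @method tidy arena_fit
#' @export
tidy.arena_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' One-line model summary
#'
#' @param x An `arena_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `nobs, logLik, converged, fallback, engine`.
#' @method glance arena_fit
#' @export
glance.arena_fit <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$data),
    logLik = x$logLik,
    converged = x$converged,
    fallback = x$fallback,
    engine = x$engine
  )
}

#' Type II Wald chi-square ANOVA
#'
#' Per-term Wald chi-square tests of the fixed effects under the Type II
#' convention (each term tested after all others at the same or lower
#' interaction order, ignoring interactions that contain it).
#'
#' @param fit An `arena_fit`.
#' @return A tibble of class `arena_anova`: `term, chisq, df, p_value`.
#' @export
anova_type2 <- function(fit) {
  stopifnot(inherits(fit, "arena_fit"))
  a <- if (fit$engine %in% c("lmer", "glmer")) {
    car::Anova(fit$model, type = 2, test.statistic = "Chisq")
  } else if (fit$fallback) {
    car::Anova(fit$model, type = 2, test.statistic = "Wald", vcov. = fit$vcov)
  } else {
    car::Anova(fit$model, type = 2, test.statistic = "Wald")
  }
  tab <- as.data.frame(a)
  keep <- !rownames(tab) %in% c("(Intercept)", "Residuals")
  chisq_vals <- tab[[grep("Chisq", names(tab), value = TRUE)[1]]][keep]
  df_vals <- tab[[grep("^Df$", names(tab), value = TRUE)[1]]][keep]
  p_vals <- tab[[grep("^Pr", names(tab), value = TRUE)[1]]][keep]
  out <- tibble::tibble(
    term = rownames(tab)[keep],
    chisq = chisq_vals,
    df = df_vals,
    p_value = p_vals
  )
  class(out) <- c("arena_anova", class(out))
  out
}

#' Pairwise estimated-marginal-mean contrasts with FDR adjustment
#'
#' EMMs are predictions at each level of `factor` averaged with equal
#' weights over the levels of the other factors (covariates at their
#' means); all pairwise differences are tested two-sided and the p-values
#' adjusted by Benjamini-Hochberg within the contrast family.
#'
#' @param fit An `arena_fit`.
#' @param factor Name of the factor whose levels are compared.
#' @return A tibble of class `arena_contrasts`: `contrast, estimate,
#'   std_error, statistic, p_value, p_adjusted`.
#' @export
emm_pairwise <- function(fit, factor) {
  stopifnot(inherits(fit, "arena_fit"))
  if (!factor %in% names(fit$data)) {
    stop("factor not in the model data: ", factor, call. = FALSE)
  }
  if (length(unique(fit$data[[factor]])) < 2) {
    stop("factor has fewer than 2 levels: ", factor, call. = FALSE)
  }
  args <- list(object = fit$model, specs = factor, data = fit$data)
  if (fit$fallback) args$vcov. <- fit$vcov
  em <- do.call(emmeans::emmeans, args)
  pr_raw <- summary(emmeans::contrast(em, method = "pairwise"),
                    adjust = "none", infer = c(FALSE, TRUE))
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(pr_raw))[1]
  out <- tibble::tibble(
    contrast = as.character(pr_raw$contrast),
    estimate = pr_raw$estimate,
    std_error = pr_raw$SE,
    statistic = pr_raw[[stat_col]],
    p_value = pr_raw$p.value,
    p_adjusted = bh_adjust(pr_raw$p.value)
  )
  class(out) <- c("arena_contrasts", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return The adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Predicted switch-probability curve over DeltaSocial
#'
#' Fixed-effects predicted probabilities of a binomial event-level model
#' over a grid of DeltaSocial values (random effects at zero), with the
#' other covariates held at their means and factors at a chosen level.
#'
#' @param fit A binomial `arena_fit` whose formula involves `delta_social`.
#' @param grid Numeric vector of DeltaSocial values.
#' @param at Named list of values for other predictors (defaults: numeric
#'   covariates at their mean, factors at their first level).
#' @return A tibble `delta_social, prob`.
#' @export
predicted_switch_curve <- function(fit, grid, at = list()) {
  stopifnot(inherits(fit, "arena_fit"))
  if (length(grid) == 0) stop("empty DeltaSocial grid", call. = FALSE)
  if (fit$family != "binomial") {
    stop("switch curves require a binomial fit", call. = FALSE)
  }
  preds <- setdiff(all.vars(fit$formula)[-1], "delta_social")
  newdata <- tibble::tibble(delta_social = grid)
  for (v in preds) {
    if (!is.null(at[[v]])) {
      newdata[[v]] <- at[[v]]
    } else if (is.numeric(fit$data[[v]])) {
      newdata[[v]] <- mean(fit$data[[v]])
    } else {
      newdata[[v]] <- sort(unique(as.character(fit$data[[v]])))[1]
    }
  }
  eta <- if (fit$engine == "glmer") {
    stats::predict(fit$model, newdata = as.data.frame(newdata), re.form = NA,
                   type = "link")
  } else {
    stats::predict(fit$model, newdata = as.data.frame(newdata), type = "link")
  }
  tibble::tibble(delta_social = grid, prob = stats::plogis(unname(eta)))
}
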