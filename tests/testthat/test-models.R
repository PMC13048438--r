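test_that("an exact linear relationship is recovered exactly", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20) + 1)
  f <- fit_model(d, y ~ x, family = "gaussian")
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-8)
  expect_lt(stats::sigma(f$model), 1e-6)
  expect_false(f$fallback)
})

test_that("a balanced binomial intercept sits at logit of the rate", {
  d <- tibble::tibble(y = rep(c(0, 1), each = 50))
  f <- fit_model(d, y ~ 1, family = "binomial")
  expect_equal(unname(f$coefficients[1]), 0, tolerance = 1e-6)
  expect_error(fit_model(tibble::tibble(y = c(0, 1, 2)), y ~ 1,
                         family = "binomial"),
               "coded 0/1")
})

test_that("incomplete rows are dropped with a count", {
  d <- tibble::tibble(x = c(1:9, NA), y = 2 * c(1:9, 1) + 1)
  expect_message(f <- fit_model(d, y ~ x, family = "gaussian"),
                 "1 incomplete rows")
  expect_equal(f$n_dropped, 1)
  expect_equal(nrow(f$data), 9)
})

test_that("mixed fits carry random-intercept variances; tidy/glance work", {
  d <- withr::with_seed(1, {
    g <- rep(sprintf("g%02d", 1:20), each = 10)
    u <- rep(stats::rnorm(20, 0, 2), each = 10)
    x <- stats::rnorm(200)
    tibble::tibble(g = g, x = x, y = 1 + 0.5 * x + u + stats::rnorm(200))
  })
  f <- fit_model(d, y ~ x, random = "g", family = "gaussian")
  expect_equal(f$engine, "lmer")
  expect_false(f$fallback)
  expect_gt(f$re_var[["g"]], 1)
  expect_equal(unname(f$coefficients["x"]), 0.5, tolerance = 0.2)
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate, unname(f$coefficients))
  gl <- glance(f)
  expect_equal(gl$nobs, 200)
  expect_true(gl$converged)
})

test_that("an impossible grouping falls back to a cluster-robust fit", {
  d <- tibble::tibble(x = stats::rnorm(30), g = "only_one_level",
                      y = stats::rnorm(30))
  f <- fit_model(d, y ~ x, random = "g", family = "gaussian")
  expect_true(f$fallback)
  expect_true(f$converged)
  expect_equal(f$engine, "glm")
  expect_equal(dim(f$vcov), c(2, 2))
})

test_that("a 1-df Wald chi-square equals the squared z statistic", {
  d <- withr::with_seed(3, tibble::tibble(
    x = stats::rnorm(100), y = 1 + 0.3 * stats::rnorm(100) + 0.4 * x
  ))
  f <- fit_model(d, y ~ x, family = "gaussian")
  a <- anova_type2(f)
  z <- tidy(f)$statistic[2]
  expect_equal(a$chisq[a$term == "x"], z^2, tolerance = 1e-6)
  expect_equal(a$df[a$term == "x"], 1)
})

test_that("Type II equals Type III on a balanced one-factor design", {
  d <- withr::with_seed(4, tibble::tibble(
    f = factor(rep(c("a", "b", "c"), each = 30)),
    y = rep(c(0, 0.5, 1), each = 30) + stats::rnorm(90)
  ))
  fit <- fit_model(d, y ~ f, family = "gaussian")
  t2 <- anova_type2(fit)
  t3 <- car::Anova(fit$model, type = 3, test.statistic = "Wald")
  expect_equal(t2$chisq[t2$term == "f"],
               as.data.frame(t3)["f", grep("Chisq", colnames(t3), value = TRUE)[1]],
               tolerance = 1e-8)
})

test_that("EMM contrasts reduce to cell-mean differences when balanced", {
  d <- tibble::tibble(
    f = factor(rep(c("a", "b"), each = 20)),
    y = rep(c(1, 3), each = 20) + rep(c(-0.5, 0.5), 20)
  )
  fit <- fit_model(d, y ~ f, family = "gaussian")
  ct <- emm_pairwise(fit, "f")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$estimate, mean(d$y[d$f == "a"]) - mean(d$y[d$f == "b"]))
  d3 <- tibble::tibble(
    f = factor(rep(c("a", "b", "c"), each = 10)),
    y = stats::rnorm(30)
  )
  ct3 <- emm_pairwise(fit_model(d3, y ~ f, family = "gaussian"), "f")
  expect_equal(nrow(ct3), 3)          # all pairs of three levels
  expect_true(all(ct3$p_adjusted >= ct3$p_value - 1e-12))
  expect_error(emm_pairwise(fit, "zzz"), "not in the model data")
})

test_that("BH adjustment matches the hand computation and is idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 4)), rep(0.07, 4))
  once <- bh_adjust(c(0.001, 0.013, 0.04, 0.04, 0.8))
  expect_true(all(diff(sort(once)) >= 0))   # monotone in the order statistics
  expect_true(all(once >= c(0.001, 0.013, 0.04, 0.04, 0.8)))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("predicted switch curves are logistic in DeltaSocial", {
  d <- withr::with_seed(6, {
    ds <- sample(-5:5, 400, replace = TRUE)
    p <- stats::plogis(-1 + 0.4 * ds)
    tibble::tibble(delta_social = ds,
                   switch = stats::rbinom(400, 1, p))
  })
  f <- fit_model(d, switch ~ delta_social, family = "binomial")
  curve <- predicted_switch_curve(f, grid = -9:9)
  expect_equal(nrow(curve), 19)
  expect_true(all(diff(curve$prob) > 0))   # positive slope -> increasing
  at0 <- predicted_switch_curve(f, grid = 0)$prob
  expect_equal(at0, unname(stats::plogis(f$coefficients[1])), tolerance = 1e-9)
  expect_error(predicted_switch_curve(f, grid = numeric(0)), "empty")
  g <- fit_model(tibble::tibble(y = 1:5, delta_social = 1:5), y ~ delta_social,
                 family = "gaussian")
  expect_error(predicted_switch_curve(g, grid = 0:1), "binomial")
})
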