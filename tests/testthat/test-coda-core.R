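test_that("the independent-mutation model recovers a noiseless product surface", {
  act <- toy_activity(n_doubles = 400, seed = 1)
  # at the default tube width residuals are bounded by ~epsilon
  model0 <- fit_independent_model(act)
  d0 <- model0$doubles
  expect_lt(max(abs(predict_double(model0, d0$ra_i, d0$ra_j) -
                      d0$ra_i * d0$ra_j)), 0.105)
  # a tighter tube tracks the noiseless product surface within 0.05
  model <- fit_independent_model(act, epsilon = 0.04)
  d <- model$doubles
  pred <- predict_double(model, d$ra_i, d$ra_j)
  expect_lt(max(abs(pred - d$ra_i * d$ra_j)), 0.05)
  # symmetry to numerical tolerance
  expect_equal(predict_double(model, 0.3, 0.7),
               predict_double(model, 0.7, 0.3), tolerance = 1e-9)
  # oracle = the generating product model (absolute tolerances)
  expect_lt(abs(predict_double(model, 0.5, 0.5) - 0.25), 0.05)
  expect_lt(abs(predict_double(model, 1.0, 1.0) - 1.0), 0.1)
})

test_that("too few doubles or missing singles are rejected/skipped", {
  act <- toy_activity(n_doubles = 12, seed = 5)
  expect_error(fit_independent_model(act), "at least 50")
  act2 <- toy_activity(n_doubles = 200, seed = 6)
  drop <- act2$n_mut == 1 & startsWith(act2$subs, "G1")
  act2_df <- act2[!drop, ]
  attr(act2_df, "wild_type") <- attr(act2, "wild_type")
  class(act2_df) <- class(act2)
  has_g1 <- grepl("(^|,)G1[ACU]", act2_df$subs) & act2_df$n_mut == 2
  if (any(has_g1)) {
    expect_warning(fit_independent_model(act2_df), "skipped")
  }
})

test_that("CODA score follows its exact formula", {
  expect_equal(coda_score(0.3, 0.3), 0)
  expect_equal(coda_score(1.0, 0.0), 5.0)
  expect_equal(coda_score(0.8, 0.2), 1.5)
  expect_equal(coda_score(0.8, 0.2, shift = 0.5), 0.6 / 0.7)
  # variant whose observation equals the prediction scores exactly 0
  expect_equal(coda_score(c(0.1, 0.5, 2), c(0.1, 0.5, 2)), c(0, 0, 0))
})

test_that("mixture de-mixing matches the closed-form truncated-mixture oracle", {
  # oracle: with scores from p*N(a2,sd2) + (1-p)*N(a1,sd1), the one-pass
  # rule computes the mean/sd of all scores, cuts at mean + 3 sd, and
  # takes the truncated-mixture moments above the cut
  p <- 0.013; a1t <- -0.004; sd1t <- 0.237; a2t <- 1.26; sd2t <- 0.763
  mu <- (1 - p) * a1t + p * a2t
  v <- (1 - p) * (sd1t^2 + (a1t - mu)^2) + p * (sd2t^2 + (a2t - mu)^2)
  cut <- mu + 3 * sqrt(v)
  trunc_mean <- function(m, s) {
    a <- (cut - m) / s
    m + s * dnorm(a) / pnorm(a, lower.tail = FALSE)
  }
  w2 <- p * pnorm(cut, a2t, sd2t, lower.tail = FALSE)
  w1 <- (1 - p) * pnorm(cut, a1t, sd1t, lower.tail = FALSE)
  a2_expect <- (w2 * trunc_mean(a2t, sd2t) + w1 * trunc_mean(a1t, sd1t)) /
    (w2 + w1)
  p_expect <- w1 + w2

  set.seed(31)
  reps <- purrr::map(1:5, function(k) {
    z <- runif(20000) < p
    x <- ifelse(z, rnorm(20000, a2t, sd2t), rnorm(20000, a1t, sd1t))
    fit_mixture(x)
  })
  a2_hat <- purrr::map_dbl(reps, "a2")
  p_hat <- purrr::map_dbl(reps, "p_paired")
  expect_lt(max(abs(a2_hat - a2_expect)), 0.15)
  expect_lt(max(abs(p_hat - p_expect)), 0.004)
})

test_that("mixture fitting rejects degenerate inputs", {
  expect_error(fit_mixture(rep(1, 200)), "zero variance")
  expect_error(fit_mixture(rnorm(50)), "at least 100")
})

test_that("a pure Gaussian sample leaves only the 3-sd tail as outliers", {
  set.seed(5)
  fits <- purrr::map(1:4, ~ fit_mixture(rnorm(20000)))
  p_hat <- purrr::map_dbl(fits, "p_paired")
  expect_true(all(abs(p_hat - 0.0013) < 0.001))
})

test_that("pairing score equals direct naive-Bayes density arithmetic", {
  mx <- structure(list(a1 = -0.004, sd1 = 0.237, a2 = 1.26, sd2 = 0.763,
                       p_paired = 0.013), class = "coda_mixture")
  oracle <- function(coda) {
    dp <- dnorm(coda, 1.26, 0.763)
    du <- dnorm(coda, -0.004, 0.237)
    log(dp / (dp * 0.013 + du * 0.987))
  }
  expect_equal(pairing_score(1.26, mx), oracle(1.26))
  expect_equal(pairing_score(1.26, mx), 4.3, tolerance = 0.05)
  expect_equal(pairing_score(0, mx), oracle(0))
  expect_equal(pairing_score(0, mx), -2.5, tolerance = 0.1)
  # with P(paired) = 1 the score is identically zero
  mx1 <- mx; mx1$p_paired <- 1
  expect_equal(pairing_score(c(-1, 0, 2, 5), mx1), rep(0, 4))
  # monotone nondecreasing beyond the paired mean
  grid <- seq(1.26, 8, length.out = 100)
  expect_true(all(diff(pairing_score(grid, mx)) >= -1e-12))
})

test_that("per-position scores aggregate mutation combinations by maximum", {
  planted <- tibble::tibble(i = c(2, 5), j = c(15, 12))
  act <- toy_activity(n_doubles = 400, seed = 8, planted = planted)
  fit <- coda_fit(act)
  pm <- fit$scores$per_mutation
  pp <- fit$scores$per_position
  by_hand <- dplyr::summarise(dplyr::group_by(pm, i, j),
                              ps = max(ps), .groups = "drop")
  expect_equal(dplyr::arrange(pp[, c("i", "j", "ps")], i, j),
               dplyr::arrange(by_hand, i, j))
  # a pair with no double data is absent from the map
  seen <- unique(paste(pm$i, pm$j))
  L <- attr(act, "wild_type")$length
  allp <- tidyr::expand_grid(i = 1:(L - 1), j = 1:L) |>
    dplyr::filter(j > i)
  expect_lt(length(seen), nrow(allp))
  expect_true(all(paste(pp$i, pp$j) %in% seen))
  # the mean aggregation alternative is wired through
  fit_mean <- score_all(act, fit$model, fit$mixture, aggregate = "mean")
  by_mean <- dplyr::summarise(dplyr::group_by(pm, i, j),
                              ps = mean(ps), .groups = "drop")
  expect_equal(dplyr::arrange(fit_mean$per_position[, c("i", "j", "ps")],
                              i, j),
               dplyr::arrange(by_mean, i, j))
})

test_that("planted compensatory pairs top the position ranking", {
  fx <- benchmark_fixture()
  pp <- dplyr::arrange(fx$fit$scores$per_position, dplyr::desc(ps))
  truth_keys <- paste(fx$rz$structure$i, fx$rz$structure$j)
  top10 <- paste(pp$i[1:10], pp$j[1:10])
  expect_gte(sum(top10 %in% truth_keys), 7)
})

test_that("pairing scores of planted-pair mutations dominate the rest", {
  fx <- benchmark_fixture()
  pm <- fx$fit$scores$per_mutation
  truth_keys <- paste(fx$rz$structure$i, fx$rz$structure$j)
  is_pair <- paste(pm$i, pm$j) %in% truth_keys
  wt <- suppressWarnings(
    stats::wilcox.test(pm$ps[is_pair], pm$ps[!is_pair],
                       alternative = "greater"))
  expect_lt(wt$p.value, 1e-6)
})

test_that("no scoring operation consults the reference structure", {
  # unsupervised contract: the scoring surface takes only the activity
  # table and tuning constants
  expect_named(formals(coda_fit),
               c("table", "C", "gamma", "epsilon", "shift", "k_sd",
                 "aggregate"))
  expect_named(formals(fit_independent_model),
               c("table", "C", "gamma", "epsilon"))
  expect_named(formals(fit_mixture), c("scores", "k_sd"))
})

test_that("tidy and glance summarise a CODA fit", {
  fx <- benchmark_fixture()
  td <- tidy(fx$fit)
  expect_equal(td$component, c("unpaired", "paired"))
  expect_equal(sum(td$weight), 1)
  gl <- glance(fx$fit)
  expect_equal(gl$a2, fx$fit$mixture$a2)
  expect_gt(gl$n_doubles, 5000)
})
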