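test_that("simulate_engagement is deterministic and validates parameters", {
  a <- simulate_engagement(n_influencers = 10, posts_per_influencer = 5, seed = 3)
  b <- simulate_engagement(n_influencers = 10, posts_per_influencer = 5, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 50)
  expect_true(all(a$likes >= 0 & a$likes == round(a$likes)))

  expect_error(simulate_engagement(true_irr_warning = -1), "> 0")
  expect_error(simulate_engagement(nb_dispersion = 0), "> 0")
  expect_error(simulate_engagement(warning_prevalence = 2), "\\[0, 1\\]")
  expect_error(simulate_engagement(brand_effects = c(0, 1)), "named")
})

test_that("a null warning effect leaves group means equal at large n", {
  posts <- simulate_engagement(n_influencers = 500, posts_per_influencer = 100,
                               true_irr_warning = 1.0, warning_prevalence = 0.5,
                               seed = 21)
  m1 <- mean(posts$likes[posts$has_warning])
  m0 <- mean(posts$likes[!posts$has_warning])
  expect_lt(abs(m1 - m0) / m0, 0.05)
})

test_that("small NB dispersion produces strong overdispersion", {
  posts <- simulate_engagement(n_influencers = 50, posts_per_influencer = 20,
                               nb_dispersion = 0.5, seed = 8)
  expect_gt(var(posts$likes) / mean(posts$likes), 2)
})

test_that("the NB mixed fit recovers a known warning rate ratio", {
  posts <- simulate_engagement(n_influencers = 100, posts_per_influencer = 20,
                               true_irr_warning = 0.59, seed = 42)
  fit <- fit_nb_mixed(posts, "likes")
  expect_true(fit$converged)
  i <- match("has_warning", fit$terms)
  expect_lt(abs(fit$coefficients[i] - log(0.59)), 3 * fit$se[i])
  # IRR/coefficient consistency to machine precision, all terms
  expect_equal(log(fit$irr), fit$coefficients, tolerance = 1e-12)
  expect_true(all(fit$ci95[, "lower"] <= fit$ci95[, "upper"]))
  expect_gt(fit$dispersion, 0)
})

test_that("a zero random-intercept variance is recovered near zero", {
  posts <- simulate_engagement(n_influencers = 60, posts_per_influencer = 30,
                               random_intercept_sd = 0, seed = 15)
  fit <- fit_nb_mixed(posts, "likes")
  expect_lt(fit$random_intercept_variance, 0.05)
})

test_that("fit_nb_mixed matches an unmixed NB fit when grouping is inert", {
  skip_if_not_installed("MASS")
  posts <- simulate_engagement(n_influencers = 40, posts_per_influencer = 25,
                               random_intercept_sd = 0, seed = 31)
  fit <- fit_nb_mixed(posts, "likes")
  ref <- MASS::glm.nb(
    likes ~ as.integer(has_warning) + log(followers + 1) + factor(brand),
    data = posts
  )
  i <- match("has_warning", fit$terms)
  expect_equal(fit$coefficients[i], unname(coef(ref)[2]), tolerance = 0.02)
})

test_that("fit_nb_mixed rejects inestimable inputs", {
  posts <- simulate_engagement(n_influencers = 10, posts_per_influencer = 5, seed = 1)
  const <- posts; const$has_warning <- FALSE
  expect_error(fit_nb_mixed(const, "likes"), "constant")
  zeros <- posts; zeros$likes <- 0L
  expect_error(fit_nb_mixed(zeros, "likes"), "zero")
  one_infl <- posts; one_infl$influencer_id <- "infl_001"
  expect_error(fit_nb_mixed(one_infl, "likes"), "2 influencers")
  expect_error(fit_nb_mixed(posts[, -3], "likes"), "missing columns")
})

test_that("tidy and glance expose the fit in broom shape", {
  posts <- simulate_engagement(n_influencers = 30, posts_per_influencer = 10, seed = 6)
  fit <- fit_nb_mixed(posts, "comments")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "irr", "conf.low",
                    "conf.high", "p.value") %in% names(td)))
  expect_equal(nrow(td), length(fit$terms))
  gl <- glance(fit)
  expect_equal(gl$outcome, "comments")
  expect_equal(gl$nobs, 300)
})

test_that("pct_change maps rate ratios to signed percent changes", {
  expect_equal(round_half_up(pct_change(0.59)), -41)
  expect_equal(round_half_up(pct_change(0.46)), -54)
  expect_equal(pct_change(1.0), 0)
  expect_equal(pct_change(2.0), 100)
  expect_error(pct_change(0), "positive")
  expect_error(pct_change(-0.5), "positive")
})

test_that("vif is near 1 for independent predictors", {
  posts <- simulate_engagement(n_influencers = 100, posts_per_influencer = 10,
                               seed = 12)
  v <- vif_scores(posts)
  expect_true(all(v >= 1))
  expect_true(all(v[c("has_warning", "log_followers")] <= 1.1))
})

test_that("vif matches the closed form under known collinearity", {
  set.seed(44)
  n <- 5000
  warn <- runif(n) < 0.5
  # follower covariate correlated ~0.8 with the warning indicator
  raw <- as.numeric(warn) + rnorm(n, 0, 0.375)
  posts <- tibble::tibble(
    post_id = as.character(seq_len(n)), influencer_id = "x",
    brand = sample(c("A", "B"), n, replace = TRUE),
    followers = pmax(0, round(exp(raw))), has_warning = warn,
    likes = 1L, comments = 1L
  )
  posts$followers <- raw  # raw transform uses the column as-is
  v <- vif_scores(posts, followers_transform = "raw")
  expect_equal(unname(v["has_warning"]), 1 / (1 - 0.64), tolerance = 0.3 / 2.78)
})

test_that("vif cross-checks against car on numeric predictors", {
  skip_if_not_installed("car")
  posts <- simulate_engagement(n_influencers = 80, posts_per_influencer = 10,
                               seed = 18)
  v <- vif_scores(posts)
  ref <- car::vif(lm(likes ~ as.integer(has_warning) + log(followers + 1),
                     data = posts))
  # same two-predictor VIF when the brand factor is excluded on both sides
  v2 <- 1 / (1 - summary(lm(log(followers + 1) ~ as.integer(has_warning),
                            data = posts))$r.squared)
  expect_equal(unname(ref[2]), v2, tolerance = 1e-8)
})

test_that("vif detects rank deficiency and names the columns", {
  posts <- simulate_engagement(n_influencers = 20, posts_per_influencer = 5, seed = 2)
  posts$followers <- as.numeric(posts$has_warning)  # duplicate of the indicator
  expect_error(vif_scores(posts, followers_transform = "raw"), "rank deficient")
})

test_that("cohen_kappa matches hand computations and handles degeneracy", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))$kappa, 1)

  # 2x2 cross-tab [[45, 5], [5, 45]]: po = 0.9, pe = 0.5, kappa = 0.8
  r1 <- c(rep("a", 50), rep("b", 50))
  r2 <- c(rep("a", 45), rep("b", 5), rep("a", 5), rep("b", 45))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$kappa, 0.8)
  expect_equal(k$observed_agreement, 0.9)
  expect_equal(k$expected_agreement, 0.5)

  # constant rater vs mixed: finite, non-positive
  k2 <- cohen_kappa(rep("a", 10), rep(c("a", "b"), 5))
  expect_true(is.finite(k2$kappa))
  expect_lte(k2$kappa, 0)

  expect_error(cohen_kappa(1:3, 1:4), "equal length")
})

test_that("kappa is invariant under category relabeling and 1 iff perfect", {
  set.seed(5)
  r1 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  r2 <- ifelse(runif(60) < 0.8, r1, sample(c("x", "y", "z"), 60, replace = TRUE))
  k_orig <- cohen_kappa(r1, r2)$kappa
  relab <- c(x = "cat", y = "dog", z = "owl")
  k_new <- cohen_kappa(relab[r1], relab[r2])$kappa
  expect_equal(k_orig, k_new)
  expect_lt(k_orig, 1)  # imperfect agreement never reaches 1 when pe < 1
})
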