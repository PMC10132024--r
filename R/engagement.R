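#' Simulate influencer post engagement data
#'
#' Draws a synthetic corpus of post records from the generative model the
#' engagement analysis assumes: per-influencer random intercepts on the
#' log-rate scale, a log-linear follower effect, brand offsets, a
#' multiplicative warning effect, and negative binomial (NB2) counts.
#' Follower counts are an influencer-level attribute drawn once per
#' influencer from a log-normal. Comment counts share the linear predictor
#' shape with a lower baseline. Deterministic per seed.
#'
#' @param n_influencers Number of influencers.
#' @param posts_per_influencer Posts per influencer.
#' @param true_irr_warning Multiplicative effect of a warning on the
#'   expected count (rate ratio; < 1 means fewer likes).
#' @param true_coef_followers Coefficient on `log(followers + 1)`.
#' @param brand_effects Named numeric log-scale brand offsets; names define
#'   the brand levels (first alphabetically is the reference and should be 0).
#' @param intercept Log-scale intercept of the likes model.
#' @param nb_dispersion NB2 dispersion theta (variance = mu + mu^2/theta).
#' @param random_intercept_sd SD of per-influencer random intercepts.
#' @param warning_prevalence Probability a post carries a warning.
#' @param followers_meanlog,followers_sdlog Log-normal parameters of
#'   influencer follower counts.
#' @param comments_offset Log-scale shift of the comments baseline relative
#'   to likes.
#' @param seed Integer seed.
#' @return Tibble of post records: `post_id`, `influencer_id`, `brand`,
#'   `followers`, `has_warning`, `likes`, `comments`.
#' @export
simulate_engagement <- function(n_influencers = 100,
                                posts_per_influencer = 20,
                                true_irr_warning = 0.59,
                                true_coef_followers = 0.6,
                                brand_effects = c("Backwoods" = 0,
                                                  "Dutch Masters" = 0.10,
                                                  "Swisher Sweets" = -0.10),
                                intercept = -1.0,
                                nb_dispersion = 1.5,
                                random_intercept_sd = 0.5,
                                warning_prevalence = 0.1,
                                followers_meanlog = log(2e4),
                                followers_sdlog = 1.2,
                                comments_offset = -3,
                                seed = 1L) {
  if (true_irr_warning <= 0) abort("`true_irr_warning` must be > 0")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be > 0")
  if (random_intercept_sd < 0) abort("`random_intercept_sd` must be >= 0")
  if (warning_prevalence < 0 || warning_prevalence > 1) abort("`warning_prevalence` must be in [0, 1]")
  if (n_influencers < 1 || posts_per_influencer < 1) abort("sizes must be >= 1")
  brands <- names(brand_effects)
  if (is.null(brands)) abort("`brand_effects` must be a named numeric vector")
  with_preserved_rng({
    set.seed(seed)
    n <- n_influencers * posts_per_influencer
    u <- rnorm(n_influencers, 0, random_intercept_sd)
    followers_i <- round(rlnorm(n_influencers, followers_meanlog, followers_sdlog))
    # each influencer mostly posts for one brand; occasional cross-posts
    home_brand <- sample(brands, n_influencers, replace = TRUE)
    infl <- rep(seq_len(n_influencers), each = posts_per_influencer)
    brand <- home_brand[infl]
    switch_post <- runif(n) < 0.1
    brand[switch_post] <- sample(brands, sum(switch_post), replace = TRUE)
    followers <- followers_i[infl]
    has_warning <- runif(n) < warning_prevalence
    eta <- intercept +
      true_coef_followers * log(followers + 1) +
      log(true_irr_warning) * has_warning +
      unname(brand_effects[brand]) +
      u[infl]
    likes <- rnbinom(n, size = nb_dispersion, mu = exp(eta))
    comments <- rnbinom(n, size = nb_dispersion, mu = exp(eta + comments_offset))
    tibble(
      post_id = sprintf("post_%05d", seq_len(n)),
      influencer_id = sprintf("infl_%03d", infl),
      brand = brand,
      followers = followers,
      has_warning = has_warning,
      likes = likes,
      comments = comments
    )
  })
}

#' Fit the negative binomial mixed engagement model
#'
#' Fits `outcome ~ has_warning + log(followers + 1) + brand` with a
#' per-influencer random intercept and NB2 dispersion, the standard model
#' for overdispersed, within-influencer-correlated engagement counts.
#' Estimation uses `glmmTMB` (Laplace approximation). Exponentiated
#' coefficients are reported as incidence rate ratios with Wald 95% CIs.
#'
#' @param posts Data frame of post records (see [simulate_engagement()] for
#'   the columns).
#' @param outcome `"likes"` or `"comments"`.
#' @param followers_transform `"log1p"` (default) enters followers as
#'   `log(followers + 1)`; `"raw"` enters the raw count.
#' @return An `nb_fit`: coefficients, standard errors, IRRs with 95% CIs,
#'   p-values, NB dispersion, random-intercept variance, `n_obs`,
#'   `converged`. Methods: [tidy()], [glance()], `print`.
#' @export
fit_nb_mixed <- function(posts, outcome = c("likes", "comments"),
                         followers_transform = c("log1p", "raw")) {
  outcome <- match.arg(outcome)
  followers_transform <- match.arg(followers_transform)
  posts <- validate_posts(posts, outcome)
  df <- tibble(
    y = posts[[outcome]],
    has_warning = as.integer(posts$has_warning),
    log_followers = if (followers_transform == "log1p") log(posts$followers + 1)
                    else as.numeric(posts$followers),
    brand = factor(posts$brand, levels = sort(unique(posts$brand))),
    influencer = factor(posts$influencer_id)
  )
  fit <- glmmTMB::glmmTMB(
    y ~ has_warning + log_followers + brand + (1 | influencer),
    family = glmmTMB::nbinom2(), data = df
  )
  sm <- summary(fit)
  co <- sm$coefficients$cond
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]; p <- co[, "Pr(>|z|)"]
  converged <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
  re_var <- tryCatch(
    as.numeric(glmmTMB::VarCorr(fit)$cond$influencer[1, 1]),
    error = function(e) NA_real_
  )
  structure(
    list(
      outcome = outcome,
      terms = rownames(co),
      coefficients = unname(est),
      se = unname(se),
      irr = unname(exp(est)),
      ci95 = cbind(lower = unname(exp(est - 1.96 * se)),
                   upper = unname(exp(est + 1.96 * se))),
      p_values = unname(p),
      dispersion = glmmTMB::sigma(fit),
      random_intercept_variance = re_var,
      n_obs = nrow(df),
      n_influencers = nlevels(df$influencer),
      converged = converged,
      model = fit
    ),
    class = "nb_fit"
  )
}

validate_posts <- function(posts, outcome) {
  posts <- as_tibble(posts)
  required <- c("post_id", "influencer_id", "brand", "followers", "has_warning", outcome)
  missing <- setdiff(required, names(posts))
  if (length(missing) > 0) abort(paste("posts table is missing columns:", paste(missing, collapse = ", ")))
  if (any(posts[[outcome]] < 0) || any(posts[[outcome]] != round(posts[[outcome]]))) {
    abort(sprintf("`%s` must be non-negative integer counts", outcome))
  }
  if (all(posts[[outcome]] == 0)) abort(sprintf("all `%s` counts are zero; the model is not estimable", outcome))
  if (length(unique(posts$influencer_id)) < 2) abort("need at least 2 influencers for a random intercept")
  if (length(unique(posts$has_warning)) < 2) {
    abort("`has_warning` is constant; the warning effect is not estimable")
  }
  posts
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("Negative binomial mixed model for %s (n = %d posts, %d influencers)\n",
              x$outcome, x$n_obs, x$n_influencers))
  cat(sprintf("NB dispersion (theta): %.3f  random-intercept variance: %.3f  converged: %s\n\n",
              x$dispersion, x$random_intercept_variance, x$converged))
  tab <- data.frame(
    term = x$terms,
    estimate = sprintf("%.4f", x$coefficients),
    irr = sprintf("%.3f", x$irr),
    ci95 = sprintf("[%.3f, %.3f]", x$ci95[, "lower"], x$ci95[, "upper"]),
    p = format.pval(x$p_values, digits = 3)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_nb_mixed
#' @param x An `nb_fit`.
#' @param ... Unused.
#' @export
tidy.nb_fit <- function(x, ...) {
  tibble(
    term = x$terms,
    estimate = x$coefficients,
    std.error = x$se,
    irr = x$irr,
    conf.low = x$ci95[, "lower"],
    conf.high = x$ci95[, "upper"],
    p.value = x$p_values
  )
}

#' @rdname fit_nb_mixed
#' @export
glance.nb_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    nobs = x$n_obs,
    n_influencers = x$n_influencers,
    dispersion = x$dispersion,
    random_intercept_variance = x$random_intercept_variance,
    converged = x$converged,
    AIC = tryCatch(stats::AIC(x$model), error = function(e) NA_real_)
  )
}

#' Percent change implied by a rate ratio
#'
#' `(irr - 1) * 100`; negative values are decreases. Report display rounds
#' to the nearest integer percent.
#'
#' @param irr Positive rate ratio(s).
#' @export
pct_change <- function(irr) {
  if (any(!is.finite(irr)) || any(irr <= 0)) abort("`irr` must be positive")
  (irr - 1) * 100
}

#' Variance inflation factors of the engagement fixed effects
#'
#' Classic per-column VIF on the fixed-effects design matrix of the
#' engagement model (warning indicator, transformed follower count, brand
#' dummies): each column is regressed on the others and `1 / (1 - R^2)`
#' reported. Values start at 1 for orthogonal predictors.
#'
#' @inheritParams fit_nb_mixed
#' @return Named numeric vector of VIF scores.
#' @export
vif_scores <- function(posts, followers_transform = c("log1p", "raw")) {
  followers_transform <- match.arg(followers_transform)
  posts <- as_tibble(posts)
  df <- tibble(
    has_warning = as.integer(posts$has_warning),
    log_followers = if (followers_transform == "log1p") log(posts$followers + 1)
                    else as.numeric(posts$followers),
    brand = factor(posts$brand, levels = sort(unique(posts$brand)))
  )
  X <- model.matrix(~ has_warning + log_followers + brand, data = df)[, -1, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep_cols) - 1L
    abort(paste("design matrix is rank deficient; collinear columns:",
                paste(colnames(X)[dropped], collapse = ", ")))
  }
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement from the two raters' cross-tabulation:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed and `pe` the
#' chance agreement. Used to report intercoder reliability of manual image
#' coding.
#'
#' @param rater1,rater2 Equal-length label vectors.
#' @return A `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n_items`.
#' @export
cohen_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) abort("`rater1` and `rater2` must have equal length")
  n <- length(rater1)
  if (n < 1) abort("need at least one rated item")
  levels_all <- sort(unique(c(as.character(rater1), as.character(rater2))))
  t1 <- factor(as.character(rater1), levels = levels_all)
  t2 <- factor(as.character(rater2), levels = levels_all)
  tab <- table(t1, t2) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  kap <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(
    list(kappa = kap, observed_agreement = po, expected_agreement = pe, n_items = n),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (observed %.3f, expected %.3f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n_items))
  invisible(x)
}
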