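# Simulated count datasets for fitting tests.
sim_counts <- function(n = 20, beta0 = -8, beta1 = 0.7, alpha = 0.4,
                       seed = 1) {
  set.seed(seed)
  data.frame(zone_id = sprintf("z%02d", seq_len(n)),
             score = runif(n, 1, 4),
             population = round(runif(n, 2000, 60000))) |>
    within({
      mu <- population * exp(beta0 + beta1 * score)
      count <- if (alpha == 0) rpois(n, mu)
               else rnbinom(n, mu = mu, size = 1 / alpha)
      rm(mu)
    })
}

test_that("NB2 log-likelihood has the correct closed-form values and Poisson limit", {
  # single observation y=0, mu=1, alpha=1: logL = log((1/(1+mu))^(1/alpha))
  ll <- nb_loglik(beta = 0, alpha = 1, y = 0, X = matrix(1, 1, 1),
                  offset = 0)
  expect_equal(ll, -log(2), tolerance = 1e-12)
  # Poisson limit: alpha -> 0 approaches the Poisson log-likelihood
  d <- sim_counts(15, seed = 2)
  X <- cbind(1, d$score); off <- log(d$population)
  beta <- c(-8, 0.7)
  pois <- sum(stats::dpois(d$count, exp(X %*% beta + off), log = TRUE))
  expect_equal(nb_loglik(beta, 1e-12, d$count, X, off), pois,
               tolerance = 1e-6)
  expect_equal(nb_loglik(beta, 1e-7, d$count, X, off), pois,
               tolerance = 1e-4)
  expect_error(nb_loglik(c(500, 500), 0.5, d$count, X, off), "non-finite")
})

test_that("the fitted optimum is a local maximum of the likelihood", {
  d <- sim_counts(25, seed = 3)
  f <- fit_nb(d, terms = "score")
  X <- cbind(1, d$score); off <- log(d$population)
  ll_hat <- nb_loglik(f$coefficients, f$alpha, d$count, X, off)
  expect_equal(ll_hat, f$loglik, tolerance = 1e-10)
  for (dir in list(c(1, 0), c(0, 1), c(-1, 1), c(1, 1))) {
    step <- 0.05 * dir / sqrt(sum(dir^2))
    expect_lt(nb_loglik(f$coefficients + step, f$alpha, d$count, X, off),
              ll_hat)
    expect_lt(nb_loglik(f$coefficients - step, f$alpha, d$count, X, off),
              ll_hat)
  }
})

test_that("fit matches the independent reference implementation", {
  skip_if_not_installed("MASS")
  for (seed in 1:3) {
    d <- sim_counts(30, seed = seed)
    f <- fit_nb(d, terms = "score")
    ref <- MASS::glm.nb(count ~ score + offset(log(population)), data = d)
    expect_true(f$converged)
    expect_equal(unname(f$coefficients), unname(coef(ref)),
                 tolerance = 1e-3)
    expect_equal(f$theta, ref$theta, tolerance = 1e-2)
    expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  }
})

test_that("Poisson-generated data yields near-zero dispersion and nested betas", {
  d <- sim_counts(40, alpha = 0, seed = 4)
  f <- fit_nb(d, terms = "score")
  expect_lt(f$alpha, 0.05)
  expect_lt(abs(f$coefficients["score"] - 0.7), 3 * f$se["score"])
  # Poisson nesting: at pinned tiny alpha the IRLS solution matches glm
  pois <- glm(count ~ score + offset(log(population)), data = d,
              family = poisson())
  b <- redscore:::nb_irls(c(-8, 0), 1e-9, d$count, cbind(1, d$score),
                          log(d$population))
  expect_equal(unname(b), unname(coef(pois)), tolerance = 1e-4)
})

test_that("rescaling the offset shifts only the intercept", {
  d <- sim_counts(30, seed = 5)
  f1 <- fit_nb(d, terms = "score")
  d2 <- d; d2$population <- d2$population * 10
  f2 <- fit_nb(d2, terms = "score")
  expect_equal(f2$coefficients["(Intercept)"],
               f1$coefficients["(Intercept)"] - log(10), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(f2$coefficients["score"], f1$coefficients["score"],
               tolerance = 1e-6)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(exp(f2$coefficients["score"]), exp(f1$coefficients["score"]),
               tolerance = 1e-6)
})

test_that("degenerate inputs fail loudly", {
  d <- sim_counts(20, seed = 6)
  d$count <- 0L
  expect_error(fit_nb(d, terms = "score"), "all counts are zero")
  expect_error(fit_nb(sim_counts(2, seed = 7), terms = "score"), "too few")
})

test_that("effect table satisfies its algebraic identities", {
  d <- sim_counts(30, seed = 8)
  f <- fit_nb(d, terms = "score")
  et <- effect_table(f)
  expect_true(all(et$irr > 0))
  expect_true(all(et$irr_lo <= et$irr & et$irr <= et$irr_hi))
  # exp of the coefficient-scale CI midpoint equals the IRR
  expect_equal(exp((et$coef_lo + et$coef_hi) / 2), et$irr, tolerance = 1e-12)
  expect_equal(et$irr, exp(et$coef), tolerance = 1e-12)
  # beta = 0 with SE 1 would give IRR 1, p 1 (Wald formula check)
  expect_equal(2 * pnorm(-abs(0 / 1)), 1)
  expect_equal(et$p, 2 * pnorm(-abs(et$coef / et$se)), tolerance = 1e-12)
})

test_that("AIC ranking prefers the data-generating model and breaks ties by size", {
  d <- sim_counts(60, beta1 = 0.7, seed = 9)
  set.seed(10)
  d$noise <- rnorm(60)
  f0 <- fit_nb(d, terms = character(0))  # intercept-only
  f1 <- fit_nb(d, terms = "score")
  f2 <- fit_nb(d, terms = c("score", "noise"))
  ranked <- compare_aic(list(null = f0, score = f1, score_noise = f2))
  expect_equal(ranked$model[1], "score")
  expect_lt(f1$aic, f0$aic)
  # ties: identical fits ranked by parameter count
  tie <- compare_aic(list(big = f2, small = f1, same_small = f1))
  expect_equal(tie$model[1], "small")
  # mismatched response rows refuse to rank
  expect_error(compare_aic(list(f1, fit_nb(sim_counts(30, seed = 11),
                                           terms = "score"))),
               "identical response rows")
})

test_that("score-rate correlation behaves for exact, null and degenerate cases", {
  # exactly linear rate in score -> r = 1
  d <- data.frame(score = seq(1, 4, length.out = 10),
                  population = rep(1000, 10))
  d$count <- d$score * 10
  rc <- rate_correlation(d)
  expect_equal(rc$r, 1, tolerance = 1e-12)
  # permuted scores: small |r|, roughly uniform p over repeats
  set.seed(12)
  base <- sim_counts(400, beta1 = 0.7, seed = 12)
  ps <- replicate(20, {
    perm <- base; perm$score <- sample(perm$score)
    rate_correlation(perm)$p
  })
  rs <- replicate(20, {
    perm <- base; perm$score <- sample(perm$score)
    abs(rate_correlation(perm)$r)
  })
  expect_lt(max(rs), 0.2)
  expect_gt(mean(ps > 0.05), 0.5)
  expect_error(rate_correlation(data.frame(score = c(1, 1, 1),
                                           population = 1:3 * 100,
                                           count = c(1, 2, 3))),
               "constant")
})
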