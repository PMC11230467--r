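# Negative-binomial rate regression, written from first principles.
#
# Model: y_z ~ NB2(mu_z, alpha) with log mu_z = x_z' beta + log N_z, i.e. a
# rate model via the fixed log-population offset. Variance mu + alpha*mu^2;
# alpha -> 0 recovers Poisson. Fitting alternates IRLS for beta at fixed
# alpha with one-dimensional profile maximisation of the log-likelihood
# over log(alpha); standard errors come from the observed information in
# beta at the optimum. exp(beta) is the incidence rate ratio per unit of
# the covariate.

#' NB2 log-likelihood with offset
#'
#' `sum_z [ lgamma(y+1/a) - lgamma(1/a) - lgamma(y+1)
#'          + (1/a) log(1/(1+a mu)) + y log(a mu/(1+a mu)) ]`
#' with `mu = exp(X beta + offset)`. Below `poisson_threshold` the exact
#' Poisson limit `sum[y log mu - mu - lgamma(y+1)]` is used (the NB2 form is
#' numerically unstable as alpha -> 0).
#'
#' @param beta coefficient vector (intercept first).
#' @param alpha dispersion, `>= 0`.
#' @param y non-negative integer response.
#' @param X model matrix (including the intercept column).
#' @param offset offset vector on the log scale (e.g. log population).
#' @param poisson_threshold alpha below which the Poisson limit is used.
#' @return scalar log-likelihood.
#' @export
nb_loglik <- function(beta, alpha, y, X, offset,
                      poisson_threshold = 1e-8) {
  stopifnot(alpha >= 0)
  eta <- as.vector(X %*% beta) + offset
  mu <- exp(eta)
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu))[1]
    stop("non-finite mean for observation ",
         if (!is.null(rownames(X))) rownames(X)[bad] else bad,
         " (overflowing linear predictor)")
  }
  if (alpha < poisson_threshold) {
    return(sum(y * eta - mu - lgamma(y + 1)))
  }
  inv <- 1 / alpha
  sum(lgamma(y + inv) - lgamma(inv) - lgamma(y + 1) -
        inv * log1p(alpha * mu) + y * (log(alpha) + eta - log1p(alpha * mu)))
}

# IRLS for beta at fixed alpha (Fisher scoring with expected information
# weights mu/(1+alpha*mu)); returns converged beta.
nb_irls <- function(beta, alpha, y, X, offset, tol = 1e-12, max_iter = 50) {
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(X * w)
    beta_new <- tryCatch(solve(xtw %*% X, xtw %*% z)[, 1],
                         error = function(e)
                           stop("singular information matrix ",
                                "(perfect separation or collinear terms)"))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol * (1 + max(abs(beta)))) break
  }
  beta
}

#' Fit the negative-binomial rate model
#'
#' Maximum likelihood by alternating (a) iteratively reweighted least
#' squares for the coefficients at fixed dispersion and (b) profile
#' maximisation of the log-likelihood over `log(alpha)`, until the joint
#' change falls below `tol`. The dispersion is floored at the Poisson
#' boundary (`alpha_floor`) rather than allowed negative. Deterministic
#' given the data.
#'
#' @param data data frame with columns `count`, `population`, and every
#'   covariate named in `terms`. Rows with zero population or an undefined
#'   score/covariate are excluded with a message (no imputation).
#' @param terms character vector of covariate names (default
#'   `"score"`); the intercept and the log-population offset are always
#'   included.
#' @param tol joint convergence tolerance (default 1e-8): maximum relative
#'   coefficient change; the dispersion change is assessed on the
#'   `log(alpha)` scale at `sqrt(tol)`.
#' @param max_iter maximum outer iterations.
#' @param alpha_floor lower bound for the dispersion (Poisson boundary).
#' @return object of class `nb_fit`: list with `coefficients`, `se`,
#'   `vcov`, `alpha`, `theta` (`= 1/alpha`, shape parameterisation),
#'   `loglik`, `aic` (`2k - 2 logL`, dispersion counted in `k`),
#'   `converged`, `n_iter`, `n`, `terms`, plus the fitting frame.
#' @export
fit_nb <- function(data, terms = "score", tol = 1e-8, max_iter = 100,
                   alpha_floor = 1e-8) {
  stopifnot(all(c("count", "population") %in% names(data)),
            all(terms %in% names(data)))
  keep <- data$population > 0 & !is.na(data$count) &
    !Reduce(`|`, lapply(data[terms], is.na), rep(FALSE, nrow(data)))
  if (any(!keep))
    message("excluded from regression (zero population or undefined ",
            "covariate): ",
            paste(data$zone_id[!keep], collapse = ", "))
  d <- data[keep, , drop = FALSE]
  y <- d$count
  if (nrow(d) < length(terms) + 2)
    stop("too few usable zones to fit ", length(terms), " term(s)")
  if (all(y == 0)) stop("degenerate fit: all counts are zero")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, terms, drop = FALSE]))
  if (!is.null(d$zone_id)) rownames(X) <- d$zone_id
  offset <- log(d$population)
  # start at the Poisson fit, then moment estimate of alpha
  beta <- c(log(sum(y) / sum(d$population)), rep(0, length(terms)))
  beta <- nb_irls(beta, 0, y, X, offset)
  mu <- exp(as.vector(X %*% beta) + offset)
  alpha <- max(sum((y - mu)^2 - mu) / sum(mu^2), alpha_floor)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    beta_new <- nb_irls(beta, alpha, y, X, offset)
    prof <- stats::optimize(
      function(la) nb_loglik(beta_new, exp(la), y, X, offset),
      interval = c(log(alpha_floor), log(1e4)), maximum = TRUE,
      tol = 1e-12)
    alpha_new <- exp(prof$maximum)
    if (alpha_new < alpha_floor * 1.5) alpha_new <- alpha_floor
    delta_beta <- max(abs(beta_new - beta))
    delta_la <- abs(log(alpha_new) - log(alpha))
    beta <- beta_new; alpha <- alpha_new
    # the profile location is only identifiable to ~sqrt(eps), so the
    # dispersion part of the joint criterion is held at that scale
    if (delta_beta < tol * (1 + max(abs(beta))) &&
        delta_la < max(sqrt(tol), 1e-7)) { converged <- TRUE; break }
  }
  mu <- exp(as.vector(X %*% beta) + offset)
  # observed information for beta at (beta_hat, alpha_hat)
  w_obs <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  info <- t(X * w_obs) %*% X
  vcov <- tryCatch(solve(info), error = function(e)
    stop("singular observed information at the optimum"))
  se <- sqrt(diag(vcov))
  ll <- nb_loglik(beta, alpha, y, X, offset)
  k <- length(beta) + 1  # dispersion counted
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 vcov = vcov,
                 alpha = alpha, theta = 1 / alpha,
                 loglik = ll, aic = 2 * k - 2 * ll,
                 converged = converged, n_iter = it,
                 n = length(y), terms = terms,
                 y = y, X = X, offset = offset),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial rate model (log link, log-population offset)\n")
  cat("  n =", x$n, " alpha =", signif(x$alpha, 4),
      " logLik =", signif(x$loglik, 6), " AIC =", signif(x$aic, 6), "\n")
  if (!x$converged) cat("  WARNING: did not converge\n")
  print(effect_table(x, include_intercept = TRUE), row.names = FALSE)
  invisible(x)
}

#' Incidence rate ratios with Wald inference
#'
#' Per model term: IRR `= exp(beta)`, 95% confidence limits on both the
#' IRR scale (`exp(beta +- 1.96 se)`) and the coefficient (log) scale, and
#' the two-sided Wald p-value `2 Phi(-|beta/se|)`. p-values are carried at
#' full precision; presentation-layer formatting (e.g. "<0.001") is left to
#' the caller.
#'
#' @param fit a converged [fit_nb()] result.
#' @param conf_level confidence level (default 0.95).
#' @param include_intercept include the intercept row (default FALSE).
#' @return data frame with columns `term`, `irr`, `irr_lo`, `irr_hi`,
#'   `coef`, `coef_lo`, `coef_hi`, `se`, `p`.
#' @export
effect_table <- function(fit, conf_level = 0.95, include_intercept = FALSE) {
  stopifnot(inherits(fit, "nb_fit"))
  if (!fit$converged) stop("effect_table requires a converged fit")
  if (any(fit$se == 0)) stop("zero standard error")
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coefficients; se <- fit$se
  out <- data.frame(term = names(b),
                    irr = exp(b),
                    irr_lo = exp(b - zc * se), irr_hi = exp(b + zc * se),
                    coef = b, coef_lo = b - zc * se, coef_hi = b + zc * se,
                    se = se,
                    p = 2 * stats::pnorm(-abs(b / se)),
                    row.names = NULL)
  if (!include_intercept) out <- out[out$term != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank fitted models by AIC
#'
#' @param fits list of [fit_nb()] results fitted to the identical response
#'   rows.
#' @return data frame ranked by ascending AIC; ties broken by fewer
#'   parameters.
#' @export
compare_aic <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "nb_fit")))
  y0 <- fits[[1]]$y
  for (f in fits)
    if (!identical(f$y, y0))
      stop("models were not fitted to identical response rows")
  labels <- names(fits)
  if (is.null(labels))
    labels <- vapply(fits, function(f)
      paste(f$terms, collapse = "+"), "")
  k <- vapply(fits, function(f) length(f$coefficients) + 1, 0)
  aic <- vapply(fits, function(f) f$aic, 0)
  ord <- order(aic, k)
  data.frame(model = labels[ord], terms = vapply(
    fits[ord], function(f) paste(f$terms, collapse = "+"), ""),
    k = k[ord], loglik = vapply(fits[ord], function(f) f$loglik, 0),
    aic = aic[ord], delta_aic = aic[ord] - min(aic), row.names = NULL)
}

#' Correlation between redlining score and injury rate
#'
#' Pearson correlation of the per-zone score with the crude rate
#' `count/population`, with the two-sided t-based p-value
#' (`t = r sqrt(n-2)/sqrt(1-r^2)`).
#'
#' @param data data frame with columns `count`, `population`, and `score`.
#' @return list with `r`, `p`, `n`.
#' @export
rate_correlation <- function(data) {
  keep <- !is.na(data$score) & !is.na(data$count) & data$population > 0
  s <- data$score[keep]
  rate <- data$count[keep] / data$population[keep]
  if (length(s) < 3) stop("need at least 3 zones")
  if (stats::var(s) == 0 || stats::var(rate) == 0)
    stop("constant score or constant rate")
  ct <- stats::cor.test(s, rate, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(s))
}

#' Serialize model results to a JSON document
#'
#' @param fits named list of [fit_nb()] results.
#' @param path output JSON path.
#' @param correlation optional [rate_correlation()] result.
#' @export
write_models_json <- function(fits, path, correlation = NULL) {
  doc <- list(models = lapply(fits, function(f) list(
    terms = f$terms,
    coefficients = as.list(f$coefficients),
    se = as.list(f$se),
    alpha = f$alpha, theta = f$theta,
    loglik = f$loglik, aic = f$aic,
    converged = f$converged, n_iter = f$n_iter, n = f$n,
    effects = effect_table(f)
  )),
  aic_ranking = compare_aic(fits))
  if (!is.null(correlation)) doc$correlation <- correlation
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
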