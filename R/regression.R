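# Cauchy-prior penalized logistic regression (approximate-EM t-prior IRLS)
# and the likelihood-ratio variable scan with BH correction and McFadden
# pseudo-R2.

#' Penalized logistic regression with independent Student-t priors
#'
#' MAP estimation of a binomial logistic model under independent t priors
#' on the coefficients (default scale 2.5, df 1, i.e. Cauchy; intercept
#' scale 10), the configuration known to keep estimates finite under
#' complete separation. Continuous predictors are internally centered and
#' rescaled to SD 0.5 and binary (0/1) predictors centered, so the prior
#' scale has a common meaning across predictors; coefficients are
#' reported back on the input scale. Fitting alternates iteratively
#' reweighted least squares with an EM update of the per-coefficient
#' prior variances, stopping when `max |delta beta| < tol`.
#'
#' The reported log-likelihood is the UNPENALIZED binomial log-likelihood
#' evaluated at the MAP estimates, which is what the likelihood-ratio
#' scan compares between nested penalized fits.
#'
#' @param x Design matrix or data.frame of predictors (no intercept
#'   column; factors in a data.frame are dummy-coded against their first
#'   level).
#' @param y 0/1 outcome vector.
#' @param prior List with `scale`, `df`, `intercept_scale`,
#'   `intercept_df`.
#' @param tol Convergence tolerance on `max |delta beta|`.
#' @param max_iter Iteration cap; non-convergence is flagged, not hidden.
#' @return Object of class `logistic_fit`: `coefficients` (input scale),
#'   `loglik`, `deviance`, `n`, `converged`, `iterations`, `prior`,
#'   `fitted`.
#' @export
fit_penalized_logistic <- function(x, y,
                                   prior = list(scale = 2.5, df = 1,
                                                intercept_scale = 10,
                                                intercept_df = 1),
                                   tol = 1e-8, max_iter = 200L) {
  if (is.data.frame(x)) {
    x <- if (ncol(x) == 0L) matrix(0, nrow(x), 0L) else {
      stats::model.matrix(~ ., data = x)[, -1L, drop = FALSE]
    }
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop_nucmut("need both outcome classes present")
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  x_fit <- x[, keep, drop = FALSE]
  fit <- bayes_logit_engine(x_fit, y, prior, tol, max_iter)
  beta <- stats::setNames(rep(0, ncol(x) + 1L), c("(Intercept)", colnames(x)))
  beta["(Intercept)"] <- fit$beta[1L]
  beta[colnames(x_fit)] <- fit$beta[-1L]
  eta <- as.vector(cbind(1, x) %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(coefficients = beta, loglik = ll, deviance = -2 * ll,
                 n = length(y), converged = fit$converged,
                 iterations = fit$iterations, prior = prior, fitted = mu),
            class = "logistic_fit")
}

# Core fitter on the standardized scale. X without intercept column.
bayes_logit_engine <- function(x, y, prior, tol, max_iter) {
  n <- length(y)
  p <- ncol(x)
  # standardize: binary columns centered; continuous centered, sd -> 0.5
  ctr <- colMeans(x)
  scl <- rep(1, p)
  if (p > 0L) {
    for (j in seq_len(p)) {
      vals <- unique(x[, j])
      if (!all(vals %in% c(0, 1))) scl[j] <- 2 * stats::sd(x[, j])
    }
    xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  } else {
    xs <- x
  }
  X <- cbind(`(Intercept)` = 1, xs)
  s0 <- c(prior$intercept_scale, rep(prior$scale, p))
  df0 <- c(prior$intercept_df %||% prior$df, rep(prior$df, p))
  beta <- rep(0, p + 1L)
  vprior <- s0^2
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    A <- XtW %*% X + diag(1 / vprior, p + 1L)
    b <- XtW %*% z
    beta_new <- tryCatch(as.vector(solve(A, b)),
                         error = function(e) as.vector(qr.solve(A, b)))
    # EM update of the t-prior variances at the current estimates
    vprior <- (beta_new^2 + df0 * s0^2) / (1 + df0)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # back-transform to the input scale
  out <- numeric(p + 1L)
  if (p > 0L) {
    out[-1L] <- beta[-1L] / scl
    out[1L] <- beta[1L] - sum(beta[-1L] * ctr / scl)
  } else {
    out[1L] <- beta[1L]
  }
  list(beta = out, converged = converged, iterations = iter)
}

#' McFadden pseudo-R2
#'
#' `1 - loglik(model) / loglik(intercept-only)`, both unpenalized
#' log-likelihoods at the respective MAP estimates.
#'
#' @param fit,null_fit `logistic_fit` objects for the model and the
#'   intercept-only model on the same data.
#' @return Numeric scalar.
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  1 - fit$loglik / null_fit$loglik
}

#' Likelihood-ratio variable scan
#'
#' Fits the full model in each stratum, then for each variable refits
#' without that variable's columns and reports the likelihood-ratio
#' statistic `deviance(reduced) - deviance(full)` (clamped at 0 with a
#' warning if numerically negative), the chi-square p-value with df equal
#' to the number of columns removed, BH-adjusted p-values (family = the
#' variables scanned within one stratum), the sign of the coefficient for
#' scalar variables, the full-model McFadden pseudo-R2 and the drop in
#' pseudo-R2 expressed as a percent of the full-model pseudo-R2.
#'
#' @param table Feature table (e.g. [assemble_feature_table()]).
#' @param variables Character vector of modeled variable (column) names.
#' @param drop Variables to test by removal (default: all of
#'   `variables`).
#' @param strata Optional column name (e.g. `"class"`); the scan runs
#'   within each stratum level separately. `NULL` pools all rows.
#' @param interactions `"none"` or `"pairwise_context"` (adds all two-way
#'   interactions among the `ctx_*` context columns to the full model).
#' @param prior Prior configuration passed to
#'   [fit_penalized_logistic()].
#' @return data.frame of class `scan_result`: stratum, variable, lrt, df,
#'   p, p_adj, coef_sign, pseudo_r2_full, delta_pseudo_r2_pct.
#' @export
likelihood_ratio_scan <- function(table, variables, drop = variables,
                                  strata = NULL,
                                  interactions = c("none", "pairwise_context"),
                                  prior = list(scale = 2.5, df = 1,
                                               intercept_scale = 10,
                                               intercept_df = 1)) {
  interactions <- match.arg(interactions)
  strata_levels <- if (is.null(strata)) list(pooled = rep(TRUE, nrow(table)))
  else {
    f <- table[[strata]]
    lv <- levels(factor(f))
    stats::setNames(lapply(lv, function(l) f == l), lv)
  }
  res <- list()
  for (sname in names(strata_levels)) {
    rows <- which(strata_levels[[sname]])
    sub <- table[rows, , drop = FALSE]
    if (length(unique(sub$y)) < 2L) next
    ctx_vars <- grep("^ctx_", variables, value = TRUE)
    rhs <- paste(variables, collapse = " + ")
    if (interactions == "pairwise_context" && length(ctx_vars) >= 2L) {
      rhs <- paste(rhs, "+",
                   paste0("(", paste(ctx_vars, collapse = " + "), ")^2"))
    }
    mm <- stats::model.matrix(stats::as.formula(paste("y ~", rhs)),
                              data = sub)
    assign_map <- attr(mm, "assign")
    term_labels <- attr(stats::terms(stats::as.formula(paste("y ~", rhs)),
                                     data = sub), "term.labels")
    X <- mm[, -1L, drop = FALSE]
    asg <- assign_map[-1L]
    y <- sub$y
    full <- fit_penalized_logistic(X, y, prior = prior)
    null_fit <- fit_penalized_logistic(X[, 0, drop = FALSE], y, prior = prior)
    r2_full <- mcfadden_r2(full, null_fit)
    for (v in drop) {
      drop_terms <- which(term_labels == v |
                            grepl(paste0("(^|:)", v, "($|:)"), term_labels))
      cols <- which(asg %in% drop_terms)
      if (length(cols) == 0L) {
        res[[length(res) + 1L]] <- data.frame(
          stratum = sname, variable = v, lrt = 0, df = 0L, p = 1,
          coef_sign = NA_integer_, pseudo_r2_full = r2_full,
          delta_pseudo_r2_pct = 0, stringsAsFactors = FALSE)
        next
      }
      red <- fit_penalized_logistic(X[, -cols, drop = FALSE], y,
                                    prior = prior)
      stat <- red$deviance - full$deviance
      if (stat < 0) {
        if (stat < -1e-3) warning(sprintf(
          "negative LRT (%.3g) for %s in %s clamped to 0", stat, v, sname))
        stat <- 0
      }
      dfree <- length(cols)
      r2_red <- mcfadden_r2(red, null_fit)
      csign <- if (dfree == 1L) {
        as.integer(sign(full$coefficients[colnames(X)[cols]]))
      } else NA_integer_
      res[[length(res) + 1L]] <- data.frame(
        stratum = sname, variable = v, lrt = stat, df = dfree,
        p = pchisq(stat, dfree, lower.tail = FALSE),
        coef_sign = csign, pseudo_r2_full = r2_full,
        delta_pseudo_r2_pct = 100 * max(r2_full - r2_red, 0) /
          max(r2_full, .Machine$double.eps),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (sname in unique(out$stratum)) {
    i <- out$stratum == sname
    out$p_adj[i] <- p.adjust(out$p[i], method = "BH")
  }
  out <- out[, c("stratum", "variable", "lrt", "df", "p", "p_adj",
                 "coef_sign", "pseudo_r2_full", "delta_pseudo_r2_pct")]
  class(out) <- c("scan_result", "data.frame")
  out
}
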