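# Simple mediation with covariates (single mediator):
#   M1:  b ~ a + covariates        -> alpha      (path a -> b)
#   M2:  c ~ a + b + covariates    -> tau' (direct a -> c), beta_b (b -> c)
#   indirect = alpha * beta_b;  total = tau' + indirect, which equals the
#   coefficient of a in the auxiliary model c ~ a + covariates exactly.
# Predictor, mediator and covariates are mean-centered before fitting
# (multicollinearity guard; slopes and all effects are unchanged by
# centering).  Standard errors use the ML (/n) residual variance; the
# indirect-effect SE is the first-order Sobel product-of-coefficients
# delta method.  Percentile-bootstrap CIs (case resampling) are the
# inferential authority.

EFFECT_LABELS <- c("indirect", "a_to_b", "b_to_c", "direct", "total")

# Unpivot .lm.fit coefficients into design-column order.
lmfit_coef <- function(fit) {
  co <- numeric(length(fit$coefficients))
  co[fit$pivot] <- fit$coefficients
  co
}

# Five effects (indirect, a_to_b, b_to_c, direct, total) from centered
# design matrices; ja/jb are the column positions of the predictor in X1/X2
# and of the mediator in X2.
five_effects <- function(X1, X2, mvec, yvec, ja1, ja2, jb2) {
  f1 <- .lm.fit(X1, mvec)
  f2 <- .lm.fit(X2, yvec)
  if (f1$rank < ncol(X1) || f2$rank < ncol(X2)) return(NULL)
  c1 <- lmfit_coef(f1)
  c2 <- lmfit_coef(f2)
  alpha <- c1[ja1]
  tau_p <- c2[ja2]
  beta_b <- c2[jb2]
  ind <- alpha * beta_b
  c(ind, alpha, beta_b, tau_p, tau_p + ind)
}

#' Simple mediation analysis with covariates and percentile-bootstrap CIs
#'
#' Fits the two linear models of a single-mediator path model — mediator on
#' predictor plus covariates, and outcome on predictor, mediator and
#' covariates — by least squares (maximum likelihood under normal errors)
#' and decomposes the predictor's association with the outcome into five
#' effects: `indirect` (a->b->c, the product of the component paths),
#' `a_to_b`, `b_to_c`, `direct` (a->c holding the mediator fixed) and
#' `total` (direct + indirect). Predictor, mediator and covariates are
#' mean-centered before fitting. Standard errors use the ML (/n) residual
#' variance; the indirect effect's SE is the Sobel first-order delta-method
#' value; z = estimate/SE with two-sided normal p-values. Confidence
#' intervals are empirical percentiles over case-resampled bootstrap
#' replicates and are the preferred basis for inference on the indirect
#' effect. Betas are completely standardized effect sizes.
#'
#' Incomplete cases (any model variable missing) are dropped listwise before
#' centering; the rows used are recorded in `n_used`.
#'
#' @param data Data frame containing all model variables.
#' @param outcome,predictor,mediator Column names (character scalars) of the
#'   outcome (c), predictor (a) and mediator (b).
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "duration")`); may be empty.
#' @param n_boot Number of bootstrap resamples for the percentile CIs
#'   (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed making the bootstrap reproducible; `NULL` leaves
#'   the RNG state untouched.
#' @param var_type `"ml"` (default) or `"unbiased"` residual-variance
#'   divisor for the standard errors (see [ols_ml()]).
#' @param boot_retry Maximum redraws of a degenerate (collinear) resample
#'   before failing (default 100).
#' @return An object of class `"mediation"`: a list with `effects` (a
#'   data.frame with rows `indirect`, `a_to_b`, `b_to_c`, `direct`, `total`
#'   and columns `estimate`, `se`, `ci_low`, `ci_high`, `beta`, `z`, `p`),
#'   `n_used`, `n_boot`, `ci_level`, `boot_seed`, `boot_retries`, `boot`
#'   (the replicate-by-effect matrix), `variables`, and `models` (the two
#'   [ols_ml()] fits).
#' @seealso [print.mediation()], [summary.mediation()], [coef.mediation()],
#'   [confint.mediation()], [plot.mediation()]
#' @export
#' @examples
#' set.seed(1)
#' n <- 200
#' d <- data.frame(age = rnorm(n, 70, 9), duration = rexp(n))
#' d$a <- rnorm(n, 1.55, 0.37)
#' d$b <- 10 - 10 * d$a + rnorm(n, 0, 8)
#' d$c <- -0.4 * d$a + 0.01 * d$b + rnorm(n, 0, 0.5)
#' fit <- mediate(d, outcome = "c", predictor = "a", mediator = "b",
#'                n_boot = 200, seed = 7)
#' fit
mediate <- function(data, outcome, predictor, mediator,
                    covariates = c("age", "duration"),
                    n_boot = 1000, ci_level = 0.95, seed = NULL,
                    var_type = c("ml", "unbiased"), boot_retry = 100) {
  var_type <- match.arg(var_type)
  vars <- c(predictor, mediator, outcome, covariates)
  if (anyDuplicated(vars)) {
    stop("predictor, mediator, outcome and covariates must be distinct",
         call. = FALSE)
  }
  missing_c <- setdiff(vars, names(data))
  if (length(missing_c) > 0L) {
    stop("data is missing column(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be at least 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be in (0, 1)", call. = FALSE)
  }

  d <- data[vars]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 10L) stop("fewer than 10 complete cases", call. = FALSE)
  for (v in vars) {
    if (stats::sd(d[[v]]) == 0) {
      stop("variable '", v, "' has zero variance", call. = FALSE)
    }
  }

  # mean-center predictor, mediator and covariates (not the outcome)
  for (v in c(predictor, mediator, covariates)) d[[v]] <- d[[v]] - mean(d[[v]])

  mvec <- d[[mediator]]
  yvec <- d[[outcome]]
  X1 <- cbind("(Intercept)" = 1, as.matrix(d[c(predictor, covariates)]))
  X2 <- cbind("(Intercept)" = 1,
              as.matrix(d[c(predictor, mediator, covariates)]))
  ja1 <- 2L; ja2 <- 2L; jb2 <- 3L

  m1 <- ols_ml(X1, mvec, var_type)
  m2 <- ols_ml(X2, yvec, var_type)
  m3 <- ols_ml(X1, yvec, var_type)   # auxiliary: total effect and its SE

  alpha <- unname(m1$coefficients[predictor])
  se_alpha <- unname(m1$se[predictor])
  tau_p <- unname(m2$coefficients[predictor])
  se_tau <- unname(m2$se[predictor])
  beta_b <- unname(m2$coefficients[mediator])
  se_betab <- unname(m2$se[mediator])
  indirect <- alpha * beta_b
  se_ind <- sqrt(beta_b^2 * se_alpha^2 + alpha^2 * se_betab^2)  # Sobel
  total <- tau_p + indirect
  se_total <- unname(m3$se[predictor])

  sa <- stats::sd(d[[predictor]])
  sb <- stats::sd(mvec)
  sc <- stats::sd(yvec)
  beta_ab <- alpha * sa / sb
  beta_bc <- beta_b * sb / sc
  beta_dir <- tau_p * sa / sc
  beta_ind <- beta_ab * beta_bc
  beta_tot <- beta_dir + beta_ind

  est <- c(indirect, alpha, beta_b, tau_p, total)
  se <- c(se_ind, se_alpha, se_betab, se_tau, se_total)
  beta <- c(beta_ind, beta_ab, beta_bc, beta_dir, beta_tot)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))

  bt <- boot_mediation(X1, X2, mvec, yvec, ja1, ja2, jb2,
                       n_boot = n_boot, seed = seed, boot_retry = boot_retry)
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  ci <- apply(bt$boot, 2L, stats::quantile, probs = probs, names = FALSE)

  effects <- data.frame(
    estimate = est, se = se, ci_low = ci[1L, ], ci_high = ci[2L, ],
    beta = beta, z = z, p = p,
    row.names = EFFECT_LABELS
  )
  structure(list(
    effects = effects,
    n_used = n,
    n_boot = n_boot,
    ci_level = ci_level,
    boot_seed = seed,
    boot_retries = bt$retries,
    boot = bt$boot,
    variables = list(outcome = outcome, predictor = predictor,
                     mediator = mediator, covariates = covariates),
    models = list(mediator_model = m1, outcome_model = m2),
    var_type = var_type,
    call = match.call()
  ), class = "mediation")
}

# Case-resampling bootstrap of the five effects.  One seeded RNG stream;
# a degenerate (rank-deficient) resample is redrawn up to boot_retry times.
boot_mediation <- function(X1, X2, mvec, yvec, ja1, ja2, jb2,
                           n_boot, seed, boot_retry) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  n <- nrow(X1)
  boot <- matrix(NA_real_, n_boot, 5L,
                 dimnames = list(NULL, EFFECT_LABELS))
  retries <- 0L
  for (b in seq_len(n_boot)) {
    attempt <- 0L
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      eff <- five_effects(X1[idx, , drop = FALSE], X2[idx, , drop = FALSE],
                          mvec[idx], yvec[idx], ja1, ja2, jb2)
      if (!is.null(eff) && all(is.finite(eff))) break
      attempt <- attempt + 1L
      retries <- retries + 1L
      if (attempt > boot_retry) {
        stop("bootstrap resample degenerate after ", boot_retry,
             " redraws", call. = FALSE)
      }
    }
    boot[b, ] <- eff
  }
  if (retries > 0L) {
    message("bootstrap: ", retries, " degenerate resample(s) redrawn")
  }
  list(boot = boot, retries = retries)
}

#' @export
print.mediation <- function(x, digits = 3, ...) {
  v <- x$variables
  cat("Mediation analysis (n = ", x$n_used, ")\n", sep = "")
  cat("  predictor (a): ", v$predictor,
      "   mediator (b): ", v$mediator,
      "   outcome (c): ", v$outcome, "\n", sep = "")
  if (length(v$covariates) > 0L) {
    cat("  covariates: ", paste(v$covariates, collapse = ", "),
        " (mean-centered)\n", sep = "")
  }
  cat("  percentile bootstrap CIs, ", x$n_boot, " resamples, level ",
      x$ci_level, "\n\n", sep = "")
  eff <- x$effects
  path <- c(indirect = "a -> b -> c", a_to_b = "a -> b", b_to_c = "b -> c",
            direct = "a -> c", total = "indirect + direct")
  tab <- cbind(path = path[rownames(eff)],
               format(round(eff, digits), nsmall = digits))
  print(tab, quote = FALSE, right = TRUE, ...)
  invisible(x)
}

#' @export
summary.mediation <- function(object, ...) {
  structure(list(fit = object), class = "summary.mediation")
}

#' @export
print.summary.mediation <- function(x, digits = 3, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  m1 <- fit$models$mediator_model
  m2 <- fit$models$outcome_model
  cat("\nMediator model (b ~ a + covariates):\n")
  print(round(cbind(estimate = m1$coefficients, se = m1$se), digits))
  cat("\nOutcome model (c ~ a + b + covariates):\n")
  print(round(cbind(estimate = m2$coefficients, se = m2$se), digits))
  cat("\nResidual variance (", fit$var_type, "): mediator model ",
      signif(m1$sigma2, digits + 1), ", outcome model ",
      signif(m2$sigma2, digits + 1), "\n", sep = "")
  if (fit$boot_retries > 0L) {
    cat("Bootstrap redraws of degenerate resamples: ",
        fit$boot_retries, "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.mediation <- function(object, ...) {
  stats::setNames(object$effects$estimate, rownames(object$effects))
}

#' Percentile-bootstrap confidence intervals of the mediation effects
#'
#' @param object A `"mediation"` fit.
#' @param parm Effect labels to keep (default all five).
#' @param level Confidence level; defaults to the level used at fit time.
#'   Any other level is recomputed from the stored bootstrap replicates.
#' @param ... Unused.
#' @return Matrix with one row per effect and columns `ci_low`, `ci_high`.
#' @export
confint.mediation <- function(object, parm = NULL, level = NULL, ...) {
  if (is.null(level) || isTRUE(level == object$ci_level)) {
    ci <- as.matrix(object$effects[, c("ci_low", "ci_high")])
  } else {
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- t(apply(object$boot, 2L, stats::quantile, probs = probs,
                  names = FALSE))
    dimnames(ci) <- list(rownames(object$effects), c("ci_low", "ci_high"))
  }
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Bootstrap distributions of the mediation effects
#'
#' Histograms of the bootstrap replicates of the five effects, with the point
#' estimate and the percentile CI marked.
#'
#' @param x A `"mediation"` fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.mediation <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (lab in rownames(x$effects)) {
    graphics::hist(x$boot[, lab], main = lab, xlab = "estimate",
                   col = "grey85", border = "white", ...)
    graphics::abline(v = x$effects[lab, "estimate"], lwd = 2)
    graphics::abline(v = unlist(x$effects[lab, c("ci_low", "ci_high")]),
                     lty = 2)
  }
  invisible(x)
}
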