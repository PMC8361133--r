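# Independent oracles and fixture builders used across the suite.

# Normal-equations least squares (brute force), independent of the QR path.
ne_ols <- function(X, y) {
  xtx <- t(X) %*% X
  solve(xtx, t(X) %*% y)
}

# ML standard errors from the normal-equations route.
ne_ols_se <- function(X, y) {
  beta <- ne_ols(X, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / nrow(X)
  unname(sqrt(diag(sigma2 * solve(t(X) %*% X))))
}

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, probabilities from the choose() identity (not dhyper).
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(c1, r1)
  pr <- vapply(ks, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- pr[ks == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Two-sided exact Mann-Whitney p by brute-force enumeration of all
# assignments of the pooled observations to group 1, computing the U
# statistic from scratch by pairwise comparison counts (not midranks).
enum_mwu_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  nn <- length(pool)
  u_pairwise <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- n1 * (nn - n1) / 2
  obs <- abs(u_pairwise(x, y) - mu)
  sel <- utils::combn(nn, n1)
  us <- apply(sel, 2, function(i) u_pairwise(pool[i], pool[-i]))
  mean(abs(us - mu) >= obs - 1e-9)
}

# Long-format tilt series from per-phase named vectors, e.g.
# make_tilt(supine = list("5" = c(120, 70), ...), tilted = list(...)).
make_tilt <- function(supine, tilted, patient_id = "p1") {
  row <- function(phase, tm, bp) {
    data.frame(patient_id = patient_id, phase = phase,
               time_min = as.numeric(tm), sbp = bp[1], dbp = bp[2],
               stringsAsFactors = FALSE)
  }
  sup <- do.call(rbind, Map(row, "supine", names(supine), supine))
  til <- do.call(rbind, Map(row, "tilt", names(tilted), tilted))
  rbind(sup, til)
}

# Random valid tilt series for property tests.
random_tilt <- function(patient_id, full_pools = TRUE) {
  sup_t <- c(0, 5, 10, 15, 20)
  til_t <- if (full_pools) c(0, 3, 5, 10, 15, 20) else {
    c(sample(c(3, 5), 1), sample(c(10, 15, 20), sample(0:3, 1)))
  }
  mk <- function(phase, tms) {
    sbp <- sample(90:180, length(tms), replace = TRUE)
    dbp <- sbp - sample(20:60, length(tms), replace = TRUE)
    data.frame(patient_id = patient_id, phase = phase, time_min = tms,
               sbp = sbp, dbp = pmax(dbp, 10), stringsAsFactors = FALSE)
  }
  rbind(mk("supine", sup_t), mk("tilt", til_t))
}

# Small cohort with known mediation structure for mediate() tests.
mediation_testdata <- function(n = 300, alpha = -10, beta_b = 0.01,
                               tau = -0.4, seed = 99, sigma_b = 8,
                               sigma_c = 0.5) {
  set.seed(seed)
  d <- data.frame(age = rnorm(n, 70, 9), duration = rexp(n, 1))
  d$a <- rnorm(n, 1.55, 0.37)
  d$b <- 10 + alpha * d$a + 0.2 * d$age + 0.5 * d$duration +
    rnorm(n, 0, sigma_b)
  d$c <- tau * d$a + beta_b * d$b + 0.01 * d$age + 0.05 * d$duration +
    rnorm(n, 0, sigma_c)
  d
}
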