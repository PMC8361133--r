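# Two-group comparison statistics for cohort description tables: pooled and
# Welch two-sample t, Mann-Whitney U (exact for small samples, tie-corrected
# normal approximation otherwise), Fisher's exact test, and n (%) / mean (SD)
# / median (IQR) summaries.

as_group_summary <- function(x, label) {
  if (is.list(x) || (!is.null(names(x)) && all(c("n", "mean", "sd") %in% names(x)))) {
    s <- as.list(x)
    s <- list(n = as.numeric(s$n), mean = as.numeric(s$mean),
              sd = as.numeric(s$sd))
  } else {
    x <- x[!is.na(x)]
    s <- list(n = length(x), mean = mean(x), sd = stats::sd(x))
  }
  if (s$n < 2) stop("group ", label, " needs at least 2 observations",
                    call. = FALSE)
  s
}

group_comparison <- function(method, statistic, df = NA_real_, p, summaries) {
  structure(list(method = method, statistic = statistic, df = df,
                 p.value = p, summaries = summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(x$method, ": ", names(x$statistic), " = ",
      format(round(x$statistic, digits)), sep = "")
  if (!is.na(x$df)) cat(", df =", format(round(x$df, 2)))
  cat(", p =", format.pval(x$p.value, digits = digits), "\n")
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Classical independent-samples t-test with the pooled variance estimate and
#' `n1 + n2 - 2` degrees of freedom. Each group may be given either as a
#' vector of raw values or as a `c(n = , mean = , sd = )` summary (or a list
#' with those elements), so printed summary statistics can be re-tested.
#'
#' @param x,y Raw values or `(n, mean, sd)` summaries for the two groups.
#' @return A `"group_comparison"` with `statistic` (t), `df`, `p.value` and
#'   the two group summaries.
#' @export
#' @examples
#' pooled_t(c(n = 43, mean = -4.39, sd = 7.29),
#'          c(n = 26, mean = -5.65, sd = 5.99))
pooled_t <- function(x, y) {
  s1 <- as_group_summary(x, 1)
  s2 <- as_group_summary(y, 2)
  df <- s1$n + s2$n - 2
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / df
  tstat <- (s1$mean - s2$mean) / sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  p <- 2 * stats::pt(-abs(tstat), df)
  group_comparison("Pooled two-sample t-test", c(t = tstat), df, p,
                   list(s1, s2))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' Accepts raw values or `(n, mean, sd)` summaries like [pooled_t()].
#'
#' @inheritParams pooled_t
#' @return A `"group_comparison"`.
#' @export
welch_t <- function(x, y) {
  s1 <- as_group_summary(x, 1)
  s2 <- as_group_summary(y, 2)
  v1 <- s1$sd^2 / s1$n
  v2 <- s2$sd^2 / s2$n
  tstat <- (s1$mean - s2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  group_comparison("Welch two-sample t-test", c(t = tstat), df, p,
                   list(s1, s2))
}

# U statistic for group 1 from midranks.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the U statistic computed from midranks. For
#' `n1 + n2 <= 12` (or `exact = TRUE`) the two-sided p-value is obtained by
#' complete enumeration of all group-label assignments, which remains valid
#' under ties; otherwise a normal approximation with tie-corrected variance
#' and (optionally) continuity correction is used. The permutation
#' distribution of U is symmetric about `n1 * n2 / 2`, so the two-sided p is
#' `P(|U - n1 n2 / 2| >= |observed|)`.
#'
#' @param x,y Numeric vectors of raw values (each non-empty).
#' @param exact Force or forbid exact enumeration; default `NULL` enumerates
#'   when `n1 + n2 <= 12`.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return A `"group_comparison"` with `statistic` (U for the first group).
#' @export
mann_whitney_u <- function(x, y, exact = NULL, continuity = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(exact)) exact <- (n1 + n2) <= 12
  u <- u_statistic(x, y)
  mu <- n1 * n2 / 2
  if (exact) {
    pool <- c(x, y)
    sel <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(u - mu)
    us <- apply(sel, 2L, function(i) u_statistic(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= dev_obs - 1e-9)
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    nn <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      # all values tied: no evidence either way
      p <- 1
      z <- 0
    } else {
      dev <- u - mu
      cc <- if (continuity) sign(dev) * 0.5 else 0
      z <- (dev - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U test (normal approximation)"
  }
  med_iqr <- function(v) list(n = length(v), median = stats::median(v),
                              iqr = stats::IQR(v))
  group_comparison(method, c(U = u), NA_real_, p,
                   list(med_iqr(x), med_iqr(y)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-at-most-observed rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (within a relative
#' tolerance factor of 1e-12 to absorb floating-point ties).
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return A `"group_comparison"` with the observed table probability as the
#'   statistic.
#' @export
#' @examples
#' fisher_exact(matrix(c(7, 45, 62, 113), 2))
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins must be positive", call. = FALSE)
  }
  m <- sum(table[1L, ])          # row-1 total (white balls)
  n <- sum(table[2L, ])          # row-2 total (black balls)
  k <- sum(table[, 1L])          # column-1 total (drawn)
  support <- max(0L, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table[1L, 1L], m, n, k)
  p <- sum(pr[pr <= p_obs * (1 + 1e-12)])
  p <- min(1, p)
  group_comparison("Fisher's exact test", c(p_table = p_obs), NA_real_, p,
                   list(table = table))
}

#' Shapiro-Wilk normality helper
#'
#' Thin wrapper over [stats::shapiro.test()], provided so callers can decide
#' between t-based and rank-based comparisons. It is never invoked
#' automatically by [compare_groups()].
#'
#' @param x Numeric vector.
#' @return The `htest` from [stats::shapiro.test()].
#' @export
normality_check <- function(x) stats::shapiro.test(x[!is.na(x)])

#' Count and percentage
#'
#' @param k Count in the category.
#' @param n Group size.
#' @param digits Decimals for the percentage (default 1).
#' @return Numeric percentage, rounded.
#' @export
#' @examples
#' count_percent(158, 227) # 69.6
count_percent <- function(k, n, digits = 1) {
  if (any(n <= 0)) stop("group size must be positive", call. = FALSE)
  round(100 * k / n, digits)
}

fmt_mean_sd <- function(v, digits = 1) {
  paste0(round(mean(v, na.rm = TRUE), digits), " (",
         round(stats::sd(v, na.rm = TRUE), digits), ")")
}

fmt_median_iqr <- function(v, digits = 1) {
  paste0(round(stats::median(v, na.rm = TRUE), digits), " (",
         round(stats::IQR(v, na.rm = TRUE), digits), ")")
}

fmt_n_pct <- function(flag) {
  k <- sum(flag, na.rm = TRUE)
  n <- sum(!is.na(flag))
  paste0(k, " (", count_percent(k, n), ")")
}

#' Two-group cohort description table
#'
#' Builds a baseline-characteristics style table: one row per variable with
#' a per-group summary, the test used, its statistic and the two-sided
#' p-value. Continuous variables use the pooled t, Welch t or Mann-Whitney U
#' test (summarized as mean (SD) for the t-tests, median (IQR) for the rank
#' test); logical variables use Fisher's exact test on the 2x2 table and are
#' summarized as n (%). The test choice is the caller's: supply `tests` as a
#' named character vector (`"pooled"`, `"welch"`, `"mw"`, `"fisher"`);
#' unnamed variables default to `"pooled"` for numeric and `"fisher"` for
#' logical columns.
#'
#' @param cohort Data frame.
#' @param group Name of a two-level grouping column.
#' @param vars Character vector of variable columns to compare.
#' @param tests Optional named character vector mapping variables to tests.
#' @return Data frame with columns `variable`, one summary column per group
#'   level, `test`, `statistic`, `df`, `p`.
#' @export
compare_groups <- function(cohort, group, vars, tests = NULL) {
  g <- cohort[[group]]
  if (is.null(g)) stop("grouping column '", group, "' not found", call. = FALSE)
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2L) stop("grouping column must have exactly 2 levels",
                              call. = FALSE)
  rows <- lapply(vars, function(v) {
    val <- cohort[[v]]
    if (is.null(val)) stop("variable '", v, "' not found", call. = FALSE)
    test <- if (!is.null(tests) && v %in% names(tests)) tests[[v]]
            else if (is.logical(val)) "fisher" else "pooled"
    v1 <- val[g == lev[1L] & !is.na(g)]
    v2 <- val[g == lev[2L] & !is.na(g)]
    res <- switch(test,
      pooled = pooled_t(v1, v2),
      welch = welch_t(v1, v2),
      mw = mann_whitney_u(v1, v2),
      fisher = fisher_exact(rbind(
        c(sum(v1, na.rm = TRUE), sum(!v1, na.rm = TRUE)),
        c(sum(v2, na.rm = TRUE), sum(!v2, na.rm = TRUE)))),
      stop("unknown test '", test, "' for variable '", v, "'", call. = FALSE)
    )
    summ <- switch(test,
      pooled = ,
      welch = c(fmt_mean_sd(v1), fmt_mean_sd(v2)),
      mw = c(fmt_median_iqr(v1), fmt_median_iqr(v2)),
      fisher = c(fmt_n_pct(v1), fmt_n_pct(v2))
    )
    data.frame(variable = v, g1 = summ[1L], g2 = summ[2L], test = test,
               statistic = unname(res$statistic), df = res$df,
               p = res$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0(group, "=", lev)
  rownames(out) <- NULL
  out
}
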