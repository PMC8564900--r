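#' Group summary: mean, SD, SEM
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and
#' standard error of the mean, the summary style used for all reported
#' measurements ("mean +/- SD (n)").
#'
#' @param values numeric measurements (nm); `n >= 1`.
#' @param label group label.
#' @return one-row data.frame: `group`, `n`, `mean`, `sd`, `sem`,
#'   `flags` (`"n1"` when n = 1 and SD is defined as 0).
#' @export
summarize_group <- function(values, label = "group") {
  if (length(values) == 0) stop("empty input: need at least one value")
  n <- length(values)
  s <- if (n == 1) 0 else stats::sd(values)
  data.frame(group = label, n = n, mean = mean(values), sd = s,
             sem = s / sqrt(n), flags = if (n == 1) "n1" else "",
             stringsAsFactors = FALSE)
}

#' @rdname summarize_group
#' @param summary a row from `summarize_group`.
#' @param unit unit string appended to the report.
#' @param digits rounding for the report (default 0: nearest nanometer,
#'   the rounding applied at reporting time only).
#' @return character, e.g. `"87 ± 14 nm (n = 45)"`.
#' @export
format_summary <- function(summary, unit = "nm", digits = 0) {
  sprintf("%s ± %s %s (n = %d)",
          formatC(round(summary$mean, digits), format = "fg"),
          formatC(round(summary$sd, digits), format = "fg"),
          unit, summary$n)
}

#' Student's two-tailed t test (pooled variance)
#'
#' Two-sample equal-variance t test with a two-sided p value, the test
#' applied to two-way comparisons between antigens within one genotype.
#' The equal-variance (Student) form is used rather than Welch.
#'
#' @param a,b numeric vectors, each `n >= 2`.
#' @return one-row data.frame: `test`, `statistic`, `df`, `p`, `flags`
#'   (`"zero_variance"` when both groups are constant and equal, for
#'   which p is defined as 1).
#' @export
t_test_two_tailed <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    if (mean(a) == mean(b))
      return(data.frame(test = "t_two_tailed", statistic = 0, df = df,
                        p = 1, flags = "zero_variance"))
    return(data.frame(test = "t_two_tailed", statistic = Inf * sign(mean(a) - mean(b)),
                      df = df, p = 0, flags = "zero_variance"))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  data.frame(test = "t_two_tailed", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value, flags = "")
}

# Two-sided Dunnett adjustment: P(max_i |T_i| >= |t|) under the
# many-to-one multivariate t with correlation rho, by fixed-seed Monte
# Carlo integration (abs. tolerance ~5e-4).
.dunnett_p_adjust <- function(tstat, df, rho) {
  if (!is.finite(tstat)) return(if (tstat == 0) 1 else 0)
  m <- nrow(rho)
  .with_fixed_seed(20210517, function() {
    p <- 1 - mvtnorm::pmvt(lower = rep(-abs(tstat), m),
                           upper = rep(abs(tstat), m),
                           df = df, corr = rho, sigma = NULL,
                           algorithm = mvtnorm::GenzBretz(abseps = 5e-4,
                                                          maxpts = 50000))[1]
    min(max(p, 0), 1)
  })
}

# Evaluate fn() under a fixed RNG seed without disturbing the caller's
# RNG stream (the Dunnett quantile/probability integration is Monte
# Carlo; a fixed internal seed makes adjusted p values reproducible).
.with_fixed_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' One-way ANOVA with Tukey or Dunnett post hoc correction
#'
#' Computes the one-way ANOVA F test across all groups, then adjusted
#' per-comparison p values: Tukey's honest significant difference over
#' all pairs, or Dunnett's many-to-one comparisons against a control
#' group. Dunnett adjusted p values integrate the multivariate t
#' distribution (correlation implied by the shared control,
#' `rho_ij = sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))`) by fixed-seed
#' Monte Carlo to ~1e-3 absolute tolerance.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   `n >= 2`), or a data.frame with columns `value` and `group`.
#' @param method `"tukey"` or `"dunnett"`.
#' @param control control group label (required for Dunnett).
#' @return list with `anova` (one-row data.frame: `F`, `df1`, `df2`,
#'   `p`) and `comparisons` (data.frame: `comparison`, `estimate`,
#'   `statistic`, `p_raw`, `p_adj`).
#' @export
anova_posthoc <- function(groups, method = c("tukey", "dunnett"),
                          control = NULL) {
  method <- match.arg(method)
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_len(k))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (method == "dunnett") {
    if (is.null(control)) stop("Dunnett comparisons require a control label")
    if (!control %in% names(groups))
      stop("control '", control, "' is not a group label")
  }
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  mse <- ss_within / df2
  Fstat <- if (mse > 0) (ss_between / df1) / mse else if (ss_between > 0) Inf else 0
  p_f <- if (is.finite(Fstat)) stats::pf(Fstat, df1, df2, lower.tail = FALSE)
         else 0
  anova_row <- data.frame(F = Fstat, df1 = df1, df2 = df2, p = p_f)

  if (method == "tukey") {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    comp <- do.call(rbind, lapply(pairs, function(pr) {
      i <- pr[1]; j <- pr[2]
      est <- means[j] - means[i]
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      q <- if (se > 0) abs(est) / (se / sqrt(2)) else if (est == 0) 0 else Inf
      tstat <- if (se > 0) est / se else ifelse(est == 0, 0, Inf * sign(est))
      p_raw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
      p_adj <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
      data.frame(comparison = paste(j, "-", i), estimate = unname(est),
                 statistic = unname(tstat), p_raw = unname(p_raw),
                 p_adj = unname(p_adj))
    }))
  } else {
    others <- setdiff(names(groups), control)
    m <- length(others)
    n0 <- ns[control]
    rho <- outer(others, others, function(i, j)
      sqrt((ns[i] * ns[j]) / ((ns[i] + n0) * (ns[j] + n0))))
    diag(rho) <- 1
    comp <- do.call(rbind, lapply(seq_along(others), function(ii) {
      g <- others[ii]
      est <- means[g] - means[control]
      se <- sqrt(mse * (1 / ns[g] + 1 / n0))
      tstat <- if (se > 0) est / se else ifelse(est == 0, 0, Inf * sign(est))
      p_raw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
      p_adj <- .dunnett_p_adjust(tstat, df2, rho)
      p_adj <- min(max(p_adj, p_raw), 1)
      data.frame(comparison = paste(g, "-", control), estimate = unname(est),
                 statistic = unname(tstat), p_raw = unname(p_raw),
                 p_adj = unname(p_adj))
    }))
  }
  rownames(comp) <- NULL
  list(test = if (method == "tukey") "anova_tukey" else "anova_dunnett",
       control = if (method == "dunnett") control else NA_character_,
       anova = anova_row, comparisons = comp)
}

#' Dunnett two-sided critical value
#'
#' Equicoordinate quantile of the many-to-one multivariate t: the value
#' c such that P(max_i |T_i| <= c) = 1 - alpha under the null. Used for
#' family-wise error calibration.
#'
#' @param alpha family-wise error rate.
#' @param ns group sizes, named; `control` names the control group.
#' @param control control group label.
#' @return numeric critical value.
#' @export
dunnett_critical <- function(alpha, ns, control) {
  others <- setdiff(names(ns), control)
  n0 <- ns[control]
  rho <- outer(others, others, function(i, j)
    sqrt((ns[i] * ns[j]) / ((ns[i] + n0) * (ns[j] + n0))))
  diag(rho) <- 1
  df <- sum(ns) - length(ns)
  .with_fixed_seed(20210517, function()
    mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = rho,
                  algorithm = mvtnorm::GenzBretz(abseps = 1e-4,
                                                 maxpts = 100000))$quantile)
}
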