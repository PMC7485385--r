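#' Group summary (mean, SEM, n)
#'
#' Container for a printed group-level summary, the form in which
#' published results usually report their data, so that two-group tests
#' can be reproduced at the desk without raw values.
#'
#' @param label Group label.
#' @param mean Group mean (units of the measured variable).
#' @param sem Standard error of the mean, same units, >= 0.
#' @param n Group size, >= 2 for any variance-based inference.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(label, mean, sem, n) {
  stopifnot(is.finite(mean), is.finite(sem), sem >= 0, n >= 1)
  structure(list(label = label, mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t-test from summary statistics
#'
#' Student's t-test computed from group means, SEMs and sizes. For the
#' default pooled-variance method, per-group variances are recovered as
#' `s_i^2 = sem_i^2 * n_i`, pooled with `df = n_a + n_b - 2`; with equal
#' group sizes the standard error of the difference reduces to
#' `sqrt(sem_a^2 + sem_b^2)`. The Welch option uses that same standard
#' error with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b [group_summary()] objects (or lists with `mean`, `sem`,
#'   `n`).
#' @param method `"pooled"` (Student) or `"welch"`.
#' @return An object of class `ttest_result`: list with `t`, `df`, `p`
#'   (two-sided) and `method`.
#' @export
ttest_from_summary <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  for (g in list(a, b))
    if (is.null(g$mean) || is.null(g$sem) || is.null(g$n))
      stop("summaries need 'mean', 'sem' and 'n'")
  if (a$n < 2 || b$n < 2) stop("summary t-test needs n >= 2 in both groups")
  va <- a$sem^2 * a$n   # per-group sample variance
  vb <- b$sem^2 * b$n
  if (method == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se <- sqrt(a$sem^2 + b$sem^2)
    df <- (a$sem^2 + b$sem^2)^2 /
      (a$sem^4 / (a$n - 1) + b$sem^4 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 method = method),
            class = "ttest_result")
}

#' Two-sample t-test on raw values
#'
#' Thin wrapper over [stats::t.test()] returning the same structure as
#' [ttest_from_summary()]; the two agree to numerical precision when the
#' summary is computed from the same values.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param method `"pooled"` (Student, `var.equal = TRUE`) or `"welch"`.
#' @return A `ttest_result`.
#' @export
ttest_raw <- function(x, y, method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2)
    stop("t-test needs >= 2 values per group")
  ht <- stats::t.test(x, y, var.equal = method == "pooled")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, method = method),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$t, x$df, x$p))
  invisible(x)
}

#' One-way ANOVA with Fisher's protected LSD post hoc
#'
#' Omnibus one-way ANOVA over three or more groups, followed by
#' pairwise Fisher least-significant-difference tests: ordinary t-tests
#' whose standard errors use the ANOVA within-group mean square with its
#' full residual degrees of freedom. "Protected" means the pairwise
#' p-values are only interpreted when the omnibus test is significant;
#' they are reported either way, with a `protected` flag that is FALSE
#' when the omnibus p is at or above `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each
#'   n >= 2; with exactly two groups the omnibus F equals the squared
#'   pooled t statistic and the single LSD pair is that t-test).
#' @param alpha Omnibus significance level used for protection.
#' @return An object of class `anova_lsd`: list with `F`, `df_between`,
#'   `df_within`, `p`, and `posthoc` (data frame `group_a`, `group_b`,
#'   `mean_diff`, `t`, `p`, `protected`).
#' @export
anova_fisher_lsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2)
    stop("ANOVA needs >= 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2")
  value <- unlist(groups, use.names = FALSE)
  label <- factor(rep(names(groups), lengths(groups)),
                  levels = names(groups))
  dfb <- length(groups) - 1L
  dfw <- length(value) - length(groups)
  if (stats::var(value) == 0) {
    # all-constant input: no variance anywhere, nothing to reject
    msw <- 0; F <- 0; omnibus_p <- 1
  } else {
    fit <- stats::aov(value ~ label)
    tab <- stats::anova(fit)
    msw <- tab["Residuals", "Mean Sq"]
    F <- tab["label", "F value"]
    omnibus_p <- tab["label", "Pr(>F)"]
  }
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  posthoc <- do.call(rbind, apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(msw * (1 / ns[[i]] + 1 / ns[[j]]))
    d <- means[[i]] - means[[j]]
    t <- if (se == 0 && d == 0) 0 else d / se
    data.frame(group_a = i, group_b = j, mean_diff = d, t = t,
               p = 2 * stats::pt(-abs(t), dfw),
               stringsAsFactors = FALSE)
  }))
  posthoc$protected <- omnibus_p < alpha
  rownames(posthoc) <- NULL
  structure(list(F = F, df_between = dfb, df_within = dfw,
                 p = omnibus_p, ms_within = msw, posthoc = posthoc,
                 alpha = alpha),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$p < x$alpha) "" else
                sprintf(" (omnibus not significant at %g; LSD unprotected)",
                        x$alpha)))
  print.data.frame(x$posthoc, digits = 4)
  invisible(x)
}
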