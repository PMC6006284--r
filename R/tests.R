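#' Tests for sufficient-cause interaction in a case-control study
#'
#' \code{sc_test()} fits one of four Z-tests for sufficient-cause
#' (mechanistic) interaction between two binary exposures to a 2x2x2
#' case-control table:
#'
#' \describe{
#'   \item{\code{"prism"}}{the prevalence-adjusted PRISM test (the
#'     recommended method).  Log perils are estimated per profile via
#'     Bayes' theorem from the external overall prevalence, and the
#'     contrast \eqn{\log PRISM = \log Peril_{1,1} - \log Peril_{1,0} -
#'     \log Peril_{0,1} + \log Peril_{0,0}} is tested against zero with a
#'     delta-method variance that propagates the two multinomial sampling
#'     errors and (for a finite prevalence source) the binomial error in
#'     \eqn{\hat p}.}
#'   \item{\code{"prism-odds"}}{the rare-disease approximation
#'     \eqn{\log PRISM \approx Odds_{1,1} - Odds_{1,0} - Odds_{0,1} +
#'     Odds_{0,0}}, computed from the pseudo-odds \eqn{\hat q/\hat r}.  No
#'     prevalence is needed: the unknown factor \eqn{p/(1-p)} scales the
#'     statistic and its standard error equally, so the Z statistic is
#'     invariant to it.}
#'   \item{\code{"reri-odds"}}{the additive-interaction contrast
#'     \eqn{RERI = OR_{1,1} - OR_{1,0} - OR_{0,1} + 1} on odds ratios,
#'     with the usual delta-method variance through the log odds ratios.}
#'   \item{\code{"reri-risk"}}{RERI on relative risks, with absolute risks
#'     recovered from the prevalence adjustment:
#'     \eqn{Risk_{x,z} = Odds_{x,z}/(1 + Odds_{x,z})}.}
#' }
#'
#' \code{prism_test()}, \code{odds_prism_test()}, \code{odds_reri_test()}
#' and \code{risk_reri_test()} are thin wrappers fixing \code{method}.
#'
#' @param table A [cc_table()] (or see [read_cc_table()]).
#' @param prevalence A [prevalence()] estimate (or a bare number in (0,1),
#'   then treated as exact).  Required for \code{"prism"} and
#'   \code{"reri-risk"}; ignored with a message otherwise.
#' @param method Which test to run; see Details.
#' @param alpha Significance level in (0,1) used for the reported
#'   confidence interval and by [rejection_rate_experiment()].
#' @param alternative Direction of the test: \code{"two.sided"} (default;
#'   interaction declared when the contrast differs from zero),
#'   \code{"greater"} (synergy) or \code{"less"} (antagonism).
#' @param correction Add 0.5 to all eight cells before estimation
#'   (off by default).
#' @return An object of class \code{"sc_test"} with components
#'   \code{estimate}, \code{variance}, \code{se}, \code{statistic} (the Z
#'   value), \code{p.value}, \code{conf.int} (Wald, with
#'   \code{attr(, "conf.level")}), \code{method}, \code{alternative},
#'   \code{alpha}, \code{perils} (a \code{peril_set}, for the
#'   prevalence-based methods), \code{table} and \code{prevalence}.
#'   Supports \code{print()}, \code{summary()}, \code{coef()},
#'   \code{confint()} and \code{simulate()} (parametric-bootstrap draws of
#'   the statistic).
#' @examples
#' ex <- hypertension_example()
#' fit <- prism_test(ex$table, ex$prevalence)
#' fit                      # logPRISM = 0.121, 95% CI (-0.214, 0.456)
#' coef(fit)
#' confint(fit, level = 0.9)
#' odds_reri_test(ex$table)
#' @export
sc_test <- function(table, prevalence = NULL,
                    method = c("prism", "prism-odds", "reri-odds", "reri-risk"),
                    alpha = 0.05,
                    alternative = c("two.sided", "greater", "less"),
                    correction = FALSE) {
  table <- .as_cc_table(table)
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  }
  prev <- NULL
  if (.needs_prevalence(method)) {
    if (is.null(prevalence)) {
      stop(sprintf("method '%s' needs an overall disease prevalence; see prevalence()",
                   method), call. = FALSE)
    }
    prev <- .as_prevalence(prevalence)
  } else if (!is.null(prevalence)) {
    message(sprintf("method '%s' does not use the prevalence; ignoring it", method))
  }

  core <- .test_core(method, table$cases, table$controls,
                     p = if (is.null(prev)) NA_real_ else prev$p,
                     npop = if (is.null(prev)) Inf else prev$n,
                     correction = correction)
  se <- sqrt(core$variance)
  z <- if (se > 0) core$estimate / se else 0
  p.value <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z)
  )
  ci <- switch(alternative,
    two.sided = core$estimate + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se,
    greater = c(core$estimate - stats::qnorm(1 - alpha) * se, Inf),
    less = c(-Inf, core$estimate + stats::qnorm(1 - alpha) * se)
  )
  attr(ci, "conf.level") <- 1 - alpha

  perils <- if (.needs_prevalence(method)) {
    log_perils(table, prev, correction)
  }
  structure(
    list(
      estimate = core$estimate, variance = core$variance, se = se,
      statistic = z, p.value = p.value, conf.int = ci,
      method = method, alternative = alternative, alpha = alpha,
      correction = correction, perils = perils,
      table = table, prevalence = prev
    ),
    class = "sc_test"
  )
}

#' @rdname sc_test
#' @param ... Passed on to \code{sc_test()}.
#' @export
prism_test <- function(table, prevalence, ...) {
  sc_test(table, prevalence, method = "prism", ...)
}

#' @rdname sc_test
#' @export
odds_prism_test <- function(table, ...) {
  sc_test(table, method = "prism-odds", ...)
}

#' @rdname sc_test
#' @export
odds_reri_test <- function(table, ...) {
  sc_test(table, method = "reri-odds", ...)
}

#' @rdname sc_test
#' @export
risk_reri_test <- function(table, prevalence, ...) {
  sc_test(table, prevalence, method = "reri-risk", ...)
}

.method_title <- function(method) {
  switch(method,
    "prism" = "Prevalence-adjusted PRISM test",
    "prism-odds" = "Odds-scale PRISM test (rare-disease approximation)",
    "reri-odds" = "Odds-scale RERI test",
    "reri-risk" = "Prevalence-adjusted risk-scale RERI test"
  )
}

.stat_name <- function(method) {
  switch(method,
    "prism" = "logPRISM",
    "prism-odds" = "odds contrast",
    "reri-odds" = "RERI (odds-ratio scale)",
    "reri-risk" = "RERI (risk scale)"
  )
}

#' @export
print.sc_test <- function(x, digits = 4, ...) {
  cat(.method_title(x$method), "\n\n")
  cat(sprintf("%s = %.*g, SE = %.*g\n",
              .stat_name(x$method), digits, x$estimate, digits, x$se))
  lvl <- attr(x$conf.int, "conf.level")
  cat(sprintf("%g%% CI: (%.*g, %.*g)\n", 100 * lvl,
              digits, x$conf.int[1], digits, x$conf.int[2]))
  cat(sprintf("Z = %.*g, p-value = %.*g (%s)\n",
              digits, x$statistic, digits, x$p.value, x$alternative))
  if (!is.null(x$prevalence)) {
    print(x$prevalence)
  }
  invisible(x)
}

#' @export
summary.sc_test <- function(object, ...) {
  structure(object, class = c("summary.sc_test", "sc_test"))
}

#' @export
print.summary.sc_test <- function(x, digits = 4, ...) {
  NextMethod()
  cat("\n")
  print(x$table)
  if (!is.null(x$perils)) {
    cat("\n")
    print(x$perils, digits = digits)
  }
  invisible(x)
}

#' @export
coef.sc_test <- function(object, ...) {
  stats::setNames(object$estimate, .stat_name(object$method))
}

#' @export
vcov.sc_test <- function(object, ...) {
  matrix(object$variance, 1, 1,
         dimnames = rep(list(.stat_name(object$method)), 2))
}

#' @export
confint.sc_test <- function(object, parm, level = 0.95, ...) {
  se <- object$se
  est <- object$estimate
  ci <- est + c(-1, 1) * stats::qnorm(1 - (1 - level) / 2) * se
  m <- matrix(ci, 1, 2, dimnames = list(
    .stat_name(object$method),
    sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  ))
  m
}

#' Parametric-bootstrap draws of a fitted interaction statistic
#'
#' Redraws the case and control counts (and, for a finite prevalence
#' source, the prevalence estimate) from the fitted sampling model and
#' recomputes the test statistic, as in [bootstrap_variance()].
#'
#' @param object A fitted [sc_test()].
#' @param nsim Number of bootstrap replicates.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Unused.
#' @return Numeric vector of \code{nsim} statistic values; replicates with
#'   undefined statistics are redrawn (count in \code{attr(, "rejected")}).
#' @export
simulate.sc_test <- function(object, nsim = 1, seed = 1, ...) {
  n1 <- object$table$n_cases
  n0 <- object$table$n_controls
  prev <- object$prevalence
  old <- .set_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  out <- numeric(nsim)
  need <- seq_len(nsim)
  rejected <- 0L
  guard <- 0L
  while (length(need)) {
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("cannot find valid resamples; table too sparse", call. = FALSE)
    }
    b <- length(need)
    case_m <- stats::rmultinom(b, n1, object$table$q_hat)
    control_m <- stats::rmultinom(b, n0, object$table$r_hat)
    if (!is.null(prev) && is.finite(prev$n)) {
      pstar <- stats::rbinom(b, round(prev$n), prev$p) / round(prev$n)
      ok_p <- pstar > 0 & pstar < 1
    } else {
      pstar <- rep(if (is.null(prev)) 0.5 else prev$p, b)
      ok_p <- rep(TRUE, b)
    }
    vals <- .stat_columns(object$method, case_m, control_m, pstar)
    ok <- ok_p & !is.na(vals)
    out[need[ok]] <- vals[ok]
    rejected <- rejected + sum(!ok)
    need <- need[!ok]
  }
  attr(out, "rejected") <- rejected
  out
}
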