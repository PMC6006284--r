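# Monte Carlo rejection-rate experiments (type I error and power).

# One replicate, on bare vectors for speed: draw a study, run the test,
# return the p-value (NA when the statistic is undefined for this method,
# e.g. a zero control cell at small n).
.replicate_pvalue <- function(method, d, n_cases, n_controls, p_true,
                              vital_pop, alternative) {
  cases <- drop(stats::rmultinom(1, n_cases, d$cases))
  controls <- drop(stats::rmultinom(1, n_controls, d$controls))
  redraws <- 0L
  if (is.finite(vital_pop) && .needs_prevalence(method)) {
    repeat {
      dd <- stats::rbinom(1, vital_pop, p_true)
      if (dd > 0 && dd < vital_pop) break
      redraws <- redraws + 1L
      if (redraws > 10000L) stop("'vital_pop' too small to estimate prevalence")
    }
    p_hat <- dd / vital_pop
    npop <- vital_pop
  } else {
    p_hat <- p_true
    npop <- Inf
  }
  core <- tryCatch(
    .test_core(method, cases, controls, p = p_hat, npop = npop),
    error = function(e) NULL
  )
  if (is.null(core) || core$variance <= 0) {
    return(list(p = NA_real_, redraws = redraws))
  }
  z <- core$estimate / sqrt(core$variance)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z)
  )
  list(p = p, redraws = redraws)
}

#' Monte Carlo rejection rate of an interaction test
#'
#' Repeatedly simulates case-control studies from a scenario (see
#' [simulate_study()]), applies the chosen test, and reports the fraction
#' of replicates with \eqn{p < \alpha}.  Under a null scenario
#' (\code{prism = 1}) this estimates the type I error rate; under an
#' alternative it estimates power.
#'
#' A master seed spawns one RNG substream per replicate, so results are
#' reproducible and independent of evaluation order.  Replicates on which
#' the test is undefined (zero cells) are excluded from the denominator
#' and counted in \code{failed_replicates}; more than 20% failures is an
#' error (the scenario is too extreme for that test).
#'
#' @param scenario An [sc_scenario()].
#' @param method Which test to run; as in [sc_test()].
#' @param n_cases,n_controls Study sample sizes per replicate.
#' @param vital_pop Population size behind the vital-statistics prevalence
#'   estimate drawn each replicate (default \code{1e6}); \code{Inf} uses
#'   the true prevalence exactly.
#' @param replicates Number of simulated studies.
#' @param alpha Significance level (default 0.05).
#' @param seed Master integer seed.
#' @param alternative Test direction, as in [sc_test()].
#' @return An object of class \code{"sc_power"}: list with
#'   \code{rejection_rate}, \code{mc_se} (binomial Monte Carlo standard
#'   error), \code{rejections}, \code{replicates},
#'   \code{failed_replicates}, \code{prevalence_redraws}, \code{method},
#'   \code{alpha}, \code{seed}, \code{vital_pop}, \code{n_cases},
#'   \code{n_controls} and the \code{scenario}.
#' @examples
#' sc <- sc_scenario(0.2, rr10 = 3, rr01 = 2, prism = 1)
#' rejection_rate_experiment(sc, "prism", 500, 500, replicates = 200,
#'                           seed = 11)
#' @export
rejection_rate_experiment <- function(scenario,
                                      method = c("prism", "prism-odds",
                                                 "reri-odds", "reri-risk"),
                                      n_cases, n_controls, vital_pop = 1e6,
                                      replicates = 1000, alpha = 0.05,
                                      seed = 1,
                                      alternative = c("two.sided", "greater",
                                                      "less")) {
  if (!inherits(scenario, "sc_scenario")) {
    stop("'scenario' must be an sc_scenario", call. = FALSE)
  }
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  stopifnot(replicates >= 1, n_cases >= 1, n_controls >= 1,
            alpha > 0, alpha <= 1)

  old <- .set_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  sub_seeds <- sample.int(.Machine$integer.max, replicates)

  d <- cell_distributions(scenario)
  p_true <- scenario$prevalence
  rejections <- 0L
  failed <- 0L
  redraws <- 0L
  for (i in seq_len(replicates)) {
    set.seed(sub_seeds[i])
    rep_ <- .replicate_pvalue(method, d, n_cases, n_controls, p_true,
                              vital_pop, alternative)
    redraws <- redraws + rep_$redraws
    if (is.na(rep_$p)) {
      failed <- failed + 1L
    } else if (rep_$p < alpha) {
      rejections <- rejections + 1L
    }
  }
  if (failed > 0.2 * replicates) {
    stop(sprintf(
      "%d of %d replicates failed (zero cells); scenario too extreme for '%s'",
      failed, replicates, method), call. = FALSE)
  }
  used <- replicates - failed
  rate <- rejections / used
  structure(
    list(
      rejection_rate = rate,
      mc_se = sqrt(rate * (1 - rate) / used),
      rejections = rejections, replicates = replicates,
      failed_replicates = failed, prevalence_redraws = redraws,
      method = method, alpha = alpha, alternative = alternative,
      seed = seed, vital_pop = vital_pop,
      n_cases = n_cases, n_controls = n_controls,
      scenario = scenario
    ),
    class = "sc_power"
  )
}

#' @export
print.sc_power <- function(x, digits = 4, ...) {
  cat(sprintf("Monte Carlo rejection rate: %s\n", .method_title(x$method)))
  cat(sprintf(
    "  scenario: prevalence %.4g, true PRISM %.6g; %d cases / %d controls\n",
    x$scenario$prevalence, x$scenario$prism, x$n_cases, x$n_controls))
  cat(sprintf("  rate = %.*g (MC SE %.2g) from %d replicates at alpha = %g\n",
              digits, x$rejection_rate, x$mc_se,
              x$replicates - x$failed_replicates, x$alpha))
  if (x$failed_replicates > 0) {
    cat(sprintf("  %d replicate(s) dropped (test undefined)\n",
                x$failed_replicates))
  }
  invisible(x)
}

#' @export
as.data.frame.sc_power <- function(x, ...) {
  data.frame(
    method = x$method, prevalence = x$scenario$prevalence,
    prism = x$scenario$prism, n_cases = x$n_cases,
    n_controls = x$n_controls, vital_pop = x$vital_pop,
    alpha = x$alpha, replicates = x$replicates,
    failed = x$failed_replicates, rejections = x$rejections,
    rejection_rate = x$rejection_rate, mc_se = x$mc_se, seed = x$seed
  )
}

#' Robustness of a test to an imprecise prevalence estimate
#'
#' Repeats [rejection_rate_experiment()] while varying the size of the
#' sample behind the external prevalence estimate: for each source size
#' \eqn{N}, each replicate draws \eqn{\hat p = D/N} with
#' \eqn{D \sim} Binomial(\eqn{N, p}).  Use \code{Inf} among the sizes for
#' the exactly-known baseline.  Because the same master seed is used for
#' every size, the simulated studies are identical across sizes and only
#' the prevalence noise differs.
#'
#' @inheritParams rejection_rate_experiment
#' @param source_sizes Vector of prevalence source sizes (each \eqn{\ge}
#'   10, or \code{Inf}).
#' @return A list of \code{"sc_power"} objects, one per source size (named
#'   by size), with class \code{"sc_power_grid"}; \code{as.data.frame()}
#'   gives one row per size.
#' @examples
#' sc <- sc_scenario(0.2, rr10 = 3, rr01 = 2, prism = 1.171)
#' grid <- prevalence_sensitivity_experiment(sc, "prism", 500, 500,
#'   source_sizes = c(1000, Inf), replicates = 200, seed = 3)
#' as.data.frame(grid)
#' @export
prevalence_sensitivity_experiment <- function(scenario,
                                              method = c("prism", "prism-odds",
                                                         "reri-odds",
                                                         "reri-risk"),
                                              n_cases, n_controls,
                                              source_sizes,
                                              replicates = 1000, alpha = 0.05,
                                              seed = 1,
                                              alternative = c("two.sided",
                                                              "greater",
                                                              "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!is.numeric(source_sizes) || !length(source_sizes) ||
      any(source_sizes < 10)) {
    stop("'source_sizes' must be numeric, each >= 10 (Inf for exact)",
         call. = FALSE)
  }
  out <- lapply(source_sizes, function(n_src) {
    rejection_rate_experiment(scenario, method, n_cases, n_controls,
                              vital_pop = n_src, replicates = replicates,
                              alpha = alpha, seed = seed,
                              alternative = alternative)
  })
  names(out) <- ifelse(is.finite(source_sizes),
                       format(source_sizes, scientific = FALSE, trim = TRUE),
                       "exact")
  structure(out, class = "sc_power_grid")
}

#' @export
as.data.frame.sc_power_grid <- function(x, ...) {
  df <- do.call(rbind, lapply(unclass(x), as.data.frame))
  df$prevalence_source <- names(x)
  rownames(df) <- NULL
  df
}

#' @export
print.sc_power_grid <- function(x, ...) {
  cat("Prevalence-sensitivity experiment\n")
  df <- as.data.frame(x)
  print(df[, c("prevalence_source", "rejection_rate", "mc_se", "failed")])
  invisible(x)
}
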