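# Simulation scenarios: population truths for Monte Carlo evaluation.
#
# A scenario fixes the joint exposure distribution pi[x,z] and the true
# disease risks Risk[x,z].  Everything else (overall prevalence, relative
# risks, true PRISM, case/control sampling distributions) derives from
# those.  Scenarios are specified the way simulation studies in this
# literature report them: by the marginal relative risks RR10 and RR01, the
# overall disease prevalence, and the true PRISM value, with the baseline
# risk solved numerically to satisfy all four constraints at once.

#' Construct a constrained simulation scenario
#'
#' Builds the population truth for a Monte Carlo experiment from the
#' quantities simulation studies in this literature actually report: the
#' overall disease prevalence, the marginal relative risks of the two
#' exposures, and the true PRISM (peril-ratio) interaction value.  The
#' baseline risk \eqn{Risk_{0,0}} is found by one-dimensional root finding
#' so that, with
#' \deqn{Risk_{1,0} = RR_{1,0} Risk_{0,0}, \quad
#'       Risk_{0,1} = RR_{0,1} Risk_{0,0},}
#' \deqn{Risk_{1,1} = 1 - \frac{1}{PRISM}
#'       \frac{(1-Risk_{1,0})(1-Risk_{0,1})}{1-Risk_{0,0}},}
#' the exposure-weighted mean risk equals the requested prevalence.  The
#' returned risks satisfy all four constraints to within \code{1e-10}.
#'
#' \code{PRISM = 1} gives a null scenario (log perils exactly additive);
#' \code{PRISM > 1} a synergistic alternative.
#'
#' @param prevalence Target overall disease prevalence in (0,1).
#' @param rr10,rr01 Marginal relative risks \eqn{RR_{1,0}} and
#'   \eqn{RR_{0,1}} (both > 0).
#' @param prism True PRISM value (> 0); 1 is the no-interaction null.
#' @param exposure_prev Length-2 vector of marginal exposure prevalences;
#'   the joint distribution is their independent product.  Ignored when
#'   \code{joint} is given.
#' @param joint Optional length-4 joint exposure distribution over profiles
#'   \eqn{(1,1), (1,0), (0,1), (0,0)}, summing to 1 (for correlated
#'   exposures).
#' @return An object of class \code{"sc_scenario"}: list with \code{pi}
#'   (joint exposure distribution), \code{risk} (true risks, named by
#'   profile), \code{prevalence}, \code{rr} (all four relative risks) and
#'   \code{prism} (recomputed from the risks).
#' @examples
#' sc <- sc_scenario(prevalence = 0.2, rr10 = 3, rr01 = 2, prism = 1)
#' sc$risk          # baseline risk about 0.0815
#' sc$prism         # exactly 1
#' @seealso [simulate_study()], [rejection_rate_experiment()]
#' @export
sc_scenario <- function(prevalence, rr10, rr01, prism = 1,
                        exposure_prev = c(0.5, 0.5), joint = NULL) {
  stopifnot(is.numeric(prevalence), length(prevalence) == 1L,
            prevalence > 0, prevalence < 1,
            is.numeric(rr10), rr10 > 0, is.numeric(rr01), rr01 > 0,
            is.numeric(prism), prism > 0)
  if (is.null(joint)) {
    if (!is.numeric(exposure_prev) || length(exposure_prev) != 2L ||
        any(exposure_prev <= 0) || any(exposure_prev >= 1)) {
      stop("'exposure_prev' must be two probabilities in (0, 1)", call. = FALSE)
    }
    px <- exposure_prev[1]
    pz <- exposure_prev[2]
    pi_ <- c(px * pz, px * (1 - pz), (1 - px) * pz, (1 - px) * (1 - pz))
  } else {
    if (!is.numeric(joint) || length(joint) != 4L || any(joint < 0) ||
        abs(sum(joint) - 1) > 1e-8) {
      stop("'joint' must be 4 non-negative probabilities summing to 1",
           call. = FALSE)
    }
    pi_ <- joint / sum(joint)
  }
  pi_ <- stats::setNames(pi_, .profiles)

  risks_of <- function(r00) {
    r10 <- rr10 * r00
    r01 <- rr01 * r00
    r11 <- 1 - (1 / prism) * (1 - r10) * (1 - r01) / (1 - r00)
    c(r11, r10, r01, r00)
  }
  f <- function(r00) sum(pi_ * risks_of(r00)) - prevalence

  eps <- 1e-12
  upper <- min(1 / rr10, 1 / rr01, 1) - eps
  flo <- f(eps)
  fhi <- f(upper)
  if (flo >= 0 || fhi <= 0) {
    stop(sprintf(
      paste0("no admissible baseline risk: prevalence %.4g is not reachable ",
             "with RR10 = %g, RR01 = %g, PRISM = %g ",
             "(mean risk spans [%.4g, %.4g])"),
      prevalence, rr10, rr01, prism, flo + prevalence, fhi + prevalence),
      call. = FALSE)
  }
  # mean risk should increase in the baseline risk throughout the bracket;
  # check rather than assume, so a non-monotone configuration is caught
  grid <- f(seq(eps, upper, length.out = 33))
  if (any(diff(grid) <= 0)) {
    stop("mean risk is not monotone in the baseline risk over the bracket",
         call. = FALSE)
  }
  r00 <- stats::uniroot(f, c(eps, upper), tol = 1e-14)$root
  risk <- stats::setNames(risks_of(r00), .profiles)
  if (any(risk <= 0) || any(risk >= 1)) {
    stop(sprintf(
      "solved risks fall outside (0, 1): (%s); the scenario is infeasible",
      paste(signif(risk, 4), collapse = ", ")), call. = FALSE)
  }

  peril <- 1 / (1 - risk)
  structure(
    list(
      pi = pi_, risk = risk,
      prevalence = sum(pi_ * risk),
      rr = risk / risk[4],
      prism = exp(sum(.contrast * log(peril)))
    ),
    class = "sc_scenario"
  )
}

#' @export
print.sc_scenario <- function(x, digits = 4, ...) {
  cat("Simulation scenario (population truth)\n")
  m <- cbind(x = .profile_x, z = .profile_z,
             pi = round(unname(x$pi), digits),
             risk = signif(unname(x$risk), digits),
             rr = signif(unname(x$rr), digits))
  rownames(m) <- rep("", 4)
  print(m)
  cat(sprintf("overall prevalence = %.*g, true PRISM = %.*g\n",
              digits, x$prevalence, digits + 2, x$prism))
  invisible(x)
}

#' Exposure-profile distributions among cases and controls
#'
#' Under case-control sampling, cases are drawn from the population's
#' diseased stratum and controls from the non-diseased stratum, so the
#' exposure-profile distributions are
#' \deqn{q_{x,z} = \pi_{x,z} Risk_{x,z} / p, \qquad
#'       r_{x,z} = \pi_{x,z} (1 - Risk_{x,z}) / (1 - p).}
#'
#' @param scenario An [sc_scenario()].
#' @return List with numeric vectors \code{cases} and \code{controls}
#'   (each summing to 1, profile order \eqn{(1,1), (1,0), (0,1), (0,0)}).
#' @export
cell_distributions <- function(scenario) {
  if (!inherits(scenario, "sc_scenario")) {
    stop("'scenario' must be an sc_scenario", call. = FALSE)
  }
  p <- scenario$prevalence
  list(
    cases = scenario$pi * scenario$risk / p,
    controls = scenario$pi * (1 - scenario$risk) / (1 - p)
  )
}

#' Draw one simulated case-control study from a scenario
#'
#' Draws case counts from Multinomial(\code{n_cases}, \eqn{q}), control
#' counts from Multinomial(\code{n_controls}, \eqn{r}) (see
#' [cell_distributions()]), and a vital-statistics prevalence estimate
#' \eqn{\hat p = D/N} with \eqn{D \sim} Binomial(\code{vital_pop}, \eqn{p}).
#' With \code{vital_pop = Inf} the true prevalence is returned exactly.
#' Draws of \eqn{D} giving \eqn{\hat p \in \{0, 1\}} are redrawn so the
#' estimate is always usable.
#'
#' @param scenario An [sc_scenario()].
#' @param n_cases,n_controls Study sample sizes (\eqn{\ge 1}).
#' @param vital_pop Size of the population behind the prevalence estimate
#'   (default \code{1e6}), or \code{Inf} for an exact prevalence.
#' @param seed Optional integer seed; given a seed the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return List with components \code{table} (a [cc_table()]; possibly
#'   containing zero cells) and \code{prevalence} (a [prevalence()]).
#' @examples
#' sc <- sc_scenario(0.2, rr10 = 3, rr01 = 2, prism = 1)
#' study <- simulate_study(sc, 1000, 1000, seed = 7)
#' study$table
#' @export
simulate_study <- function(scenario, n_cases, n_controls, vital_pop = 1e6,
                           seed = NULL) {
  if (!inherits(scenario, "sc_scenario")) {
    stop("'scenario' must be an sc_scenario", call. = FALSE)
  }
  stopifnot(n_cases >= 1, n_controls >= 1, vital_pop >= 10)
  if (!is.null(seed)) {
    old <- .set_seed(seed)
    on.exit(.restore_seed(old), add = TRUE)
  }
  d <- cell_distributions(scenario)
  tab <- cc_table(
    cases = drop(stats::rmultinom(1, n_cases, d$cases)),
    controls = drop(stats::rmultinom(1, n_controls, d$controls))
  )
  redraws <- 0L
  if (is.finite(vital_pop)) {
    repeat {
      dd <- stats::rbinom(1, vital_pop, scenario$prevalence)
      if (dd > 0 && dd < vital_pop) break
      redraws <- redraws + 1L
      if (redraws > 10000L) {
        stop("cannot draw a prevalence estimate in (0, 1); 'vital_pop' too small",
             call. = FALSE)
      }
    }
    prev <- prevalence(dd / vital_pop, n = vital_pop)
  } else {
    prev <- prevalence(scenario$prevalence, n = Inf)
  }
  list(table = tab, prevalence = prev, prevalence_redraws = redraws)
}
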