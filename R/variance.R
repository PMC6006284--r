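# Delta-method machinery shared by the four tests.
#
# Sampling model: case profile counts ~ Multinomial(N1, q), control profile
# counts ~ Multinomial(N0, r), and (when the prevalence source size is
# finite) D ~ Binomial(Npop, p) with p-hat = D/Npop, the three independent.
# For a statistic T(q, r, p) with gradients gq, gr (length 4) and gp
# (scalar), the multinomial covariance Cov(q_a, q_b) = (delta_ab q_a -
# q_a q_b)/N1 gives
#   Var(T) = [sum q gq^2 - (sum q gq)^2]/N1
#          + [sum r gr^2 - (sum r gr)^2]/N0
#          + gp^2 p(1-p)/Npop,
# the last term dropping out for an exactly known prevalence (Npop = Inf).
.mdelta_var <- function(q, r, n1, n0, gq, gr, gp, p, npop) {
  v <- (sum(q * gq^2) - sum(q * gq)^2) / n1 +
    (sum(r * gr^2) - sum(r * gr)^2) / n0
  if (is.finite(npop)) {
    v <- v + gp^2 * p * (1 - p) / npop
  }
  if (is.na(v) || v < -1e-12) {
    stop("internal error: delta-method variance is negative", call. = FALSE)
  }
  max(v, 0)
}

.method_labels <- c("prism", "prism-odds", "reri-odds", "reri-risk")

.needs_prevalence <- function(method) method %in% c("prism", "reri-risk")

# Point estimate and delta-method variance for one method on raw counts.
# This is the hot path for the Monte Carlo experiments, so it works on bare
# vectors rather than classed objects.
.test_core <- function(method, cases, controls, p, npop, correction = FALSE) {
  if (correction) {
    cases <- cases + 0.5
    controls <- controls + 0.5
  }
  n1 <- sum(cases)
  n0 <- sum(controls)
  q <- cases / n1
  r <- controls / n0
  s <- .contrast

  if (any(r <= 0)) {
    zero <- which(r <= 0)
    stop(sprintf("odds undefined: control count is zero for profile %s",
                 paste(vapply(zero, .profile_label, ""), collapse = ", ")),
         call. = FALSE)
  }

  if (method == "prism") {
    cfac <- p / (1 - p)
    odds <- cfac * q / r
    a <- odds / (1 + odds)
    est <- sum(s * log1p(odds))
    # d logPeril / dq = a/q, with analytic limit cfac/r at q = 0 (the
    # limit is finite; its variance contribution q * g^2 vanishes anyway)
    gq <- s * ifelse(q > 0, a / q, cfac / r)
    gr <- -s * a / r
    gp <- sum(s * a) / (p * (1 - p))
    var <- .mdelta_var(q, r, n1, n0, gq, gr, gp, p, npop)
  } else if (method == "prism-odds") {
    # rare-disease approximation: pseudo-odds q/r stand in for the log
    # perils; the unknown factor p/(1-p) cancels from the Z statistic
    t_ <- q / r
    est <- sum(s * t_)
    gq <- s / r
    gr <- -s * q / r^2
    var <- .mdelta_var(q, r, n1, n0, gq, gr, 0, 0.5, Inf)
  } else if (method == "reri-odds") {
    if (any(cases <= 0)) {
      zero <- which(cases <= 0)
      stop(sprintf("odds ratios undefined: case count is zero for profile %s",
                   paste(vapply(zero, .profile_label, ""), collapse = ", ")),
           call. = FALSE)
    }
    or <- (cases[1:3] * controls[4]) / (cases[4] * controls[1:3])
    est <- or[1] - or[2] - or[3] + 1
    # delta method through the log odds ratios; the shared reference cell
    # induces covariance 1/cases00 + 1/controls00 between any two log ORs
    shared <- 1 / cases[4] + 1 / controls[4]
    cmat <- matrix(shared, 3, 3)
    diag(cmat) <- 1 / cases[1:3] + 1 / controls[1:3] + shared
    h <- c(or[1], -or[2], -or[3])
    var <- drop(h %*% cmat %*% h)
  } else if (method == "reri-risk") {
    if (cases[4] <= 0) {
      stop("risk-scale RERI undefined: reference case count (x=0, z=0) is zero",
           call. = FALSE)
    }
    cfac <- p / (1 - p)
    odds <- cfac * q / r
    a <- odds / (1 + odds)          # absolute risks
    rr <- a[1:3] / a[4]
    est <- rr[1] - rr[2] - rr[3] + 1
    ga <- c(1, -1, -1, -(a[1] - a[2] - a[3]) / a[4]) / a[4]
    dadq <- ifelse(q > 0, a * (1 - a) / q, cfac / r)
    gq <- ga * dadq
    gr <- -ga * a * (1 - a) / r
    gp <- sum(ga * a * (1 - a)) / (p * (1 - p))
    var <- .mdelta_var(q, r, n1, n0, gq, gr, gp, p, npop)
  } else {
    stop(sprintf("unknown method '%s'; use one of %s", method,
                 paste(.method_labels, collapse = ", ")), call. = FALSE)
  }

  list(estimate = unname(est), variance = unname(var))
}

# Column-wise statistic on 4 x B count matrices (parametric bootstrap path).
# Returns NA for replicates where the statistic is undefined.
.stat_columns <- function(method, case_m, control_m, p) {
  n1 <- colSums(case_m)
  n0 <- colSums(control_m)
  qm <- sweep(case_m, 2, n1, "/")
  rm_ <- sweep(control_m, 2, n0, "/")
  bad <- colSums(rm_ <= 0) > 0
  s <- .contrast
  if (method == "prism") {
    odds <- sweep(qm / rm_, 2, p / (1 - p), "*")
    out <- colSums(s * log1p(odds))
  } else if (method == "prism-odds") {
    out <- colSums(s * qm / rm_)
  } else if (method == "reri-odds") {
    bad <- bad | colSums(case_m <= 0) > 0
    or <- sweep(case_m[1:3, , drop = FALSE], 2,
                control_m[4, ] / case_m[4, ], "*") / control_m[1:3, , drop = FALSE]
    out <- or[1, ] - or[2, ] - or[3, ] + 1
  } else if (method == "reri-risk") {
    bad <- bad | case_m[4, ] <= 0
    odds <- sweep(qm / rm_, 2, p / (1 - p), "*")
    a <- odds / (1 + odds)
    out <- (a[1, ] - a[2, ] - a[3, ]) / a[4, ] + 1
  } else {
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  }
  out[bad] <- NA_real_
  out
}

#' Parametric-bootstrap variance of an interaction statistic
#'
#' Independent check on the delta-method variances: resamples case counts
#' from Multinomial(\eqn{N_1, \hat q}), control counts from
#' Multinomial(\eqn{N_0, \hat r}) and, when the prevalence source size is
#' finite, \eqn{D^* \sim} Binomial(\eqn{N_{pop}, \hat p}), recomputes the
#' chosen statistic for each replicate, and returns the empirical variance.
#' Replicates on which the statistic is undefined (a zero control cell, or
#' any zero cell for the odds-scale RERI) are rejected and redrawn; their
#' count is reported and a warning is issued if they exceed 10% of draws.
#'
#' @param table A [cc_table()].
#' @param prevalence A [prevalence()] estimate; required for methods
#'   \code{"prism"} and \code{"reri-risk"}, ignored otherwise.
#' @param method One of \code{"prism"}, \code{"prism-odds"},
#'   \code{"reri-odds"}, \code{"reri-risk"}.
#' @param replicates Number of bootstrap replicates (\eqn{\ge 1}; 10,000
#'   gives variance estimates accurate to a few percent).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return The bootstrap variance (single number) with attributes
#'   \code{"replicates"} and \code{"rejected"} (number of redraws).
#' @examples
#' ex <- hypertension_example()
#' v_boot <- bootstrap_variance(ex$table, ex$prevalence, replicates = 2000,
#'                              seed = 1)
#' sqrt(v_boot)  # close to the delta-method SE of prism_test()
#' @export
bootstrap_variance <- function(table, prevalence = NULL,
                               method = c("prism", "prism-odds",
                                          "reri-odds", "reri-risk"),
                               replicates = 10000, seed = 1) {
  method <- match.arg(method)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  fit <- sc_test(table, prevalence, method = method)
  draws <- stats::simulate(fit, nsim = replicates, seed = seed)
  rejected <- attr(draws, "rejected")
  if (rejected > 0.1 * replicates) {
    warning(sprintf("%d of %d bootstrap draws rejected (zero cells)",
                    rejected, replicates + rejected), call. = FALSE)
  }
  structure(stats::var(as.numeric(draws)),
            replicates = replicates, rejected = rejected)
}

# Seed handling: set a local seed and restore the caller's RNG state.
.set_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
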