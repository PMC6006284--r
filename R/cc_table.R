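# Exposure-profile bookkeeping shared by every estimator in the package.
# Profiles are ordered (x=1,z=1), (1,0), (0,1), (0,0); the PRISM/RERI
# contrast signs (+, -, -, +) are bound to this order here and nowhere else.
.profiles <- c("x1z1", "x1z0", "x0z1", "x0z0")
.profile_x <- c(1L, 1L, 0L, 0L)
.profile_z <- c(1L, 0L, 1L, 0L)
.contrast <- c(1, -1, -1, 1)

.profile_label <- function(i) {
  sprintf("(x=%d, z=%d)", .profile_x[i], .profile_z[i])
}

#' Case-control contingency table for two binary exposures
#'
#' Stores the 2x2x2 counts of a case-control study: for each joint exposure
#' profile \eqn{(x, z)} with \eqn{x, z \in \{0, 1\}}, the number of cases and
#' the number of controls recruited with that profile.  Counts are supplied
#' in profile order \eqn{(1,1), (1,0), (0,1), (0,0)}.
#'
#' The object carries the totals \eqn{N_1} (cases) and \eqn{N_0} (controls)
#' and the sample proportions \eqn{\hat q_{x,z} = } cases\eqn{_{x,z}/N_1} and
#' \eqn{\hat r_{x,z} = } controls\eqn{_{x,z}/N_0}, which are the sufficient
#' statistics for all four interaction tests.
#'
#' @param cases Non-negative integer vector of length 4: case counts for
#'   profiles \eqn{(1,1), (1,0), (0,1), (0,0)} in that order.
#' @param controls Non-negative integer vector of length 4: control counts
#'   in the same profile order.
#' @return An object of class \code{"cc_table"}: a list with elements
#'   \code{cases}, \code{controls} (named count vectors), \code{n_cases},
#'   \code{n_controls}, \code{q_hat} and \code{r_hat}.
#' @examples
#' # Gene-noise essential-hypertension study (AT1R A1166C x occupational
#' # noise >= 85 dB): AC+CC/noise, AC+CC/quiet, AA/noise, AA/quiet
#' tab <- cc_table(cases = c(20, 13, 161, 117), controls = c(18, 24, 261, 319))
#' tab
#' @seealso [read_cc_table()], [prism_test()], [hypertension_example()]
#' @export
cc_table <- function(cases, controls) {
  cases <- .check_counts(cases, "cases")
  controls <- .check_counts(controls, "controls")
  n1 <- sum(cases)
  n0 <- sum(controls)
  if (n1 <= 0) stop("total number of cases must be positive", call. = FALSE)
  if (n0 <= 0) stop("total number of controls must be positive", call. = FALSE)
  structure(
    list(
      cases = cases, controls = controls,
      n_cases = n1, n_controls = n0,
      q_hat = cases / n1, r_hat = controls / n0
    ),
    class = "cc_table"
  )
}

.check_counts <- function(x, what) {
  if (!is.numeric(x) || length(x) != 4L) {
    stop(sprintf("'%s' must be a numeric vector of length 4 (profiles %s)",
                 what, paste(.profiles, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and non-negative", what), call. = FALSE)
  }
  # non-integer "counts" are accepted on purpose: expected counts (exact
  # population proportions times a total) are valid inputs for plug-in checks
  stats::setNames(as.numeric(x), .profiles)
}

#' @export
print.cc_table <- function(x, ...) {
  cat("Case-control table (2 binary exposures)\n")
  m <- cbind(x = .profile_x, z = .profile_z,
             cases = unname(x$cases), controls = unname(x$controls))
  rownames(m) <- rep("", 4)
  print(m)
  cat(sprintf("N1 = %g cases, N0 = %g controls\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
as.data.frame.cc_table <- function(x, ...) {
  data.frame(x = .profile_x, z = .profile_z,
             cases = unname(x$cases), controls = unname(x$controls))
}

#' External estimate of the overall disease prevalence
#'
#' The prevalence-adjusted tests need an estimate \eqn{\hat p = D/N} of the
#' overall disease prevalence of the source population, typically taken from
#' vital statistics or a published survey.  \code{n} is the size of the
#' population (or sample) the estimate came from; it drives the
#' binomial-uncertainty term in the delta-method variance.  Use
#' \code{n = Inf} to treat the prevalence as known exactly, in which case
#' that variance term vanishes.
#'
#' @param p Overall disease prevalence, strictly between 0 and 1.
#' @param n Size of the population behind the estimate (\eqn{\ge 1}), or
#'   \code{Inf} for an exactly known prevalence.
#' @return An object of class \code{"prevalence_estimate"} with elements
#'   \code{p} and \code{n}.
#' @examples
#' prevalence(0.252, n = 1e5)   # 25.2% from a population of 100,000
#' prevalence(0.2)              # treated as exact
#' @export
prevalence <- function(p, n = Inf) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("prevalence 'p' must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("population size 'n' must be >= 1 (or Inf for an exact prevalence)",
         call. = FALSE)
  }
  structure(list(p = as.numeric(p), n = as.numeric(n)),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  if (is.finite(x$n)) {
    cat(sprintf("Disease prevalence estimate: %.4g (population size %g)\n",
                x$p, x$n))
  } else {
    cat(sprintf("Disease prevalence: %.4g (treated as exact)\n", x$p))
  }
  invisible(x)
}

.as_prevalence <- function(prev) {
  if (inherits(prev, "prevalence_estimate")) return(prev)
  if (is.numeric(prev) && length(prev) == 1L) return(prevalence(prev))
  stop("'prevalence' must be a prevalence_estimate or a single number",
       call. = FALSE)
}

.as_cc_table <- function(table) {
  if (inherits(table, "cc_table")) return(table)
  stop("'table' must be a cc_table object; see cc_table() or read_cc_table()",
       call. = FALSE)
}

#' Worked example: gene-noise interaction in essential hypertension
#'
#' The case-control study of essential hypertension by Tong and colleagues,
#' cross-classifying the AT1R A1166C genotype (AC+CC vs AA) against
#' occupational noise exposure (>= 85 dB vs < 85 dB), together with the
#' hypertension prevalence of 25.2% reported for the source population of
#' 100,000.  This is the dataset used throughout the package documentation.
#'
#' @return A list with components \code{table} (a [cc_table()]) and
#'   \code{prevalence} (a [prevalence()] estimate).
#' @examples
#' ex <- hypertension_example()
#' prism_test(ex$table, ex$prevalence)
#' @export
hypertension_example <- function() {
  path <- system.file("extdata", "hypertension.csv", package = "prismcc")
  list(
    table = read_cc_table(path),
    prevalence = prevalence(0.252, n = 1e5)
  )
}
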