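# Bayes-theorem point estimators of per-profile disease odds and log perils.
#
# In a case-control study absolute risks are not identified, but with an
# external overall prevalence p the disease odds of profile (x,z) are
#   Odds_{x,z} = p/(1-p) * q_{x,z}/r_{x,z}
# (Cornfield's argument), where q and r are the exposure-profile proportions
# among cases and controls.  The peril is 1/(1 - Risk) = 1 + Odds, so
# logPeril = log1p(Odds).

# Optionally apply the add-0.5 continuity correction to all eight cells.
.table_props <- function(table, correction = FALSE) {
  ca <- table$cases
  co <- table$controls
  if (correction) {
    ca <- ca + 0.5
    co <- co + 0.5
  }
  list(q = ca / sum(ca), r = co / sum(co))
}

.check_positive_controls <- function(r, correction) {
  zero <- which(r <= 0)
  if (length(zero)) {
    stop(sprintf(
      "odds undefined: control count is zero for profile %s%s",
      paste(vapply(zero, .profile_label, ""), collapse = ", "),
      if (correction) "" else " (consider correction = TRUE)"
    ), call. = FALSE)
  }
}

#' Estimate per-profile disease odds and log perils
#'
#' \code{cell_odds()} converts the exposure-profile proportions of a
#' case-control table into absolute disease odds per profile using an
#' external overall prevalence: \eqn{\widehat{Odds}_{x,z} =
#' \hat p/(1-\hat p) \cdot \hat q_{x,z}/\hat r_{x,z}}.  \code{log_perils()}
#' additionally returns the log perils
#' \eqn{\log \widehat{Peril}_{x,z} = \log(1 + \widehat{Odds}_{x,z})},
#' evaluated with \code{log1p} so that the rare-disease regime (odds near
#' zero) does not lose precision.
#'
#' A zero case count is allowed (the odds estimate is 0); a zero control
#' count makes the estimator undefined and is an error unless
#' \code{correction = TRUE}, which adds 0.5 to all eight cells before
#' forming proportions (off by default).
#'
#' @param table A [cc_table()].
#' @param prevalence A [prevalence()] estimate (or a bare number in (0,1)).
#' @param correction Logical; add 0.5 to every cell before estimating.
#' @return An object of class \code{"peril_set"}: a list with named numeric
#'   vectors \code{odds} and \code{log_peril} (profile order
#'   \eqn{(1,1), (1,0), (0,1), (0,0)}) plus the prevalence used.
#' @examples
#' ex <- hypertension_example()
#' log_perils(ex$table, ex$prevalence)
#' @export
log_perils <- function(table, prevalence, correction = FALSE) {
  table <- .as_cc_table(table)
  prev <- .as_prevalence(prevalence)
  pr <- .table_props(table, correction)
  .check_positive_controls(pr$r, correction)
  odds <- prev$p / (1 - prev$p) * pr$q / pr$r
  structure(
    list(odds = odds, log_peril = log1p(odds), prevalence = prev),
    class = "peril_set"
  )
}

#' @rdname log_perils
#' @export
cell_odds <- function(table, prevalence, correction = FALSE) {
  log_perils(table, prevalence, correction)
}

#' @export
print.peril_set <- function(x, digits = 4, ...) {
  cat("Per-profile disease odds and log perils\n")
  m <- cbind(x = .profile_x, z = .profile_z,
             odds = round(unname(x$odds), digits),
             risk = round(unname(x$odds / (1 + x$odds)), digits),
             log_peril = round(unname(x$log_peril), digits))
  rownames(m) <- rep("", 4)
  print(m)
  cat(sprintf("logPRISM = %.*f\n", digits, log_prism(x)))
  invisible(x)
}

#' The log peril-ratio interaction contrast (logPRISM)
#'
#' Computes the double-difference contrast
#' \deqn{\log PRISM = \log Peril_{1,1} - \log Peril_{1,0}
#'   - \log Peril_{0,1} + \log Peril_{0,0},}
#' which is zero exactly when log perils are additive, i.e. under the null
#' of no sufficient-cause interaction between the two exposures.
#'
#' @param perils A \code{"peril_set"} from [log_perils()].
#' @return The signed contrast (a single number).
#' @examples
#' ex <- hypertension_example()
#' log_prism(log_perils(ex$table, ex$prevalence))  # 0.121
#' @export
log_prism <- function(perils) {
  if (!inherits(perils, "peril_set")) {
    stop("'perils' must be a peril_set from log_perils()", call. = FALSE)
  }
  lp <- perils$log_peril
  if (any(!is.finite(lp))) {
    stop("log perils must all be finite", call. = FALSE)
  }
  sum(.contrast * lp)
}
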