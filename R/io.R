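# Readers, writers and fixture generation.

#' Read a case-control table from CSV or TSV
#'
#' Expects a header \code{x,z,cases,controls} and exactly four data rows,
#' one per exposure profile with \eqn{x, z \in \{0, 1\}}, in any order.
#' Duplicate or missing profiles, negative counts and malformed rows are
#' rejected with the offending row named.
#'
#' @param path Path to the file.
#' @param format \code{"csv"}, \code{"tsv"}, or \code{"auto"} (default:
#'   by file extension, falling back to CSV).
#' @return A [cc_table()].
#' @examples
#' path <- system.file("extdata", "hypertension.csv", package = "prismcc")
#' read_cc_table(path)
#' @export
read_cc_table <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  needed <- c("x", "z", "cases", "controls")
  if (!all(needed %in% names(df))) {
    stop(sprintf("missing column(s): %s (need header x,z,cases,controls)",
                 paste(setdiff(needed, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  for (col in needed) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric value in column '%s' (data row %d)",
                   col, which(is.na(v))[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(df$x %notin% c(0, 1)) || any(df$z %notin% c(0, 1))) {
    bad <- which(df$x %notin% c(0, 1) | df$z %notin% c(0, 1))[1]
    stop(sprintf("x and z must be 0 or 1 (data row %d)", bad), call. = FALSE)
  }
  key <- paste0("x", df$x, "z", df$z)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop(sprintf("duplicated exposure profile(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  missing_ <- setdiff(.profiles, key)
  if (length(missing_)) {
    stop(sprintf("missing exposure profile(s): %s",
                 paste(missing_, collapse = ", ")), call. = FALSE)
  }
  ord <- match(.profiles, key)
  cc_table(cases = df$cases[ord], controls = df$controls[ord])
}

`%notin%` <- function(x, table) !(x %in% table)

#' Write a test result or simulation summary to disk
#'
#' JSON output (\code{"json"}) keeps full precision and round-trips
#' through [read_report()] field-for-field.  Text output (\code{"text"})
#' is the human-readable report: estimate, SE, Z, p-value, confidence
#' interval, method and the prevalence used.  CSV output (\code{"csv"})
#' applies to simulation summaries (\code{sc_power} /
#' \code{sc_power_grid} or lists of them) and writes one row per summary.
#'
#' @param result An \code{sc_test}, \code{sc_power}, \code{sc_power_grid},
#'   or a list of these.
#' @param path Output file path.
#' @param format \code{"json"}, \code{"text"} or \code{"csv"} (default: by
#'   file extension, falling back to text).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(result, path,
                         format = c("auto", "json", "text", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
      else "text"
  }
  if (format == "json") {
    jsonlite::write_json(.report_payload(result), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (format == "csv") {
    df <- .report_frame(result)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    writeLines(utils::capture.output(.print_report(result)), path)
  }
  invisible(path)
}

.print_report <- function(result) {
  if (inherits(result, c("sc_test", "sc_power", "sc_power_grid"))) {
    print(result)
  } else if (is.list(result)) {
    for (r in result) {
      print(r)
      cat("\n")
    }
  } else {
    print(result)
  }
}

.report_frame <- function(result) {
  if (inherits(result, "sc_power")) return(as.data.frame(result))
  if (inherits(result, "sc_power_grid")) return(as.data.frame(result))
  if (inherits(result, "sc_test")) result <- list(result)
  do.call(rbind, lapply(result, function(r) {
    if (inherits(r, "sc_power")) as.data.frame(r)
    else if (inherits(r, "sc_power_grid")) as.data.frame(r)
    else .sc_test_frame(r)
  }))
}

.sc_test_frame <- function(r) {
  data.frame(
    method = r$method, estimate = r$estimate, variance = r$variance,
    se = r$se, z = r$statistic, p_value = r$p.value,
    ci_low = r$conf.int[1], ci_high = r$conf.int[2],
    conf_level = attr(r$conf.int, "conf.level"),
    alternative = r$alternative,
    prevalence = if (is.null(r$prevalence)) NA_real_ else r$prevalence$p,
    prevalence_n = if (is.null(r$prevalence)) NA_real_ else r$prevalence$n
  )
}

.report_payload <- function(result) {
  if (inherits(result, "sc_test")) {
    out <- list(
      method = result$method, estimate = result$estimate,
      variance = result$variance, se = result$se, z = result$statistic,
      p_value = result$p.value,
      ci_low = result$conf.int[1], ci_high = result$conf.int[2],
      conf_level = attr(result$conf.int, "conf.level"),
      alpha = result$alpha, alternative = result$alternative
    )
    if (!is.null(result$prevalence)) {
      out$prevalence <- result$prevalence$p
      out$prevalence_n <- result$prevalence$n
    }
    if (!is.null(result$perils)) {
      out$odds <- as.list(result$perils$odds)
      out$log_peril <- as.list(result$perils$log_peril)
    }
    out
  } else if (inherits(result, "sc_power")) {
    as.list(as.data.frame(result))
  } else if (inherits(result, "sc_power_grid")) {
    lapply(unclass(result), .report_payload)
  } else if (is.list(result)) {
    lapply(result, .report_payload)
  } else {
    result
  }
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return The parsed list (field-for-field equal to the payload written).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Generate reproducible example files
#'
#' Writes small, self-describing input files into a directory:
#' \describe{
#'   \item{\code{"worked_example"}}{the gene-noise hypertension table
#'     (\code{table.csv}) and its prevalence configuration
#'     (\code{config.json}: prevalence 0.252 from a population of
#'     100,000).}
#'   \item{\code{"null_scenario"}}{a configuration for the no-interaction
#'     scenario (prevalence 0.2, RR10 = 3, RR01 = 2, PRISM = 1, 1000
#'     cases / 1000 controls) plus one simulated table drawn from it.}
#'   \item{\code{"power_scenario"}}{the synergistic scenario (prevalence
#'     0.2, PRISM = 1.1710, 500 cases / 500 controls) plus one simulated
#'     table.}
#' }
#' Output is deterministic given \code{seed}.
#'
#' @param kind Which fixture to write.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed used for the simulated tables.
#' @return Character vector of the paths written, invisibly.
#' @export
generate_fixture <- function(kind = c("worked_example", "null_scenario",
                                      "power_scenario"),
                             dir = ".", seed = 1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table_path <- file.path(dir, "table.csv")
  config_path <- file.path(dir, "config.json")

  if (kind == "worked_example") {
    ex <- hypertension_example()
    utils::write.csv(as.data.frame(ex$table), table_path, row.names = FALSE)
    jsonlite::write_json(
      list(kind = kind, method = "prism",
           prevalence = ex$prevalence$p, prevalence_n = ex$prevalence$n,
           alpha = 0.05, alternative = "two.sided"),
      config_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(c(table_path, config_path)))
  }

  cfg <- if (kind == "null_scenario") {
    list(kind = kind, prevalence = 0.2, rr10 = 3, rr01 = 2, prism = 1,
         exposure_prev = c(0.5, 0.5), n_cases = 1000, n_controls = 1000,
         vital_pop = 1e6, alpha = 0.05, replicates = 2000, seed = seed)
  } else {
    list(kind = kind, prevalence = 0.2, rr10 = 3, rr01 = 2, prism = 1.1710,
         exposure_prev = c(0.5, 0.5), n_cases = 500, n_controls = 500,
         vital_pop = 1e6, alpha = 0.05, replicates = 1000, seed = seed)
  }
  sc <- sc_scenario(cfg$prevalence, cfg$rr10, cfg$rr01, cfg$prism,
                    exposure_prev = cfg$exposure_prev)
  study <- simulate_study(sc, cfg$n_cases, cfg$n_controls, cfg$vital_pop,
                          seed = seed)
  utils::write.csv(as.data.frame(study$table), table_path, row.names = FALSE)
  cfg$prevalence_estimate <- study$prevalence$p
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(table_path, config_path))
}
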