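# CSV input/output for frequency tables and structured text fit reports.
# The CSV dialect is fixed: UTF-8, comma separator, dot decimal, header
#   pressure_Pa, concentration_per_mL, frequency_per_s, sem_per_s, n_replicates
# Column names carry units; concentrations are converted to SI on read.

.csv_columns <- c("pressure_Pa", "concentration_per_mL", "frequency_per_s",
                  "sem_per_s", "n_replicates")

#' Read a frequency-curve CSV
#'
#' Reads a comma-separated table with header `pressure_Pa,
#' concentration_per_mL, frequency_per_s, sem_per_s, n_replicates` (a
#' `concentration_per_m3` column is also accepted) and returns a validated
#' [frequency_curve()] in SI units, preserving row order.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A [frequency_curve()].
#' @export
read_frequency_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  per_m3 <- "concentration_per_m3" %in% names(raw)
  want <- .csv_columns
  if (per_m3) want[want == "concentration_per_mL"] <- "concentration_per_m3"
  miss <- setdiff(want, names(raw))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad)) {
      stop("column `", col, "` has a malformed number at data row ", bad[1L],
           " (value '", raw[[col]][bad[1L]],
           "'); use dot decimals", call. = FALSE)
    }
    x
  }
  freq <- num("frequency_per_s")
  neg <- which(freq < 0)
  if (length(neg)) {
    stop("negative frequency at data row ", neg[1L], call. = FALSE)
  }
  conc <- if (per_m3) num("concentration_per_m3") else
    per_ml_to_per_m3(num("concentration_per_mL"))
  frequency_curve(pressure = num("pressure_Pa"),
                  concentration = conc,
                  frequency = freq,
                  sem = num("sem_per_s"),
                  n_replicates = as.integer(num("n_replicates")))
}

#' Write a frequency curve to CSV
#'
#' Writes the dialect read by [read_frequency_csv()], converting
#' concentrations back to particles/mL. Full double precision is preserved.
#'
#' @param curve A [frequency_curve()] (or data.frame with SI columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_csv <- function(curve, path) {
  d <- .as_curve_df(curve)
  out <- data.frame(
    pressure_Pa = sprintf("%.17g", d$pressure),
    concentration_per_mL = sprintf("%.17g", per_m3_to_per_ml(d$concentration)),
    frequency_per_s = sprintf("%.17g", d$frequency),
    sem_per_s = sprintf("%.17g", d$sem),
    n_replicates = if ("n_replicates" %in% names(curve))
      curve$n_replicates else 1L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt_num <- function(x) sprintf("%.17g", as.numeric(x))

#' Write a structured text fit report
#'
#' Serialises a `fit_result` as a nested key-value text report
#' (`[section]` headers, `key: value` lines, full double precision), with
#' optional extra quantities (e.g. the adhesion energy barrier together with
#' the attempt rate it assumed, or a collapse metric). Byte-deterministic
#' given identical inputs.
#'
#' @param result A `fit_result` from one of the fitters.
#' @param path Output path.
#' @param extra Optional named list of scalar numerics appended in an
#'   `[extra]` section.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(result, path, extra = list()) {
  stopifnot(inherits(result, "fit_result"))
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open '", path, "' for writing", call. = FALSE)
  }
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w("# porejam fit report")
  w("method: ", result$method)
  w("[estimates]")
  for (nm in names(result$estimates)) w(nm, ": ", .fmt_num(result$estimates[[nm]]))
  w("[se]")
  for (nm in names(result$se)) w(nm, ": ", .fmt_num(result$se[[nm]]))
  if (length(result$fixed)) {
    w("[fixed]")
    for (nm in names(result$fixed)) w(nm, ": ", .fmt_num(result$fixed[[nm]]))
  }
  if (length(result$derived)) {
    w("[derived]")
    for (nm in names(result$derived)) w(nm, ": ", .fmt_num(result$derived[[nm]]))
  }
  w("[diagnostics]")
  w("objective: ", .fmt_num(result$objective))
  w("dof: ", result$dof)
  w("converged: ", result$converged)
  w("seed: ", result$seed)
  w("n_starts: ", result$n_starts)
  if (length(extra)) {
    w("[extra]")
    for (nm in names(extra)) w(nm, ": ", .fmt_num(extra[[nm]]))
  }
  invisible(path)
}

#' Parse a text fit report
#'
#' Reads a report written by [write_fit_report()] back into a nested list of
#' numeric values; round-trips every number exactly.
#'
#' @param path Path to a report file.
#' @return A named list of sections, each a named list of values.
#' @export
read_fit_report <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  section <- "header"
  out[[section]] <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else {
      kv <- regmatches(ln, regexec("^([^:]+): ?(.*)$", ln))[[1L]]
      if (length(kv) == 3L) {
        val <- suppressWarnings(as.numeric(kv[3L]))
        if (is.na(val) && !kv[3L] %in% c("NA", "NaN")) val <- kv[3L]
        out[[section]][[trimws(kv[2L])]] <- val
      }
    }
  }
  out
}
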