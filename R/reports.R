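#' Construct a deduplicated safety-report collection
#'
#' The central container of the package: a relational snapshot of one case
#' per row plus its drug exposures and reaction terms. Most users obtain one
#' from [build_reports()], [simulate_reports()] or [table1_fixture()] rather
#' than calling this constructor directly.
#'
#' @param cases data.frame with one row per case. Required columns:
#'   `case_id`, `primary_id` (character), `sex` ("M"/"F"/"U"), `age_years`
#'   (numeric, NA allowed), `country`, `continent`, `report_date`,
#'   `event_date` (Date), `indication`, `indication_group`, `outcome_codes`
#'   (";"-separated subset of DE/LT/HO/DS/CA/RI/OT, "" when none), `died`
#'   (logical).
#' @param drugs data.frame with columns `case_id`, `drug_seq`,
#'   `verbatim_name`, `substance` ("other" when not in the dictionary),
#'   `role` (PS/SS/C/I), `start_raw`, `end_raw` (raw FAERS date strings).
#' @param reactions data.frame with columns `case_id`, `pt`.
#' @param counters named list of bookkeeping counts accumulated by the
#'   ingest steps (orphan rows, dropped versions, unit warnings, ...).
#' @return An object of class `safety_reports`.
#' @export
safety_reports <- function(cases, drugs, reactions, counters = list()) {
  req_cases <- c("case_id", "primary_id", "sex", "age_years", "country",
                 "continent", "report_date", "event_date", "indication",
                 "indication_group", "outcome_codes", "died")
  miss <- setdiff(req_cases, names(cases))
  if (length(miss)) stop("safety_reports: cases lacks columns: ", paste(miss, collapse = ", "))
  stopifnot(all(c("case_id", "drug_seq", "verbatim_name", "substance", "role",
                  "start_raw", "end_raw") %in% names(drugs)),
            all(c("case_id", "pt") %in% names(reactions)))
  if (anyDuplicated(cases$case_id)) stop("safety_reports: duplicated case_id in cases")
  # died must mirror the DE outcome code exactly
  has_de <- vapply(strsplit(cases$outcome_codes, ";", fixed = TRUE),
                   function(x) "DE" %in% x, logical(1))
  if (!identical(unname(has_de), unname(cases$died))) {
    stop("safety_reports: died flag inconsistent with DE outcome code")
  }
  bad_age <- !is.na(cases$age_years) & (cases$age_years < 0 | cases$age_years > 120)
  if (any(bad_age)) stop("safety_reports: age_years outside [0, 120]")
  rownames(cases) <- rownames(drugs) <- rownames(reactions) <- NULL
  structure(list(cases = cases, drugs = drugs, reactions = reactions,
                 counters = counters),
            class = "safety_reports")
}

#' @export
print.safety_reports <- function(x, ...) {
  cat("<safety_reports> ", nrow(x$cases), " cases, ",
      nrow(x$drugs), " drug rows, ", nrow(x$reactions), " reaction rows\n", sep = "")
  if (nrow(x$cases)) {
    cat("  deaths: ", sum(x$cases$died), " (",
        .pct(sum(x$cases$died), nrow(x$cases)), "%)\n", sep = "")
    if ("regimen" %in% names(x$cases)) {
      top <- sort(table(x$cases$regimen), decreasing = TRUE)
      cat("  top regimens: ",
          paste(utils::head(names(top), 3), utils::head(top, 3),
                sep = "=", collapse = ", "), "\n", sep = "")
    }
  }
  if (length(x$counters)) {
    cat("  counters: ",
        paste(names(x$counters), unlist(x$counters), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.safety_reports <- function(object, ...) {
  cohort_summary(object)
}

#' Number of cases in a safety-report collection
#' @param x a `safety_reports` object.
#' @export
n_cases <- function(x) nrow(x$cases)

# keep only the given case ids, subsetting all three tables consistently
.filter_cases <- function(reports, keep_ids, counters = reports$counters) {
  safety_reports(
    cases = reports$cases[reports$cases$case_id %in% keep_ids, , drop = FALSE],
    drugs = reports$drugs[reports$drugs$case_id %in% keep_ids, , drop = FALSE],
    reactions = reports$reactions[reports$reactions$case_id %in% keep_ids, , drop = FALSE],
    counters = counters
  )
}

# ---- interchange format -----------------------------------------------------

# doubles are serialised with %.17g so that read.csv reproduces them bit for bit
.fmt_num <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}

.df_to_text <- function(df) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "Date")) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA_character_, format(df[[nm]], "%Y-%m-%d"))
    } else if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- .fmt_num(df[[nm]])
    }
  }
  df
}

#' Write / read the case-level interchange tables
#'
#' `write_reports()` serialises a `safety_reports` object to three CSV files
#' (`cases.csv`, `drugs.csv`, `reactions.csv`) under `dir`, plus a
#' `counters.json` log. Doubles are written with 17 significant digits so the
#' round trip through `read_reports()` is bit-exact. `flat_case_table()`
#' additionally returns the one-row-per-case flat table used as the pipeline
#' interchange artifact (list-valued fields collapsed with ";").
#'
#' @param reports a `safety_reports` object.
#' @param dir output directory (created if needed).
#' @return `write_reports` returns the directory invisibly; `read_reports`
#'   returns a `safety_reports` object.
#' @export
write_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(.df_to_text(reports$cases), file.path(dir, "cases.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(.df_to_text(reports$drugs), file.path(dir, "drugs.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(.df_to_text(reports$reactions), file.path(dir, "reactions.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(reports$counters, file.path(dir, "counters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_reports
#' @export
read_reports <- function(dir) {
  chr <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                                     colClasses = "character", na.strings = "")
  cases <- chr("cases.csv")
  for (nm in c("report_date", "event_date")) cases[[nm]] <- as.Date(cases[[nm]])
  cases$age_years <- as.numeric(cases$age_years)
  if ("tto_days" %in% names(cases)) cases$tto_days <- as.numeric(cases$tto_days)
  if ("n_ici" %in% names(cases)) cases$n_ici <- as.integer(cases$n_ici)
  cases$died <- cases$died == "TRUE"
  if ("mono" %in% names(cases)) cases$mono <- as.logical(cases$mono)
  cases$outcome_codes[is.na(cases$outcome_codes)] <- ""
  drugs <- chr("drugs.csv")
  drugs$drug_seq <- as.integer(drugs$drug_seq)
  reactions <- chr("reactions.csv")
  counters <- jsonlite::read_json(file.path(dir, "counters.json"), simplifyVector = TRUE)
  safety_reports(cases, drugs, reactions, counters = as.list(counters))
}

#' @rdname write_reports
#' @export
flat_case_table <- function(reports) {
  collapse_by <- function(df, val) {
    s <- split(df[[val]], df$case_id)
    v <- vapply(s, paste, character(1), collapse = ";")
    v[match(reports$cases$case_id, names(v))]
  }
  out <- reports$cases
  out$substances <- collapse_by(reports$drugs, "substance")
  out$drug_roles <- collapse_by(reports$drugs, "role")
  out$reaction_pts <- collapse_by(reports$reactions, "pt")
  out
}
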