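#' 2x2 contingency table for one drug-event pair
#'
#' @param a target drug and target event; @param b target drug, other events;
#' @param c other drugs, target event; @param d other drugs, other events.
#' @return object of class `contingency`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency_table: cells must be non-negative integers")
  }
  if (sum(cells) <= 0) stop("contingency_table: empty table")
  structure(as.list(cells), class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

# resolve a drug selector to a logical vector over cases.
# selector: logical vector, function(reports)->logical, or character vector
# of canonical substances (case qualifies when a drug row with that substance
# and one of `roles` is present).
.case_has_drug <- function(reports, selector, roles = "PS") {
  if (is.logical(selector)) {
    stopifnot(length(selector) == nrow(reports$cases))
    return(selector)
  }
  if (is.function(selector)) return(selector(reports))
  d <- reports$drugs
  ids <- unique(d$case_id[!is.na(d$role) & d$role %in% roles &
                          d$substance %in% selector])
  reports$cases$case_id %in% ids
}

# event selector over cases: character vector of PTs (case-insensitive) or
# logical/function
.case_has_event <- function(reports, selector) {
  if (is.logical(selector)) {
    stopifnot(length(selector) == nrow(reports$cases))
    return(selector)
  }
  if (is.function(selector)) return(selector(reports))
  r <- reports$reactions
  ids <- unique(r$case_id[tolower(r$pt) %in% tolower(selector)])
  reports$cases$case_id %in% ids
}

#' Build the 2x2 disproportionality table from a report database
#'
#' With `unit = "record"` the counting units are reaction rows (drug-event
#' pairs): one case reporting two qualifying PTs contributes 2 to cell `a`.
#' With `unit = "case"` units are unique cases. Either way the four cells
#' partition all counted units exactly once.
#'
#' @param reports a `safety_reports` database holding target and background
#'   reports.
#' @param drug drug selector: character vector of canonical substances,
#'   a logical vector over cases, or a function of `reports`.
#' @param event event selector: character vector of PTs (case-insensitive),
#'   a logical vector over cases, or a function.
#' @param unit `"record"` (default) or `"case"`.
#' @param roles drug roles that qualify (default `"PS"`).
#' @return a [contingency_table()].
#' @export
build_contingency <- function(reports, drug, event,
                              unit = c("record", "case"), roles = "PS") {
  unit <- match.arg(unit)
  drug_case <- .case_has_drug(reports, drug, roles = roles)
  if (unit == "case") {
    event_case <- .case_has_event(reports, event)
    a <- sum(drug_case & event_case)
    b <- sum(drug_case & !event_case)
    c <- sum(!drug_case & event_case)
    d <- sum(!drug_case & !event_case)
  } else {
    r <- reports$reactions
    row_drug <- drug_case[match(r$case_id, reports$cases$case_id)]
    row_event <- if (is.character(event)) {
      tolower(r$pt) %in% tolower(event)
    } else {
      # case-level selectors mark every reaction row of a qualifying case
      ev <- .case_has_event(reports, event)
      ev[match(r$case_id, reports$cases$case_id)]
    }
    a <- sum(row_drug & row_event)
    b <- sum(row_drug & !row_event)
    c <- sum(!row_drug & row_event)
    d <- sum(!row_drug & !row_event)
  }
  if (c + d == 0) {
    stop("build_contingency: empty background (c + d = 0); supply a database ",
         "containing non-target reports for the denominators")
  }
  contingency_table(a, b, c, d)
}

# ---- vectorised estimators --------------------------------------------------

# reporting odds ratio with Wald CI; Haldane-Anscombe +0.5 on all cells when
# any cell is zero (flagged)
.ror_vec <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0)
  aa <- a + 0.5 * corrected; bb <- b + 0.5 * corrected
  cc <- c + 0.5 * corrected; dd <- d + 0.5 * corrected
  est <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  data.frame(ror = est,
             ror_low = exp(log(est) - z * se),
             ror_high = exp(log(est) + z * se),
             ror_corrected = corrected)
}

# proportional reporting ratio and Yates-corrected chi-square.
# PRR is 0 when a = 0 and +Inf when c = 0 with a > 0 (flagged).
.prr_vec <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  prr <- ifelse(a == 0, 0, (a / (a + b)) / (c / (c + d)))
  det <- abs(a * d - b * c)
  corr <- if (yates) pmin(det, n / 2) else 0
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * (det - corr)^2 / denom, NA_real_)
  data.frame(prr = prr, chi2 = chi2, prr_infinite = is.infinite(prr))
}

# information component: shrinkage log2 observed/expected with credible
# bounds from the Gamma(a + 0.5, E + 0.5) posterior ("gamma", default) or a
# large-count polynomial approximation ("approx")
.ic_vec <- function(a, b, c, d, method = c("gamma", "approx"), conf = 0.95) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  E <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (E + 0.5))
  alpha <- (1 - conf) / 2
  if (method == "gamma") {
    low <- log2(stats::qgamma(alpha, shape = a + 0.5, rate = E + 0.5))
    high <- log2(stats::qgamma(1 - alpha, shape = a + 0.5, rate = E + 0.5))
  } else {
    off <- 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-0.75)
    low <- ic - off
    high <- ic + off
  }
  data.frame(ic = ic, ic_low = low, ic_high = high, ic_expected = E)
}

.as_cells <- function(table) {
  if (inherits(table, "contingency")) {
    list(a = table$a, b = table$b, c = table$c, d = table$d)
  } else if (is.numeric(table) && length(table) == 4) {
    list(a = table[[1]], b = table[[2]], c = table[[3]], d = table[[4]])
  } else stop("expected a contingency table or a length-4 numeric vector")
}

#' Reporting odds ratio
#'
#' ROR = (a d)/(b c) with the Wald interval
#' exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero,
#' 0.5 is added to all four cells (Haldane-Anscombe) and the result flagged.
#'
#' @param table a [contingency_table()] or numeric `c(a, b, c, d)`.
#' @param z normal quantile for the interval (default 1.96).
#' @return list with `ror`, `ror_low`, `ror_high`, `corrected`.
#' @export
ror <- function(table, z = 1.96) {
  cl <- .as_cells(table)
  r <- .ror_vec(cl$a, cl$b, cl$c, cl$d, z = z)
  list(ror = r$ror, ror_low = r$ror_low, ror_high = r$ror_high,
       corrected = r$ror_corrected)
}

#' Proportional reporting ratio with chi-square
#'
#' PRR = (a/(a+b)) / (c/(c+d)); the chi-square is the Yates-corrected
#' Pearson statistic on the 2x2 by default (`yates = FALSE` for the
#' uncorrected version). PRR is 0 when a = 0 and `Inf` (flagged) when c = 0
#' with a > 0.
#'
#' @inheritParams ror
#' @param yates apply the continuity correction (default TRUE).
#' @return list with `prr`, `chi2`, `infinite`.
#' @export
prr <- function(table, yates = TRUE) {
  cl <- .as_cells(table)
  if (cl$a + cl$b == 0 || cl$c + cl$d == 0) {
    stop("prr: requires a + b > 0 and c + d > 0")
  }
  r <- .prr_vec(cl$a, cl$b, cl$c, cl$d, yates = yates)
  list(prr = r$prr, chi2 = r$chi2, infinite = r$prr_infinite)
}

#' Bayesian information component
#'
#' IC = log2((a + 0.5) / (E + 0.5)) with E = (a+b)(a+c)/N, the
#' observed-to-expected shrinkage measure. Credible bounds (IC025, IC975)
#' come from the quantiles of the Gamma(a + 0.5, E + 0.5) posterior of the
#' Poisson intensity ratio (default), or from a polynomial approximation
#' accurate only at large counts (`method = "approx"`).
#'
#' @inheritParams ror
#' @param method `"gamma"` (exact posterior quantiles, default) or
#'   `"approx"`.
#' @param conf credibility level (default 0.95).
#' @return list with `ic`, `ic_low`, `ic_high`, `expected`.
#' @export
ic <- function(table, method = c("gamma", "approx"), conf = 0.95) {
  cl <- .as_cells(table)
  r <- .ic_vec(cl$a, cl$b, cl$c, cl$d, method = method, conf = conf)
  list(ic = r$ic, ic_low = r$ic_low, ic_high = r$ic_high, expected = r$ic_expected)
}

#' Composite signal criteria
#'
#' The screening thresholds: a drug-event pair is a signal when at least one
#' of (i) the lower 95% bound of ROR exceeds 1, (ii) PRR > 1 with
#' chi-square > 4, (iii) IC025 > 0 holds, and the pair has at least
#' `min_cases` reports. The minimum-case rule binds all three clauses by
#' default (`apply_min_cases_ic = FALSE` restricts it to ROR and PRR).
#'
#' @param min_cases minimum number of reports (default 3).
#' @param ror_low_threshold,prr_threshold,chi2_threshold,ic_low_threshold
#'   the clause thresholds (defaults 1, 1, 4, 0).
#' @param z normal quantile for the ROR interval (default 1.96).
#' @param apply_min_cases_ic also require `min_cases` for the IC clause
#'   (default TRUE).
#' @return list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_cases = 3, ror_low_threshold = 1,
                            prr_threshold = 1, chi2_threshold = 4,
                            ic_low_threshold = 0, z = 1.96,
                            apply_min_cases_ic = TRUE) {
  stopifnot(min_cases >= 1, is.finite(c(ror_low_threshold, prr_threshold,
                                        chi2_threshold, ic_low_threshold, z)))
  structure(list(min_cases = min_cases, ror_low_threshold = ror_low_threshold,
                 prr_threshold = prr_threshold, chi2_threshold = chi2_threshold,
                 ic_low_threshold = ic_low_threshold, z = z,
                 apply_min_cases_ic = apply_min_cases_ic),
            class = "signal_criteria")
}

#' Apply the composite signal criteria to computed statistics
#'
#' @param x data.frame with columns `n`, `ror_low`, `prr`, `chi2`, `ic_low`.
#' @param criteria a [signal_criteria()].
#' @return `x` with logical columns `ror_signal`, `prr_signal`, `ic_signal`,
#'   `any_signal` appended.
#' @export
evaluate_signal <- function(x, criteria = signal_criteria()) {
  n_ok <- x$n >= criteria$min_cases
  x$ror_signal <- !is.na(x$ror_low) & x$ror_low > criteria$ror_low_threshold & n_ok
  x$prr_signal <- !is.na(x$prr) & !is.na(x$chi2) &
    x$prr > criteria$prr_threshold & x$chi2 > criteria$chi2_threshold & n_ok
  ic_ok <- if (criteria$apply_min_cases_ic) n_ok else TRUE
  x$ic_signal <- !is.na(x$ic_low) & x$ic_low > criteria$ic_low_threshold & ic_ok
  x$any_signal <- (x$ror_signal | x$prr_signal | x$ic_signal) & n_ok
  x
}

# compute all statistics for vectors of cells; returns a data.frame
.signal_stats <- function(a, b, c, d, criteria = signal_criteria(),
                          ic_method = "gamma") {
  out <- cbind(data.frame(n = a, a = a, b = b, c = c, d = d),
               .ror_vec(a, b, c, d, z = criteria$z),
               .prr_vec(a, b, c, d),
               .ic_vec(a, b, c, d, method = ic_method))
  evaluate_signal(out, criteria)
}

#' Disproportionality screen for drug-event pairs
#'
#' The core estimator: builds the 2x2 table for each requested drug selector
#' against each event selector over the supplied report database, computes
#' ROR (Wald interval), PRR (Yates chi-square) and IC (gamma credible
#' bounds), and applies the composite signal criteria.
#'
#' @param reports a `safety_reports` database including background reports.
#' @param drugs named list of drug selectors (see [build_contingency()]); a
#'   bare character vector is treated as one selector per substance.
#' @param events named list of event selectors; a bare character vector is
#'   treated as a single event set; a [pt_catalog()] expands to one selector
#'   per PT.
#' @param unit counting unit, `"record"` (default) or `"case"`.
#' @param criteria a [signal_criteria()].
#' @param ic_method IC interval method, `"gamma"` or `"approx"`.
#' @param roles qualifying drug roles (default `"PS"`).
#' @return data.frame of class `disprop`: one row per drug x event with the
#'   cells, all statistics and the signal flags.
#' @export
disprop <- function(reports, drugs, events, unit = c("record", "case"),
                    criteria = signal_criteria(), ic_method = c("gamma", "approx"),
                    roles = "PS") {
  unit <- match.arg(unit)
  ic_method <- match.arg(ic_method)
  if (is.character(drugs)) drugs <- stats::setNames(as.list(drugs), drugs)
  if (inherits(events, "pt_catalog")) {
    events <- stats::setNames(as.list(events$pt), events$pt)
  } else if (is.character(events)) {
    events <- stats::setNames(list(events), paste(events[1],
      if (length(events) > 1) sprintf("(+%d)", length(events) - 1) else ""))
    names(events) <- trimws(names(events))
  }
  rows <- list()
  for (dn in names(drugs)) {
    for (en in names(events)) {
      tab <- build_contingency(reports, drugs[[dn]], events[[en]],
                               unit = unit, roles = roles)
      st <- .signal_stats(tab$a, tab$b, tab$c, tab$d, criteria, ic_method)
      st <- cbind(data.frame(drug = dn, event = en, stringsAsFactors = FALSE), st)
      rows[[length(rows) + 1L]] <- st
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  attr(out, "criteria") <- criteria
  class(out) <- c("disprop", "data.frame")
  out
}

#' @export
print.disprop <- function(x, digits = 2, ...) {
  cat("Disproportionality screen (", attr(x, "unit"), " unit, ",
      nrow(x), " drug-event pairs)\n\n", sep = "")
  show <- data.frame(
    drug = x$drug, event = x$event, n = x$n,
    ROR = sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
                  x$ror, x$ror_low, x$ror_high),
    PRR = sprintf(paste0("%.", digits, "f (%.", digits, "f)"), x$prr, x$chi2),
    IC = sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
                 x$ic, x$ic_low, x$ic_high),
    signal = ifelse(x$any_signal, "*", ""))
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.disprop <- function(object, ...) {
  cat("pairs screened: ", nrow(object),
      "; signals: ", sum(object$any_signal),
      " (ROR ", sum(object$ror_signal),
      ", PRR ", sum(object$prr_signal),
      ", IC ", sum(object$ic_signal), ")\n", sep = "")
  invisible(object)
}

#' Comparative reporting odds ratio between two report groups
#'
#' Restricts the database to the union of two disjoint groups and crosses
#' group membership against event occurrence (case unit): ROR > 1 means the
#' event is reported relatively more often in group A.
#'
#' @param reports a `safety_reports` database.
#' @param group_a,group_b case selectors (logical vectors over cases,
#'   functions, or character vectors of regimen-class labels matched against
#'   `cases$regimen_class`).
#' @param event event selector as in [build_contingency()].
#' @param z normal quantile (default 1.96).
#' @return list with `ror`, `ror_low`, `ror_high`, `corrected` and the cells.
#' @export
comparative_ror <- function(reports, group_a, group_b, event, z = 1.96) {
  resolve <- function(sel) {
    if (is.logical(sel)) { stopifnot(length(sel) == nrow(reports$cases)); sel }
    else if (is.function(sel)) sel(reports)
    else reports$cases$regimen_class %in% sel
  }
  ga <- resolve(group_a); gb <- resolve(group_b)
  if (any(ga & gb)) stop("comparative_ror: groups must be disjoint")
  if (!any(ga) || !any(gb)) stop("comparative_ror: a group has zero reports")
  ev <- .case_has_event(reports, event)
  a <- sum(ga & ev); b <- sum(ga & !ev); c <- sum(gb & ev); d <- sum(gb & !ev)
  r <- .ror_vec(a, b, c, d, z = z)
  list(ror = r$ror, ror_low = r$ror_low, ror_high = r$ror_high,
       corrected = r$ror_corrected, a = a, b = b, c = c, d = d)
}

#' Drug-by-event signal spectrum
#'
#' One [disprop]-style row per (regimen, preferred term) pair with at least
#' one co-report; pairs below the minimum case count keep their statistics
#' but carry all-FALSE flags; pairs with zero co-reports are absent.
#'
#' @param reports a classified `safety_reports` database (with `regimen`).
#' @param regimens character vector of regimen labels (default: all observed
#'   ICI regimens in the database).
#' @param catalog a [pt_catalog()].
#' @param criteria a [signal_criteria()].
#' @param unit counting unit (default `"record"`).
#' @return data.frame of class `signal_spectrum` (long format) with an
#'   attribute matrix `ror025` (regimen x PT lower bounds, NA where absent).
#' @export
signal_spectrum <- function(reports, regimens = NULL, catalog = pt_catalog(),
                            criteria = signal_criteria(),
                            unit = c("record", "case")) {
  unit <- match.arg(unit)
  if (!"regimen" %in% names(reports$cases)) {
    stop("signal_spectrum: run classify_regimens() first")
  }
  if (is.null(regimens)) {
    regimens <- sort(unique(reports$cases$regimen[!is.na(reports$cases$regimen)]))
  }
  rows <- list()
  for (rg in regimens) {
    sel <- !is.na(reports$cases$regimen) & reports$cases$regimen == rg
    for (pt in catalog$pt) {
      tab <- tryCatch(build_contingency(reports, sel, pt, unit = unit),
                      error = function(e) NULL)
      if (is.null(tab) || tab$a == 0) next
      st <- .signal_stats(tab$a, tab$b, tab$c, tab$d, criteria)
      st <- cbind(data.frame(regimen = rg, pt = pt, stringsAsFactors = FALSE), st)
      rows[[length(rows) + 1L]] <- st
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(regimen = character(0), pt = character(0)),
          .signal_stats(integer(0), integer(0), integer(0), integer(0), criteria))
  rownames(out) <- NULL
  m <- matrix(NA_real_, length(regimens), nrow(catalog),
              dimnames = list(regimens, catalog$pt))
  if (nrow(out)) m[cbind(out$regimen, out$pt)] <- out$ror_low
  attr(out, "ror025") <- m
  attr(out, "unit") <- unit
  class(out) <- c("signal_spectrum", "data.frame")
  out
}

#' @export
print.signal_spectrum <- function(x, ...) {
  cat("Signal spectrum: ", nrow(x), " non-empty cells, ",
      sum(x$any_signal), " flagged\n", sep = "")
  m <- attr(x, "ror025")
  cat("ROR025 matrix: ", nrow(m), " regimens x ", ncol(m), " PTs\n", sep = "")
  invisible(x)
}

#' Serialise a signal spectrum to JSON
#'
#' Writes the long table plus the ROR025 matrix with significance marks,
#' mirroring a heat-map style spectrum figure.
#'
#' @param spectrum a [signal_spectrum()] result.
#' @param path output file.
#' @export
write_spectrum_json <- function(spectrum, path) {
  m <- attr(spectrum, "ror025")
  doc <- list(
    unit = attr(spectrum, "unit"),
    regimens = rownames(m),
    pts = colnames(m),
    ror025 = ifelse(is.na(m), NA, round(m, 2)),
    cells = spectrum[, c("regimen", "pt", "n", "ror", "ror_low", "ror_high",
                         "prr", "chi2", "ic", "ic_low", "ic_high",
                         "ror_signal", "prr_signal", "ic_signal", "any_signal")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 6, na = "null",
                       matrix = "rowmajor")
  invisible(path)
}
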