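.age_bands <- function(age) {
  band <- rep("Unknown", length(age))
  band[!is.na(age) & age < 18] <- "<18"
  band[!is.na(age) & age >= 18 & age < 65] <- "18-64"
  band[!is.na(age) & age >= 65] <- ">=65"
  factor(band, levels = c("<18", "18-64", ">=65", "Unknown"))
}

.tto_bands <- function(tto) {
  band <- rep("Unknown", length(tto))
  band[!is.na(tto) & tto <= 30] <- "0-30"
  band[!is.na(tto) & tto > 30 & tto <= 60] <- "31-60"
  band[!is.na(tto) & tto > 60 & tto <= 90] <- "61-90"
  band[!is.na(tto) & tto > 90 & tto <= 180] <- "91-180"
  band[!is.na(tto) & tto > 180] <- ">180"
  factor(band, levels = c("0-30", "31-60", "61-90", "91-180", ">180", "Unknown"))
}

# one exclusive outcome level per case, by severity precedence
.outcome_levels <- c(DE = "Death", LT = "Life-threatening", DS = "Disability",
                     HO = "Hospitalization", RI = "Required intervention",
                     CA = "Congenital anomaly", OT = "Other outcomes")
.outcome_level <- function(codes) {
  sets <- strsplit(codes, ";", fixed = TRUE)
  vapply(sets, function(s) {
    for (code in names(.outcome_levels)) {
      if (code %in% s) return(.outcome_levels[[code]])
    }
    "Non-serious"
  }, character(1))
}

.sex_levels <- c(F = "Female", M = "Male", U = "Unknown")

# characteristic levels for one report collection, as a named list of factors
.characteristics <- function(cases) {
  out <- list(
    sex = factor(.sex_levels[cases$sex], levels = unname(.sex_levels)),
    age_band = .age_bands(cases$age_years),
    reporting_year = factor(ifelse(is.na(cases$report_date), "Unknown",
                                   format(cases$report_date, "%Y"))),
    continent = factor(cases$continent,
                       levels = c("Europe", "America", "Asia", "Oceania",
                                  "Africa", "Unknown")),
    indication_group = factor(cases$indication_group),
    outcome = factor(.outcome_level(cases$outcome_codes),
                     levels = c(unname(.outcome_levels), "Non-serious"))
  )
  if ("tto_days" %in% names(cases)) out$tto_band <- .tto_bands(cases$tto_days)
  if ("regimen" %in% names(cases)) {
    out$regimen <- factor(cases$regimen)
    out$regimen_class <- factor(cases$regimen_class)
  }
  out
}

.median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Descriptive cohort summary
#'
#' Counts and percents of the cohort by sex, age band (<18, 18-64, >=65,
#' unknown), reporting year, continent, indication group, outcome (one
#' exclusive level per case by severity precedence: death, life-threatening,
#' disability, hospitalisation, required intervention, congenital anomaly,
#' other, non-serious), time-to-onset band and regimen, plus median/IQR for
#' age and TTO (linear-interpolation quantiles). For TTO bands a share among
#' known-TTO cases is reported alongside the share of the whole cohort.
#'
#' @param reports a `safety_reports` collection (ideally selected, classified
#'   and TTO-annotated).
#' @return list of class `cohort_summary`: `n`, `strata` (data.frame with
#'   `characteristic`, `level`, `n`, `pct`, `pct_known`), `age`, `tto`
#'   (median/quartiles).
#' @export
cohort_summary <- function(reports) {
  cases <- reports$cases
  n <- nrow(cases)
  chars <- .characteristics(cases)
  strata <- do.call(rbind, lapply(names(chars), function(ch) {
    tab <- table(chars[[ch]])
    if (!length(tab)) return(NULL)
    data.frame(characteristic = ch, level = names(tab), n = as.integer(tab),
               pct = .pct(as.integer(tab), n), stringsAsFactors = FALSE)
  }))
  strata$pct_known <- NA_real_
  if ("tto_band" %in% names(chars)) {
    known <- sum(!is.na(cases$tto_days))
    idx <- strata$characteristic == "tto_band" & strata$level != "Unknown"
    strata$pct_known[idx] <- .pct(strata$n[idx], known)
  }
  rownames(strata) <- NULL
  structure(list(n = n, strata = strata,
                 age = .median_iqr(cases$age_years),
                 tto = if ("tto_days" %in% names(cases))
                         .median_iqr(cases$tto_days) else NULL),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of ", x$n, " cases\n", sep = "")
  if (!all(is.na(x$age))) {
    cat(sprintf("  age: median %.5g (IQR %.5g-%.5g)\n",
                x$age["median"], x$age["q1"], x$age["q3"]))
  }
  if (!is.null(x$tto) && !all(is.na(x$tto))) {
    cat(sprintf("  TTO: median %.5g (IQR %.5g-%.5g) days\n",
                x$tto["median"], x$tto["q1"], x$tto["q3"]))
  }
  for (ch in unique(x$strata$characteristic)) {
    s <- x$strata[x$strata$characteristic == ch, ]
    cat("  ", ch, ": ",
        paste(s$level, " ", s$n, " (", s$pct, "%)", sep = "", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Look up one stratum count/percent from a cohort summary
#' @param x a `cohort_summary`; @param characteristic,level the stratum.
#' @param value `"pct"`, `"n"` or `"pct_known"`.
#' @export
stratum <- function(x, characteristic, level, value = "pct") {
  s <- x$strata
  hit <- s$characteristic == characteristic & s$level == level
  if (!any(hit)) return(NA_real_)
  s[[value]][hit][1]
}

#' Compare fatal and non-fatal cases
#'
#' Categorical characteristics are tested with a chi-square on the
#' characteristic-by-fatality contingency (unknown levels excluded from the
#' test but kept in summaries); age and TTO with a two-sided Wilcoxon
#' rank-sum test. Characteristics with a single observed level are skipped
#' with a notice.
#'
#' @param reports a `safety_reports` collection with both fatal and
#'   non-fatal cases.
#' @return data.frame of class `group_comparison` with `characteristic`,
#'   `test`, `statistic`, `p_value`, `note`.
#' @export
compare_fatal_nonfatal <- function(reports) {
  cases <- reports$cases
  if (!any(cases$died) || all(cases$died)) {
    stop("compare_fatal_nonfatal: need both fatal and non-fatal cases")
  }
  chars <- .characteristics(cases)
  chars$outcome <- NULL  # outcome defines the grouping itself
  rows <- list()
  for (ch in names(chars)) {
    lv <- as.character(chars[[ch]])
    keep <- !(lv %in% "Unknown")
    tab <- table(lv[keep], cases$died[keep])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      rows[[ch]] <- data.frame(characteristic = ch, test = "chi-square",
                               statistic = NA_real_, p_value = NA_real_,
                               note = "skipped: single observed level")
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab))
    rows[[ch]] <- data.frame(characteristic = ch, test = "chi-square",
                             statistic = unname(ct$statistic),
                             p_value = ct$p.value, note = "")
  }
  for (v in c("age_years", "tto_days")) {
    if (!v %in% names(cases)) next
    x <- cases[[v]][cases$died]; y <- cases[[v]][!cases$died]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) next
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    rows[[v]] <- data.frame(characteristic = v, test = "rank-sum",
                            statistic = unname(wt$statistic),
                            p_value = wt$p.value, note = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Time to onset by regimen
#'
#' Per-regimen median and IQR of known TTO plus an omnibus Kruskal-Wallis
#' test across regimens with at least `min_n` known TTO values; optional
#' pairwise rank-sum tests.
#'
#' @param reports a classified, TTO-annotated `safety_reports` collection.
#' @param min_n minimum known TTO count for a regimen to enter the omnibus
#'   test (default 5).
#' @param pairwise also compute pairwise Wilcoxon tests (default FALSE).
#' @return list with `table` (regimen, n_known, median, q1, q3), `test`
#'   (kruskal.test result) and optionally `pairwise`.
#' @export
tto_by_regimen <- function(reports, min_n = 5, pairwise = FALSE) {
  cases <- reports$cases
  if (!"tto_days" %in% names(cases)) stop("tto_by_regimen: run add_tto() first")
  if (!"regimen" %in% names(cases)) stop("tto_by_regimen: run classify_regimens() first")
  known <- !is.na(cases$tto_days)
  if (!any(known)) stop("tto_by_regimen: no known TTO values")
  per <- split(cases$tto_days[known], cases$regimen[known])
  tab <- do.call(rbind, lapply(names(per), function(rg) {
    q <- .median_iqr(per[[rg]])
    data.frame(regimen = rg, n_known = length(per[[rg]]),
               median = q["median"], q1 = q["q1"], q3 = q["q3"],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  eligible <- tab$regimen[tab$n_known >= min_n]
  test <- NULL
  if (length(eligible) >= 2) {
    sub <- known & cases$regimen %in% eligible
    test <- stats::kruskal.test(cases$tto_days[sub], factor(cases$regimen[sub]))
  }
  out <- list(table = tab, test = test)
  if (pairwise && length(eligible) >= 2) {
    sub <- known & cases$regimen %in% eligible
    out$pairwise <- stats::pairwise.wilcox.test(
      cases$tto_days[sub], factor(cases$regimen[sub]),
      p.adjust.method = "none", exact = FALSE)
  }
  out
}

#' Case-fatality proportions by stratum
#'
#' Deaths divided by total reports within each stratum, times 100, rounded
#' to 2 decimals. With `by = "event_group"` every case contributes to each
#' event group in which it has at least one qualifying PT, so group totals
#' may exceed the cohort size (multi-PT cases are intentionally counted in
#' every matching group).
#'
#' @param reports a `safety_reports` collection.
#' @param by `"regimen"`, `"event_group"`, `"continent"` or `"overall"`.
#' @param catalog a [pt_catalog()] (used for `by = "event_group"`).
#' @return data.frame of class `fatality_table` with `stratum`, `n_reports`,
#'   `n_deaths`, `fatality_pct`; empty strata are omitted.
#' @export
fatality_rates <- function(reports, by = c("regimen", "event_group",
                                           "continent", "overall"),
                           catalog = pt_catalog()) {
  by <- match.arg(by)
  cases <- reports$cases
  if (by == "overall") {
    groups <- list(overall = cases$died)
  } else if (by == "event_group") {
    r <- reports$reactions
    grp <- catalog$group[match(tolower(r$pt), tolower(catalog$pt))]
    keep <- !is.na(grp)
    pair <- unique(data.frame(case_id = r$case_id[keep], group = grp[keep],
                              stringsAsFactors = FALSE))
    pair$died <- cases$died[match(pair$case_id, cases$case_id)]
    groups <- split(pair$died, pair$group)
  } else {
    key <- if (by == "regimen") cases$regimen else cases$continent
    groups <- split(cases$died, key)
  }
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  out <- do.call(rbind, lapply(names(groups), function(g) {
    died <- groups[[g]]
    data.frame(stratum = g, n_reports = length(died),
               n_deaths = sum(died),
               fatality_pct = .pct(sum(died), length(died)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("fatality_table", "data.frame")
  out
}

#' Table-1-shaped fatal/non-fatal summary
#'
#' One row per characteristic level with total, fatal and non-fatal counts
#' and percents (percents within the respective column totals) and the
#' chi-square or rank-sum p-value of the fatal vs non-fatal contrast for the
#' characteristic, repeated down its rows.
#'
#' @param reports a `safety_reports` collection.
#' @return data.frame with columns `characteristic`, `level`, `total_n`,
#'   `total_pct`, `fatal_n`, `fatal_pct`, `nonfatal_n`, `nonfatal_pct`,
#'   `p_value`.
#' @export
table1_table <- function(reports) {
  cases <- reports$cases
  chars <- .characteristics(cases)
  n <- nrow(cases); nf <- sum(cases$died); nn <- n - nf
  cmp <- if (nf > 0 && nn > 0) compare_fatal_nonfatal(reports) else NULL
  out <- do.call(rbind, lapply(names(chars), function(ch) {
    tot <- table(chars[[ch]])
    fat <- table(chars[[ch]][cases$died])
    non <- table(chars[[ch]][!cases$died])
    p <- if (!is.null(cmp) && ch %in% cmp$characteristic) {
      cmp$p_value[cmp$characteristic == ch][1]
    } else NA_real_
    data.frame(characteristic = ch, level = names(tot),
               total_n = as.integer(tot), total_pct = .pct(as.integer(tot), n),
               fatal_n = as.integer(fat[names(tot)]),
               fatal_pct = .pct(as.integer(fat[names(tot)]), nf),
               nonfatal_n = as.integer(non[names(tot)]),
               nonfatal_pct = .pct(as.integer(non[names(tot)]), nn),
               p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
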