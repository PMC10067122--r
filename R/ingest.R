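#' Parse one quarter of FAERS-style ASCII tables
#'
#' Reads the `$`-delimited quarterly tables (DEMO, DRUG, REAC, OUTC, THER,
#' INDI) as distributed by the FDA. Headers are matched case-insensitively;
#' the legacy (pre-2012Q3) `ISR`/`CASE` keys are normalised to
#' `primaryid`/`caseid`. Lines whose field count disagrees with the header
#' are counted and skipped, never fatal. Rows in the satellite tables whose
#' `primaryid` does not occur in DEMO are dropped and counted as orphans.
#'
#' @param paths named character vector or list of file paths; names from
#'   `demo`, `drug`, `reac`, `outc`, `ther`, `indi` (case-insensitive).
#'   `demo`, `drug` and `reac` are mandatory.
#' @param quarter quarter label such as `"2019Q2"`.
#' @return A list of class `raw_recordset` with one data.frame per table
#'   (character columns), the `quarter` label, and a `counters` list
#'   (`malformed`, `orphans`).
#' @export
parse_quarter <- function(paths, quarter) {
  if (!grepl("^[0-9]{4}Q[1-4]$", quarter)) {
    stop("quarter label must match YYYYQn, got: ", quarter)
  }
  names(paths) <- tolower(names(paths))
  for (t in c("demo", "drug", "reac")) {
    if (is.null(paths[[t]])) stop("parse_quarter: missing mandatory table: ", toupper(t))
  }
  mandatory <- list(demo = c("primaryid", "caseid"),
                    drug = c("primaryid", "drugname", "role_cod"),
                    reac = c("primaryid", "pt"))
  counters <- list(malformed = 0L, orphans = 0L)
  tabs <- list()
  for (t in names(paths)) {
    path <- paths[[t]]
    if (!file.exists(path)) stop("parse_quarter: file not found: ", path)
    df <- .read_dollar_table(path)
    counters$malformed <- counters$malformed + attr(df, "malformed")
    need <- mandatory[[t]]
    if (!is.null(need)) {
      miss <- setdiff(need, names(df))
      if (length(miss)) {
        stop("parse_quarter: ", path, " lacks mandatory column(s): ",
             paste(miss, collapse = ", "))
      }
    }
    tabs[[t]] <- df
  }
  # referential integrity against DEMO
  keep <- unique(tabs$demo$primaryid)
  for (t in setdiff(names(tabs), "demo")) {
    orphan <- !(tabs[[t]]$primaryid %in% keep)
    counters$orphans <- counters$orphans + sum(orphan)
    tabs[[t]] <- tabs[[t]][!orphan, , drop = FALSE]
  }
  structure(c(tabs, list(quarter = quarter, counters = counters)),
            class = "raw_recordset")
}

# read a $-delimited table with a header line; returns character data.frame
# with lowercased, legacy-normalised column names and a "malformed" attribute
.read_dollar_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("parse_quarter: empty file: ", path)
  header <- tolower(strsplit(lines[[1]], "$", fixed = TRUE)[[1]])
  header[header == "isr"] <- "primaryid"
  header[header == "case"] <- "caseid"
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad them back
  n <- lengths(parts)
  pad <- function(p) c(p, rep("", length(header) - length(p)))
  ok <- n <= length(header)
  malformed <- sum(!ok)
  parts <- lapply(parts[ok], pad)
  if (length(parts)) {
    m <- do.call(rbind, parts)
  } else {
    m <- matrix(character(0), 0, length(header))
  }
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "malformed") <- malformed
  df
}

#' Combine several quarterly record sets
#'
#' @param recordsets list of `raw_recordset` objects.
#' @return one `raw_recordset` whose tables are the row-binds of the inputs.
#' @export
bind_recordsets <- function(recordsets) {
  stopifnot(length(recordsets) >= 1)
  tables <- setdiff(Reduce(union, lapply(recordsets, names)), c("quarter", "counters"))
  out <- list()
  for (t in tables) {
    parts <- Filter(Negate(is.null), lapply(recordsets, `[[`, t))
    all_names <- Reduce(union, lapply(parts, names))
    parts <- lapply(parts, function(p) {
      for (nm in setdiff(all_names, names(p))) p[[nm]] <- NA_character_
      p[, all_names, drop = FALSE]
    })
    out[[t]] <- do.call(rbind, parts)
    rownames(out[[t]]) <- NULL
  }
  out$quarter <- paste(vapply(recordsets, `[[`, character(1), "quarter"), collapse = ",")
  cnt <- list()
  for (rs in recordsets) {
    for (nm in names(rs$counters)) {
      cnt[[nm]] <- (cnt[[nm]] %||% 0L) + rs$counters[[nm]]
    }
  }
  out$counters <- cnt
  structure(out, class = "raw_recordset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deduplicate case versions
#'
#' FAERS ships revisions of the same case as separate `primaryid`s sharing a
#' `caseid`. For each case only the most recent version is retained: the one
#' with the highest FDA receipt date (`fda_dt`), ties broken by the highest
#' `primaryid`. All satellite tables are filtered to the retained versions.
#'
#' @param rs a `raw_recordset`.
#' @return the deduplicated `raw_recordset`; `counters` gains `cases_in`,
#'   `cases_out` and `versions_dropped`.
#' @export
deduplicate <- function(rs) {
  demo <- rs$demo
  if (!"caseid" %in% names(demo)) stop("deduplicate: DEMO lacks caseid")
  fda <- if ("fda_dt" %in% names(demo)) demo$fda_dt else rep("", nrow(demo))
  fda[is.na(fda)] <- ""
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  ord <- order(demo$caseid, fda, pid_num)      # last within case = retained
  demo_o <- demo[ord, , drop = FALSE]
  last <- !duplicated(demo_o$caseid, fromLast = TRUE)
  keep_pid <- demo_o$primaryid[last]
  out <- rs
  out$demo <- demo_o[last, , drop = FALSE]
  rownames(out$demo) <- NULL
  for (t in setdiff(names(rs), c("demo", "quarter", "counters"))) {
    if (is.data.frame(rs[[t]])) {
      out[[t]] <- rs[[t]][rs[[t]]$primaryid %in% keep_pid, , drop = FALSE]
      rownames(out[[t]]) <- NULL
    }
  }
  out$counters$cases_in <- nrow(demo)
  out$counters$cases_out <- length(keep_pid)
  out$counters$versions_dropped <- nrow(demo) - length(keep_pid)
  out
}

# age-unit codes to years-per-unit
.age_unit_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25)

#' Assemble SafetyReport records from a deduplicated record set
#'
#' Converts ages to years by the FAERS age-unit code (DEC x10, YR x1,
#' MON /12, WK /52, DY /365.25; anything else becomes missing and is
#' counted), maps the reporting country to a continent through the bundled
#' table, canonicalises drug names against the dictionary, attaches reaction
#' PTs, outcome codes (setting `died` from the `DE` code) and therapy dates,
#' and groups free-text indications by the bundled keyword map.
#'
#' @param rs a deduplicated `raw_recordset`.
#' @param dict a [drug_dictionary()].
#' @return a [safety_reports()] collection. Cases with no reaction rows are
#'   dropped and counted (`no_reaction`).
#' @export
build_reports <- function(rs, dict = drug_dictionary()) {
  demo <- rs$demo
  counters <- rs$counters %||% list()
  get_col <- function(df, nm) if (nm %in% names(df)) df[[nm]] else rep(NA_character_, nrow(df))

  # age in years
  age_raw <- suppressWarnings(as.numeric(get_col(demo, "age")))
  unit <- toupper(trimws(get_col(demo, "age_cod")))
  unit[unit == ""] <- NA
  fac <- unname(.age_unit_factor[unit])
  age <- age_raw * fac
  bad_unit <- !is.na(age_raw) & !is.na(unit) & is.na(fac)
  if (any(bad_unit)) {
    warning(sum(bad_unit), " age value(s) with unmappable unit set to missing")
  }
  counters$bad_age_unit <- sum(bad_unit)
  out_of_range <- !is.na(age) & (age < 0 | age > 120)
  counters$age_out_of_range <- sum(out_of_range)
  age[out_of_range] <- NA

  sex_raw <- toupper(trimws(get_col(demo, "sex")))
  sex <- ifelse(sex_raw %in% c("M", "F"), sex_raw, "U")

  country <- toupper(trimws(get_col(demo, "occr_country")))
  blank <- is.na(country) | country == ""
  rep_cty <- toupper(trimws(get_col(demo, "reporter_country")))
  country[blank] <- rep_cty[blank]
  country[is.na(country) | country == ""] <- NA
  cmap <- continent_map()
  continent <- unname(cmap[country])
  continent[is.na(continent)] <- "Unknown"

  report_date <- parse_faers_date(get_col(demo, "fda_dt"))
  event_date <- parse_faers_date(get_col(demo, "event_dt"))

  # indication: first INDI row per case, keyword-mapped to a group
  indication <- rep(NA_character_, nrow(demo))
  if (!is.null(rs$indi) && nrow(rs$indi)) {
    first <- rs$indi[!duplicated(rs$indi$primaryid), , drop = FALSE]
    indication <- first$indi_pt[match(demo$primaryid, first$primaryid)]
  }
  imap <- indication_map()
  igroup <- rep("Other", nrow(demo))
  ind_lc <- tolower(ifelse(is.na(indication), "", indication))
  for (i in seq_len(nrow(imap))) {
    hit <- igroup == "Other" & grepl(imap$keyword[i], ind_lc, fixed = TRUE)
    igroup[hit] <- imap$group[i]
  }
  igroup[is.na(indication) | ind_lc == ""] <- "Other"

  # outcomes
  codes <- rep("", nrow(demo))
  if (!is.null(rs$outc) && nrow(rs$outc)) {
    oc <- rs$outc
    cc <- toupper(trimws(get_col(oc, "outc_cod")))
    sp <- split(cc, oc$primaryid)
    joined <- vapply(sp, function(x) paste(sort(unique(x)), collapse = ";"), character(1))
    m <- match(demo$primaryid, names(joined))
    codes[!is.na(m)] <- joined[m[!is.na(m)]]
  }
  died <- vapply(strsplit(codes, ";", fixed = TRUE), function(x) "DE" %in% x, logical(1))

  cases <- data.frame(
    case_id = get_col(demo, "caseid"),
    primary_id = demo$primaryid,
    sex = sex, age_years = age,
    country = country, continent = continent,
    report_date = report_date, event_date = event_date,
    indication = indication, indication_group = igroup,
    outcome_codes = codes, died = died,
    stringsAsFactors = FALSE
  )

  # drugs: canonicalise names, attach therapy start dates
  dr <- rs$drug
  verb <- toupper(trimws(get_col(dr, "drugname")))
  substance <- rep("other", nrow(dr))
  for (i in seq_len(nrow(dict))) {
    hit <- substance == "other" & grepl(dict$variant[i], verb, fixed = TRUE)
    substance[hit] <- dict$substance[i]
  }
  # prod_ai (active ingredient) as a fallback matcher
  if ("prod_ai" %in% names(dr)) {
    ai <- toupper(trimws(dr$prod_ai))
    for (i in seq_len(nrow(dict))) {
      hit <- substance == "other" & grepl(dict$variant[i], ai, fixed = TRUE)
      substance[hit] <- dict$substance[i]
    }
  }
  role <- toupper(trimws(get_col(dr, "role_cod")))
  role[!role %in% c("PS", "SS", "C", "I")] <- NA
  seq_raw <- suppressWarnings(as.integer(get_col(dr, "drug_seq")))
  seq_raw[is.na(seq_raw)] <- seq_len(nrow(dr))[is.na(seq_raw)]
  drugs <- data.frame(
    case_id = cases$case_id[match(dr$primaryid, cases$primary_id)],
    drug_seq = seq_raw,
    verbatim_name = get_col(dr, "drugname"),
    substance = substance, role = role,
    start_raw = NA_character_, end_raw = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(rs$ther) && nrow(rs$ther)) {
    th <- rs$ther
    th_seq <- suppressWarnings(as.integer(get_col(th, "dsg_drug_seq")))
    key <- paste(th$primaryid, th_seq)
    dkey <- paste(dr$primaryid, seq_raw)
    m <- match(dkey, key)
    drugs$start_raw <- trimws(get_col(th, "start_dt"))[m]
    drugs$end_raw <- trimws(get_col(th, "end_dt"))[m]
    drugs$start_raw[!is.na(drugs$start_raw) & drugs$start_raw == ""] <- NA
    drugs$end_raw[!is.na(drugs$end_raw) & drugs$end_raw == ""] <- NA
  }

  reactions <- data.frame(
    case_id = cases$case_id[match(rs$reac$primaryid, cases$primary_id)],
    pt = trimws(rs$reac$pt),
    stringsAsFactors = FALSE
  )
  reactions <- reactions[!is.na(reactions$pt) & reactions$pt != "", , drop = FALSE]

  # a safety report must carry at least one reaction
  with_reac <- cases$case_id %in% reactions$case_id
  counters$no_reaction <- sum(!with_reac)
  cases <- cases[with_reac, , drop = FALSE]
  drugs <- drugs[drugs$case_id %in% cases$case_id, , drop = FALSE]
  reactions <- reactions[reactions$case_id %in% cases$case_id, , drop = FALSE]

  safety_reports(cases, drugs, reactions, counters = counters)
}

#' Select cases with an ICI as primary suspect and a qualifying arrhythmia PT
#'
#' A case is retained iff it has at least one drug whose canonical substance
#' is in the dictionary with role `PS` (primary suspect), and at least one
#' reaction PT in the catalogue (case-insensitive exact match).
#'
#' @param reports a `safety_reports` collection.
#' @param dict a [drug_dictionary()].
#' @param catalog a [pt_catalog()].
#' @return the filtered `safety_reports`.
#' @export
select_cases <- function(reports, dict = drug_dictionary(), catalog = pt_catalog()) {
  subs <- unique(dict$substance)
  d <- reports$drugs
  drug_ok <- unique(d$case_id[!is.na(d$role) & d$role == "PS" & d$substance %in% subs])
  r <- reports$reactions
  pt_ok <- unique(r$case_id[tolower(r$pt) %in% tolower(catalog$pt)])
  keep <- reports$cases$case_id[reports$cases$case_id %in% drug_ok &
                                reports$cases$case_id %in% pt_ok]
  counters <- reports$counters
  counters$selected <- length(keep)
  .filter_cases(reports, keep, counters = counters)
}

#' Classify an ICI exposure into a regimen label
#'
#' One distinct ICI substance among suspect-role drugs gives monotherapy of
#' that agent with its class (anti-PD-1, anti-PD-L1, anti-CTLA-4); two or
#' more give combination therapy, matched against the named pairs
#' (ipilimumab + nivolumab, ipilimumab + pembrolizumab, tremelimumab +
#' durvalumab, pembrolizumab + atezolizumab) or "other combination".
#' Suspect roles are PS and SS: the searched ICI must be the primary
#' suspect for the case to be selected at all, but a combination partner is
#' frequently coded as secondary suspect.
#'
#' @param substances character vector of canonical ICI substances with a
#'   suspect role in one case (must be non-empty).
#' @return list with `regimen` (label) and `class` (drug class or
#'   `"combination"`) and `mono` (logical).
#' @export
classify_regimen <- function(substances) {
  substances <- sort(unique(substances[substances %in% names(.ici_classes)]))
  if (!length(substances)) {
    stop("classify_regimen: no ICI substance among suspects; run select_cases first")
  }
  if (length(substances) == 1) {
    list(regimen = substances, class = unname(.ici_classes[substances]), mono = TRUE)
  } else {
    key <- paste(substances, collapse = "+")
    lab <- if (key %in% names(.named_combinations)) {
      unname(.named_combinations[key])
    } else {
      "other combination"
    }
    list(regimen = lab, class = "combination", mono = FALSE)
  }
}

#' Classify every case's regimen
#'
#' Vectorised wrapper around [classify_regimen()]; adds `regimen`,
#' `regimen_class`, `mono` and `n_ici` columns to the case table.
#'
#' @param reports a selected `safety_reports` collection.
#' @param strict error when a case has no ICI suspect (default TRUE); with
#'   `strict = FALSE` such cases get `NA` labels, useful for annotating a
#'   full database that still contains background reports.
#' @return the annotated `safety_reports`.
#' @export
classify_regimens <- function(reports, strict = TRUE) {
  d <- reports$drugs
  sus <- d[!is.na(d$role) & d$role %in% c("PS", "SS") &
           d$substance %in% names(.ici_classes), , drop = FALSE]
  sets <- split(sus$substance, sus$case_id)
  labs <- lapply(sets, classify_regimen)
  ids <- names(sets)
  m <- match(reports$cases$case_id, ids)
  if (anyNA(m) && strict) {
    stop("classify_regimens: case(s) without ICI suspect; run select_cases first")
  }
  reports$cases$regimen <- vapply(labs, `[[`, character(1), "regimen")[m]
  reports$cases$regimen_class <- vapply(labs, `[[`, character(1), "class")[m]
  reports$cases$mono <- vapply(labs, `[[`, logical(1), "mono")[m]
  reports$cases$n_ici <- lengths(lapply(sets, unique))[m]
  reports
}

#' Time to onset of the adverse event
#'
#' TTO is the number of whole days from the earliest full (YYYYMMDD) therapy
#' start date of an ICI suspect drug to the event date. Missing when either
#' date is absent or partial; negative intervals are treated as incorrect
#' records, excluded (set missing) and counted.
#'
#' @param reports a `safety_reports` collection (selected and classified or
#'   not; only ICI rows with role PS contribute start dates).
#' @return the collection with a `tto_days` column on `cases` and a
#'   `negative_tto` counter.
#' @export
add_tto <- function(reports) {
  d <- reports$drugs
  ici <- d[!is.na(d$role) & d$role == "PS" & d$substance %in% names(.ici_classes), ,
           drop = FALSE]
  start <- parse_faers_date(ici$start_raw)
  ok <- !is.na(start)
  starts <- tapply(as.numeric(start[ok]), ici$case_id[ok], min)
  m <- match(reports$cases$case_id, names(starts))
  start_days <- as.numeric(starts)[m]
  event_days <- as.numeric(reports$cases$event_date)
  tto <- event_days - start_days
  neg <- !is.na(tto) & tto < 0
  reports$counters$negative_tto <- sum(neg)
  tto[neg] <- NA
  reports$cases$tto_days <- tto
  reports
}

#' @rdname add_tto
#' @param event_date the event date (`Date`).
#' @param start_dates character vector of raw ICI therapy start dates for one
#'   case (`YYYYMMDD`, possibly partial).
#' @return `compute_tto` returns a single number of days or `NA`.
#' @export
compute_tto <- function(event_date, start_dates) {
  start <- parse_faers_date(start_dates)
  if (all(is.na(start)) || is.na(event_date)) return(NA_real_)
  tto <- as.numeric(event_date) - min(as.numeric(start), na.rm = TRUE)
  if (tto < 0) NA_real_ else tto
}
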