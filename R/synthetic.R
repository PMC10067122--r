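#' Configuration for the synthetic FAERS generator
#'
#' Defines the statistical structure of a simulated spontaneous-report
#' database: drug marginal reporting probabilities with role distributions,
#' per-PT background reporting probabilities, planted (drug, PT)
#' disproportionality multipliers, demographic distributions, log-normal
#' time-to-onset laws differing between fatal and non-fatal cases, per-drug
#' fatality probabilities, a case-revision rate and a partial-date rate.
#' Given the same configuration and seed the generator output is
#' byte-identical.
#'
#' @param n_reports number of unique cases to generate.
#' @param seed integer RNG seed; fully determines the output.
#' @param drugs data.frame with columns `substance` (use `"a+b"` for a fixed
#'   combination regimen), `prob` (marginal reporting probability; must sum
#'   to 1) and optionally `p_ps`, `p_ss`, `p_c`, `p_i` (role distribution of
#'   the first drug row; defaults 0.90/0.05/0.04/0.01).
#' @param events data.frame with columns `pt`, `prob` (background inclusion
#'   probability per case).
#' @param multipliers data.frame with columns `substance`, `pt`,
#'   `multiplier`; pairs not listed have multiplier 1. Inclusion probability
#'   for a case is `min(1, prob * multiplier)`; capping triggers a warning.
#' @param sex_probs named probabilities for M/F/U.
#' @param age_mean,age_sd normal age distribution in years, truncated to
#'   [0, 120].
#' @param age_missing_rate fraction of cases with missing age.
#' @param continent_probs named probabilities over continents.
#' @param tto_meanlog_fatal,tto_meanlog_nonfatal,tto_sdlog log-normal TTO
#'   parameters (log-days); the fatal mean is smaller, mirroring the earlier
#'   onset of fatal arrhythmias.
#' @param fatality_default death probability for drugs not listed in
#'   `fatality_by_drug`.
#' @param fatality_by_drug named vector of per-drug death probabilities.
#' @param revision_rate fraction of cases also emitted as a superseded
#'   earlier version (same caseid, lower primaryid, earlier receipt date).
#' @param partial_date_rate fraction of therapy start dates emitted
#'   year-month only (these cases have no computable TTO).
#' @param event_date_missing_rate fraction of cases without an event date.
#' @param quarter quarter label stamped on generated files.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 10000,
                             seed = 1,
                             drugs = default_synthetic_drugs(),
                             events = default_synthetic_events(),
                             multipliers = NULL,
                             sex_probs = c(M = 0.55, F = 0.40, U = 0.05),
                             age_mean = 68, age_sd = 11,
                             age_missing_rate = 0.15,
                             continent_probs = c(America = 0.43, Europe = 0.33,
                                                 Asia = 0.21, Oceania = 0.025,
                                                 Africa = 0.005),
                             tto_meanlog_fatal = log(30),
                             tto_meanlog_nonfatal = log(33),
                             tto_sdlog = 1.5,
                             fatality_default = 0.12,
                             fatality_by_drug = NULL,
                             revision_rate = 0.05,
                             partial_date_rate = 0.25,
                             event_date_missing_rate = 0.25,
                             quarter = "2020Q1") {
  stopifnot(n_reports >= 1, all(c("substance", "prob") %in% names(drugs)),
            all(c("pt", "prob") %in% names(events)))
  if (abs(sum(drugs$prob) - 1) > 1e-8) stop("drug probabilities must sum to 1")
  if (any(events$prob < 0 | events$prob > 1)) stop("event probabilities must lie in [0,1]")
  for (nm in c("p_ps", "p_ss", "p_c", "p_i")) {
    if (!nm %in% names(drugs)) {
      drugs[[nm]] <- c(p_ps = 0.90, p_ss = 0.05, p_c = 0.04, p_i = 0.01)[[nm]]
    }
  }
  if (is.null(multipliers)) {
    multipliers <- data.frame(substance = character(0), pt = character(0),
                              multiplier = numeric(0))
  }
  stopifnot(all(multipliers$multiplier >= 0))
  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    drugs = drugs, events = events, multipliers = multipliers,
    sex_probs = sex_probs, age_mean = age_mean, age_sd = age_sd,
    age_missing_rate = age_missing_rate, continent_probs = continent_probs,
    tto_meanlog_fatal = tto_meanlog_fatal,
    tto_meanlog_nonfatal = tto_meanlog_nonfatal, tto_sdlog = tto_sdlog,
    fatality_default = fatality_default,
    fatality_by_drug = fatality_by_drug %||% numeric(0),
    revision_rate = revision_rate, partial_date_rate = partial_date_rate,
    event_date_missing_rate = event_date_missing_rate, quarter = quarter
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_synthetic_drugs <- function() {
  d <- data.frame(
    substance = c("nivolumab", "pembrolizumab", "cemiplimab",
                  "atezolizumab", "avelumab", "durvalumab",
                  "ipilimumab", "tremelimumab", "ipilimumab+nivolumab",
                  "carboplatin", "paclitaxel", "metformin", "atorvastatin",
                  "amoxicillin"),
    prob = c(0.030, 0.020, 0.001, 0.008, 0.002, 0.003,
             0.006, 0.0005, 0.006,
             0.25, 0.20, 0.20, 0.17, 0.1035),
    stringsAsFactors = FALSE
  )
  d
}

#' @rdname synthetic_config
#' @export
default_synthetic_events <- function() {
  cat <- pt_catalog()
  rbind(
    data.frame(pt = cat$pt, prob = 0.004, stringsAsFactors = FALSE),
    data.frame(pt = c("Nausea", "Fatigue", "Rash", "Diarrhoea", "Pyrexia",
                      "Headache"),
               prob = c(0.12, 0.10, 0.08, 0.08, 0.06, 0.06),
               stringsAsFactors = FALSE)
  )
}

.continent_country <- c(America = "US", Europe = "FR", Asia = "JP",
                        Oceania = "AU", Africa = "ZA")

.synthetic_indications <- data.frame(
  verbatim = c("Non-small cell lung cancer", "Malignant melanoma",
               "Renal cell carcinoma", "Head and neck cancer",
               "Hodgkin lymphoma", "Ovarian cancer", "Gastric cancer",
               "Breast cancer", "Mesothelioma", "Hepatocellular carcinoma",
               "Neoplasm malignant"),
  prob = c(0.32, 0.20, 0.16, 0.04, 0.03, 0.02, 0.02, 0.02, 0.015, 0.012,
           0.143),
  stringsAsFactors = FALSE
)

#' Simulate the raw multi-table record set
#'
#' Draws one primary drug (or fixed combination) per case, assigns reaction
#' PTs with probability `min(1, background * multiplier)`, realises
#' demographics, outcomes and therapy dates, and emits FAERS-shaped DEMO /
#' DRUG / REAC / OUTC / THER / INDI tables together with the ground truth
#' (expected co-report counts per (drug, PT), per-case fatality and TTO
#' draws). Cases selected for revision are emitted twice: a superseded
#' version (lower primaryid, earlier receipt date) and the retained one.
#'
#' @param config a [synthetic_config()].
#' @return list with `recordset` (a `raw_recordset`) and `truth`.
#' @export
simulate_raw <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- config$drugs
  events <- config$events
  K <- nrow(events)

  di <- sample.int(nrow(drugs), n, replace = TRUE, prob = drugs$prob)

  # per-case event probabilities: background times the drug's multiplier
  pmat <- matrix(rep(events$prob, each = n), n, K)
  mult <- config$multipliers
  capped <- character(0)
  if (nrow(mult)) {
    for (i in seq_len(nrow(mult))) {
      rowsel <- drugs$substance[di] == mult$substance[i]
      colsel <- which(tolower(events$pt) == tolower(mult$pt[i]))
      if (!length(colsel)) next
      p <- events$prob[colsel] * mult$multiplier[i]
      if (p > 1) capped <- c(capped, paste0(mult$substance[i], " / ", mult$pt[i]))
      pmat[rowsel, colsel] <- min(1, p)
    }
  }
  if (length(capped)) {
    warning("event probabilities capped at 1 for: ", paste(capped, collapse = "; "))
  }
  hit <- matrix(stats::runif(n * K), n, K) < pmat

  # demographics
  sex <- sample(names(config$sex_probs), n, replace = TRUE, prob = config$sex_probs)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(bad <- age < 0 | age > 120)) {
    age[bad] <- stats::rnorm(sum(bad), config$age_mean, config$age_sd)
  }
  age <- round(age)
  age_missing <- stats::runif(n) < config$age_missing_rate
  continent <- sample(names(config$continent_probs), n, replace = TRUE,
                      prob = config$continent_probs)
  country <- .continent_country[continent]
  ind_i <- sample.int(nrow(.synthetic_indications), n, replace = TRUE,
                      prob = .synthetic_indications$prob)

  # fatality and time to onset
  pfat <- rep(config$fatality_default, n)
  if (length(config$fatality_by_drug)) {
    m <- match(drugs$substance[di], names(config$fatality_by_drug))
    pfat[!is.na(m)] <- config$fatality_by_drug[m[!is.na(m)]]
  }
  died <- stats::runif(n) < pfat
  meanlog <- ifelse(died, config$tto_meanlog_fatal, config$tto_meanlog_nonfatal)
  tto <- round(stats::rlnorm(n, meanlog, config$tto_sdlog))

  start <- as.Date("2018-01-01") + sample.int(1096, n, replace = TRUE) - 1L
  event_date <- start + tto
  fda <- event_date + 30L
  partial <- stats::runif(n) < config$partial_date_rate
  start_dt <- ifelse(partial, format(start, "%Y%m"), format(start, "%Y%m%d"))
  ev_missing <- stats::runif(n) < config$event_date_missing_rate
  event_dt <- ifelse(ev_missing, "", format(event_date, "%Y%m%d"))

  caseid <- sprintf("%07d", seq_len(n))
  revised <- stats::runif(n) < config$revision_rate
  pid <- function(i, v) sprintf("%s%02d", caseid[i], v)
  primaryid <- pid(seq_len(n), ifelse(revised, 2L, 1L))

  demo_row <- function(ids, pids, versions, fda_dates) {
    data.frame(primaryid = pids, caseid = ids,
               caseversion = as.character(versions),
               fda_dt = format(fda_dates, "%Y%m%d"),
               event_dt = event_dt[match(ids, caseid)],
               age = ifelse(age_missing[match(ids, caseid)], "",
                            as.character(age[match(ids, caseid)])),
               age_cod = ifelse(age_missing[match(ids, caseid)], "", "YR"),
               sex = sex[match(ids, caseid)],
               occr_country = unname(country[match(ids, caseid)]),
               stringsAsFactors = FALSE)
  }
  demo <- demo_row(caseid, primaryid, ifelse(revised, 2L, 1L), fda)
  if (any(revised)) {
    old <- which(revised)
    demo_old <- demo_row(caseid[old], pid(old, 1L), rep(1L, length(old)),
                         fda[old] - 30L)
    demo <- rbind(demo, demo_old)
  }

  # drug rows: combination entries expand to one row per member substance
  subs_list <- strsplit(drugs$substance[di], "+", fixed = TRUE)
  n_drug <- lengths(subs_list)
  drug_case <- rep(seq_len(n), n_drug)
  drug_sub <- unlist(subs_list)
  drug_seq <- unlist(lapply(n_drug, seq_len))
  role_first <- character(n)
  for (j in sort(unique(di))) {
    idx <- which(di == j)
    p <- unlist(drugs[j, c("p_ps", "p_ss", "p_c", "p_i")])
    role_first[idx] <- sample(c("PS", "SS", "C", "I"), length(idx),
                              replace = TRUE, prob = p)
  }
  role <- ifelse(drug_seq == 1, role_first[drug_case],
                 sample(c("PS", "SS"), length(drug_case), replace = TRUE))
  verbatim <- paste0(toupper(drug_sub), " 100 MG")
  drug_tab <- data.frame(primaryid = primaryid[drug_case],
                         caseid = caseid[drug_case],
                         drug_seq = as.character(drug_seq),
                         role_cod = role, drugname = verbatim,
                         prod_ai = toupper(drug_sub),
                         stringsAsFactors = FALSE)

  # reaction rows; cases with no drawn PT get a filler background term
  hit_idx <- which(hit, arr.ind = TRUE)
  reac_tab <- data.frame(primaryid = primaryid[hit_idx[, 1]],
                         caseid = caseid[hit_idx[, 1]],
                         pt = events$pt[hit_idx[, 2]],
                         stringsAsFactors = FALSE)
  none <- setdiff(seq_len(n), unique(hit_idx[, 1]))
  if (length(none)) {
    reac_tab <- rbind(reac_tab,
                      data.frame(primaryid = primaryid[none], caseid = caseid[none],
                                 pt = "Drug ineffective", stringsAsFactors = FALSE))
  }
  ord <- order(reac_tab$caseid, reac_tab$pt)
  reac_tab <- reac_tab[ord, , drop = FALSE]

  outc_codes <- ifelse(died, "DE",
                       sample(c("HO", "OT", "LT", ""), n, replace = TRUE,
                              prob = c(0.5, 0.2, 0.1, 0.2)))
  has_outc <- outc_codes != ""
  outc_tab <- data.frame(primaryid = primaryid[has_outc],
                         caseid = caseid[has_outc],
                         outc_cod = outc_codes[has_outc],
                         stringsAsFactors = FALSE)

  ther_tab <- data.frame(primaryid = primaryid[drug_case],
                         caseid = caseid[drug_case],
                         dsg_drug_seq = as.character(drug_seq),
                         start_dt = start_dt[drug_case],
                         end_dt = "",
                         stringsAsFactors = FALSE)

  indi_tab <- data.frame(primaryid = primaryid, caseid = caseid,
                         indi_drug_seq = "1",
                         indi_pt = .synthetic_indications$verbatim[ind_i],
                         stringsAsFactors = FALSE)

  # duplicate satellite rows for the superseded versions
  if (any(revised)) {
    dup <- function(tab) {
      old <- tab[tab$primaryid %in% primaryid[revised], , drop = FALSE]
      if (!nrow(old)) return(tab)
      old$primaryid <- sprintf("%s01", old$caseid)
      rbind(tab, old)
    }
    drug_tab <- dup(drug_tab); reac_tab <- dup(reac_tab)
    outc_tab <- dup(outc_tab); ther_tab <- dup(ther_tab); indi_tab <- dup(indi_tab)
  }

  rownames(demo) <- rownames(drug_tab) <- rownames(reac_tab) <- NULL
  rownames(outc_tab) <- rownames(ther_tab) <- rownames(indi_tab) <- NULL
  rs <- structure(list(demo = demo, drug = drug_tab, reac = reac_tab,
                       outc = outc_tab, ther = ther_tab, indi = indi_tab,
                       quarter = config$quarter,
                       counters = list(malformed = 0L, orphans = 0L)),
                  class = "raw_recordset")

  # ground truth: expected case-level co-report counts per (drug entry, PT)
  target <- unique(c(config$multipliers$pt, pt_catalog()$pt))
  truth_cells <- do.call(rbind, lapply(seq_len(nrow(drugs)), function(j) {
    kk <- match(tolower(target), tolower(events$pt))
    keep <- !is.na(kk)
    mm <- rep(1, sum(keep))
    if (nrow(mult)) {
      key <- paste(drugs$substance[j], tolower(target[keep]))
      mkey <- paste(mult$substance, tolower(mult$pt))
      hitm <- match(key, mkey)
      mm[!is.na(hitm)] <- mult$multiplier[hitm[!is.na(hitm)]]
    }
    data.frame(substance = drugs$substance[j], pt = target[keep],
               multiplier = mm,
               expected_a = n * drugs$prob[j] * pmin(1, events$prob[kk[keep]] * mm),
               stringsAsFactors = FALSE)
  }))
  truth <- list(cells = truth_cells,
                cases = data.frame(case_id = caseid,
                                   drug = drugs$substance[di],
                                   died = died, tto = tto,
                                   stringsAsFactors = FALSE),
                n_revised = sum(revised))
  list(recordset = rs, truth = truth)
}

#' Simulate a ready-made report collection
#'
#' Runs [simulate_raw()] and pushes the record set through the standard
#' ingest path ([deduplicate()] then [build_reports()]), so the simulated
#' reports are exercised by exactly the code real data would take.
#'
#' @param config a [synthetic_config()].
#' @param dict a [drug_dictionary()].
#' @return list with `reports` (a `safety_reports`) and `truth`.
#' @export
simulate_reports <- function(config, dict = drug_dictionary()) {
  sim <- simulate_raw(config)
  reports <- build_reports(deduplicate(sim$recordset), dict = dict)
  list(reports = reports, truth = sim$truth)
}

#' Write a synthetic quarter to disk in the FAERS ASCII dialect
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of written file paths (including
#'   `ground_truth.json`).
#' @export
generate_faers <- function(config, dir) {
  sim <- simulate_raw(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- sim$recordset
  paths <- character(0)
  for (t in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    path <- file.path(dir, sprintf("%s_%s.txt", t, config$quarter))
    tab <- rs[[t]]
    lines <- c(paste(names(tab), collapse = "$"),
               do.call(paste, c(unname(as.list(tab)), sep = "$")))
    writeLines(lines, path)
    paths[t] <- path
  }
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$truth, gt, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths["ground_truth"] <- gt
  invisible(paths)
}

# expand counts into a deterministic block vector of levels
.blocks <- function(levels, counts) rep(levels, counts)

#' Deterministic 1945-case cohort matching the published margins
#'
#' Builds a fixed cohort of 1945 ICI arrhythmia cases whose marginal counts
#' reproduce, stratum by stratum, the published clinical-characteristics
#' table: 507 fatal / 1438 non-fatal cases, and within each arm the printed
#' sex, age-band, reporting-year, continent, indication, outcome,
#' time-to-onset band and regimen counts. Characteristics are assigned
#' independently in deterministic blocks within each arm (the joint
#' distribution across characteristics is not identified by published
#' margins), so any function of a single characteristic and the fatality
#' flag reproduces the printed table exactly. One published inconsistency is
#' resolved in favour of the totals: non-fatal indication counts are derived
#' as total minus fatal. Representative within-band values (ages 10/50/70,
#' TTO 15/45/75/135/270 days) fill the interiors.
#'
#' @return a classified, TTO-annotated `safety_reports` collection of
#'   exactly 1945 cases.
#' @export
table1_fixture <- function() {
  arm <- function(n, fatal, sex_n, age_n, year_n, cont_n, indi_n, outc, tto_n,
                  regimen_n, id0) {
    sex <- .blocks(c("F", "M", "U"), sex_n)
    age <- .blocks(c(10, 50, 70, NA), age_n)
    year <- .blocks(2011:2021, year_n)
    cont <- .blocks(c("Europe", "America", "Asia", "Oceania", "Africa", "Unknown"),
                    cont_n)
    indi <- .blocks(c("Lung cancer", "Melanoma", "Tumors of urinary system",
                      "Head and neck cancer", "Hematological cancer and lymphoma",
                      "Tumors of female reproductive organs",
                      "Gastrointestinal cancer", "Breast cancer", "Mesothelioma",
                      "Hepatocellular carcinoma", "Other"), indi_n)
    codes <- .blocks(names(outc), outc)
    tto <- .blocks(c(15, 45, 75, 135, 270, NA), tto_n)
    regimen <- .blocks(c("pembrolizumab", "nivolumab", "cemiplimab",
                         "atezolizumab", "avelumab", "durvalumab", "ipilimumab",
                         "ipilimumab+nivolumab", "ipilimumab+pembrolizumab",
                         "durvalumab+tremelimumab", "atezolizumab+pembrolizumab"),
                       regimen_n)
    stopifnot(length(sex) == n, length(age) == n, length(year) == n,
              length(cont) == n, length(indi) == n, length(codes) == n,
              length(tto) == n, length(regimen) == n)
    ids <- sprintf("T%06d", id0 + seq_len(n))
    start <- as.Date("2018-01-01")
    cases <- data.frame(
      case_id = ids, primary_id = paste0(ids, "01"),
      sex = sex, age_years = age,
      country = unname(c(.continent_country, Unknown = NA)[cont]),
      continent = cont,
      report_date = as.Date(sprintf("%d-07-01", year)),
      event_date = start + ifelse(is.na(tto), NA, tto),
      indication = indi, indication_group = indi,
      outcome_codes = codes, died = codes == "DE",
      stringsAsFactors = FALSE
    )
    subs <- strsplit(regimen, "+", fixed = TRUE)
    nd <- lengths(subs)
    drugs <- data.frame(
      case_id = rep(ids, nd),
      drug_seq = unlist(lapply(nd, seq_len)),
      verbatim_name = paste0(toupper(unlist(subs)), " INJ"),
      substance = unlist(subs),
      role = "PS",
      start_raw = rep(ifelse(is.na(tto), "201801", "20180101"), nd),
      end_raw = NA_character_,
      stringsAsFactors = FALSE
    )
    reactions <- data.frame(case_id = ids, pt = "Atrial fibrillation",
                            stringsAsFactors = FALSE)
    list(cases = cases, drugs = drugs, reactions = reactions)
  }

  fatal <- arm(
    507, TRUE,
    sex_n = c(137, 337, 33),
    age_n = c(0, 147, 269, 91),
    year_n = c(7, 8, 5, 8, 23, 43, 55, 86, 85, 80, 107),
    cont_n = c(154, 186, 160, 7, 0, 0),
    indi_n = c(175, 92, 75, 32, 12, 16, 17, 6, 2, 9, 71),
    outc = c(DE = 507),
    tto_n = c(154, 54, 37, 26, 29, 207),
    regimen_n = c(105, 197, 2, 54, 7, 19, 46, 69, 1, 4, 3),
    id0 = 0
  )
  nonfatal <- arm(
    1438, FALSE,
    sex_n = c(424, 923, 91),
    age_n = c(7, 407, 781, 243),
    year_n = c(12, 22, 19, 28, 58, 86, 179, 228, 260, 243, 303),
    cont_n = c(490, 648, 247, 46, 4, 3),
    # non-fatal indication counts derived as total minus fatal
    indi_n = c(449, 306, 241, 39, 44, 31, 27, 26, 26, 13, 236),
    outc = stats::setNames(c(150, 25, 934, 299, 6, 1, 23),
                           c("LT", "DS", "HO", "OT", "RI", "CA", "")),
    tto_n = c(404, 145, 88, 98, 106, 597),
    regimen_n = c(270, 564, 6, 170, 22, 37, 132, 219, 4, 5, 9),
    id0 = 507
  )
  reports <- safety_reports(
    cases = rbind(fatal$cases, nonfatal$cases),
    drugs = rbind(fatal$drugs, nonfatal$drugs),
    reactions = rbind(fatal$reactions, nonfatal$reactions),
    counters = list(fixture = TRUE)
  )
  add_tto(classify_regimens(reports))
}
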