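#' Bundled brand/generic dictionary for immune checkpoint inhibitors
#'
#' Loads the name dictionary used to canonicalise verbatim FAERS drug names.
#' Lookup is case-insensitive containment: a verbatim drug name matches a
#' dictionary variant when the variant occurs anywhere inside the uppercased,
#' whitespace-trimmed name (FAERS names routinely carry dose and formulation
#' suffixes, so exact equality would miss most rows).
#'
#' @param path Optional path to a two-column CSV (`variant`, `substance`);
#'   defaults to the dictionary shipped with the package, covering the eight
#'   FDA-approved ICIs (anti-PD-1: nivolumab, pembrolizumab, cemiplimab;
#'   anti-PD-L1: atezolizumab, avelumab, durvalumab; anti-CTLA-4: ipilimumab,
#'   tremelimumab) under brand and generic names.
#' @return A data.frame of class `drug_dictionary` with columns `variant`
#'   (uppercase) and `substance` (lowercase canonical label).
#' @export
drug_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ici_drug_dictionary.csv", package = "faersvigil")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "substance") %in% names(d)))
  d$variant <- toupper(trimws(d$variant))
  d$substance <- tolower(trimws(d$substance))
  # every canonical substance must have at least one generic (equal to the
  # substance) and one distinct brand variant
  per <- split(d$variant, d$substance)
  ok <- vapply(per, function(v) length(unique(v)) >= 2, logical(1))
  if (!all(ok)) {
    stop("drug dictionary: substances with fewer than two name variants: ",
         paste(names(per)[!ok], collapse = ", "))
  }
  class(d) <- c("drug_dictionary", "data.frame")
  d
}

#' Bundled arrhythmia preferred-term catalogue
#'
#' The 24 MedDRA preferred terms (PTs) used to define an arrhythmic adverse
#' event, each assigned to exactly one event group (atrial arrhythmia,
#' ventricular arrhythmia, conduction disease, cardiac arrest/sudden death,
#' supraventricular tachycardia, QT prolongation, unspecified rate/rhythm).
#' PT matching throughout the package is case-insensitive exact string
#' comparison against this list; no MedDRA hierarchy or SMQ expansion is
#' performed.
#'
#' @param path Optional path to a CSV with columns `pt` and `group`; defaults
#'   to the catalogue shipped with the package.
#' @return A data.frame of class `pt_catalog` with columns `pt` and `group`.
#' @export
pt_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "arrhythmia_pts.csv", package = "faersvigil")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pt", "group") %in% names(d)))
  if (anyDuplicated(tolower(d$pt))) stop("pt_catalog: duplicated preferred terms")
  class(d) <- c("pt_catalog", "data.frame")
  d
}

#' @return named character vector mapping ISO-like country code to continent.
#' @noRd
continent_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "country_continents.csv", package = "faersvigil")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(d$continent, toupper(d$country))
}

#' @return data.frame keyword -> indication group (lowercase keywords).
#' @noRd
indication_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "indication_groups.csv", package = "faersvigil")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$keyword <- tolower(d$keyword)
  d
}

# class membership of the canonical ICI substances
.ici_classes <- c(
  nivolumab = "anti-PD-1", pembrolizumab = "anti-PD-1", cemiplimab = "anti-PD-1",
  atezolizumab = "anti-PD-L1", avelumab = "anti-PD-L1", durvalumab = "anti-PD-L1",
  ipilimumab = "anti-CTLA-4", tremelimumab = "anti-CTLA-4"
)

# the named combination regimens reported for ICI therapy, keyed by the
# sorted "+"-joined substance pair
.named_combinations <- c(
  "ipilimumab+nivolumab"      = "ipilimumab + nivolumab",
  "ipilimumab+pembrolizumab"  = "ipilimumab + pembrolizumab",
  "durvalumab+tremelimumab"   = "tremelimumab + durvalumab",
  "atezolizumab+pembrolizumab" = "pembrolizumab + atezolizumab"
)

#' Parse a FAERS date field
#'
#' FAERS dates are numeric strings: `YYYYMMDD` (full), `YYYYMM` (year-month)
#' or `YYYY` (year only). Only full dates are converted; partial or malformed
#' values yield `NA` so that downstream interval arithmetic never rests on an
#' imputed day.
#'
#' @param x character vector of raw date fields.
#' @return a `Date` vector, `NA` where the field is not a full `YYYYMMDD` date.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out <- rep(as.Date(NA), length(x))
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- d
  }
  out
}

# round(100 * n / N, 2) with a guard for empty denominators
.pct <- function(n, N) {
  if (length(N) == 1 && (is.na(N) || N == 0)) return(rep(NA_real_, length(n)))
  round(100 * n / N, 2)
}
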