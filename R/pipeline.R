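#' Pipeline configuration
#'
#' @param input_dir directory holding quarterly files named
#'   `<table>_<quarter>.txt` (e.g. `demo_2020Q1.txt`), as written by
#'   [generate_faers()] or renamed FAERS extracts.
#' @param out_dir output directory for the rendered artifacts.
#' @param quarters character vector of quarter labels to ingest (default:
#'   all quarters found in `input_dir`).
#' @param dictionary_path,catalog_path optional paths overriding the bundled
#'   drug dictionary and PT catalogue.
#' @param criteria a [signal_criteria()].
#' @param unit counting unit for disproportionality (default `"record"`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, quarters = NULL,
                            dictionary_path = NULL, catalog_path = NULL,
                            criteria = signal_criteria(),
                            unit = c("record", "case")) {
  unit <- match.arg(unit)
  if (!dir.exists(input_dir)) stop("pipeline_config: input_dir does not exist")
  if (is.null(quarters)) {
    hits <- list.files(input_dir, pattern = "^demo_[0-9]{4}Q[1-4]\\.txt$")
    quarters <- sort(sub("^demo_(.*)\\.txt$", "\\1", hits))
    if (!length(quarters)) stop("pipeline_config: no demo_<quarter>.txt files found")
  }
  stopifnot(all(grepl("^[0-9]{4}Q[1-4]$", quarters)))
  structure(list(input_dir = input_dir, out_dir = out_dir, quarters = quarters,
                 dictionary_path = dictionary_path, catalog_path = catalog_path,
                 criteria = criteria, unit = unit),
            class = "pipeline_config")
}

#' Run the full ingest-to-report pipeline
#'
#' Parses all configured quarters, deduplicates case versions, builds and
#' annotates reports, and renders six artifacts into the output directory:
#' the one-row-per-case interchange table, the drug/class signal table, the
#' regimen-by-PT spectrum JSON, the Table-1-shaped fatal vs non-fatal
#' summary, the fatality table and the TTO-by-regimen table, plus a run log
#' with the stage funnel (parsed, deduplicated, selected) and all exclusion
#' counters. Identical inputs and configuration yield byte-identical
#' outputs. On a hard error all partial outputs are removed and the error is
#' re-thrown.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (named artifact paths), `funnel`
#'   (stage counts), `counters`, and the in-memory `reports` objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dict <- drug_dictionary(config$dictionary_path)
  catalog <- pt_catalog(config$catalog_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_error <- function(e) {
    unlink(written)
    stop("run_pipeline failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    sets <- lapply(config$quarters, function(q) {
      tabs <- c("demo", "drug", "reac", "outc", "ther", "indi")
      paths <- file.path(config$input_dir, sprintf("%s_%s.txt", tabs, q))
      names(paths) <- tabs
      parse_quarter(as.list(paths[file.exists(paths)]), q)
    })
    raw <- if (length(sets) > 1) bind_recordsets(sets) else sets[[1]]
    parsed_n <- length(unique(raw$demo$primaryid))
    dedup <- deduplicate(raw)
    all_reports <- build_reports(dedup, dict = dict)
    all_reports <- classify_regimens(add_tto(all_reports), strict = FALSE)
    cohort <- select_cases(all_reports, dict = dict, catalog = catalog)
    cohort <- classify_regimens(add_tto(cohort))
    funnel <- c(parsed = parsed_n,
                deduplicated = dedup$counters$cases_out,
                built = n_cases(all_reports),
                selected = n_cases(cohort))

    manifest <- character(0)
    emit <- function(name, fn) {
      path <- file.path(config$out_dir, name)
      fn(path)
      written <<- c(written, path)
      manifest[[sub("\\..*$", "", name)]] <<- path
    }
    emit("case_table.csv", function(p)
      utils::write.csv(.df_to_text(flat_case_table(cohort)), p,
                       row.names = FALSE, na = ""))

    subs <- sort(unique(dict$substance))
    selectors <- stats::setNames(as.list(subs), subs)
    for (cl in unique(unname(.ici_classes))) {
      selectors[[cl]] <- names(.ici_classes)[.ici_classes == cl]
    }
    selectors[["all ICIs"]] <- names(.ici_classes)
    signals <- disprop(all_reports, drugs = selectors, events = catalog$pt,
                       unit = config$unit, criteria = config$criteria)
    emit("signal_table.csv", function(p) {
      out <- as.data.frame(signals)
      num <- vapply(out, is.double, logical(1))
      out[num] <- lapply(out[num], round, 4)
      utils::write.csv(out, p, row.names = FALSE, na = "")
    })

    spec <- signal_spectrum(all_reports, catalog = catalog,
                            criteria = config$criteria, unit = config$unit)
    emit("spectrum.json", function(p) write_spectrum_json(spec, p))

    emit("table1_summary.csv", function(p)
      utils::write.csv(table1_table(cohort), p, row.names = FALSE, na = ""))

    fat <- do.call(rbind, lapply(c("overall", "regimen", "event_group"),
      function(by) cbind(by = by, fatality_rates(cohort, by = by,
                                                 catalog = catalog))))
    emit("fatality.csv", function(p)
      utils::write.csv(fat, p, row.names = FALSE, na = ""))

    tto <- tto_by_regimen(cohort)
    tto_tab <- tto$table
    tto_tab$omnibus_p <- if (!is.null(tto$test)) tto$test$p.value else NA_real_
    emit("tto.csv", function(p)
      utils::write.csv(.df_to_text(tto_tab), p, row.names = FALSE, na = ""))

    log <- list(quarters = config$quarters, funnel = as.list(funnel),
                counters = cohort$counters,
                artifacts = as.list(basename(manifest)))
    log_path <- file.path(config$out_dir, "run_log.json")
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, log_path)

    list(manifest = manifest, funnel = funnel, counters = cohort$counters,
         reports = cohort, database = all_reports, log = log_path)
  }, error = on_error)
}
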