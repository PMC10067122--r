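demo_df <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

basic_quarter <- function() {
  list(
    demo = demo_df(primaryid = c("1001", "2001", "3001"),
                   caseid = c("100", "200", "300"),
                   fda_dt = c("20200110", "20200111", "20200112"),
                   event_dt = c("20200101", "", "20191220"),
                   age = c("7", "65", "780"),
                   age_cod = c("DEC", "YR", "MON"),
                   sex = c("M", "F", ""),
                   occr_country = c("US", "JP", "XX")),
    drug = demo_df(primaryid = c("1001", "1001", "2001", "3001", "9999"),
                   caseid = c("100", "100", "200", "300", "999"),
                   drug_seq = c("1", "2", "1", "1", "1"),
                   role_cod = c("PS", "C", "PS", "SS", "PS"),
                   drugname = c("OPDIVO 40MG/4ML", "ASPIRIN", "KEYTRUDA",
                                "NIVOLUMAB INJECTION", "OPDIVO"),
                   prod_ai = c("NIVOLUMAB", "", "PEMBROLIZUMAB", "NIVOLUMAB", "")),
    reac = demo_df(primaryid = c("1001", "1001", "2001", "3001"),
                   caseid = c("100", "100", "200", "300"),
                   pt = c("Atrial fibrillation", "Nausea",
                          "ATRIAL FIBRILLATION", "Cardiac arrest")),
    outc = demo_df(primaryid = c("1001", "2001"),
                   caseid = c("100", "200"),
                   outc_cod = c("HO", "DE")),
    ther = demo_df(primaryid = c("1001", "2001", "3001"),
                   caseid = c("100", "200", "300"),
                   dsg_drug_seq = c("1", "1", "1"),
                   start_dt = c("20191201", "201912", "20200101"))
  )
}

test_that("quarter parsing preserves counts, drops orphans, handles headers", {
  paths <- write_quarter(basic_quarter())
  rs <- parse_quarter(paths, "2020Q1")
  expect_s3_class(rs, "raw_recordset")
  expect_equal(nrow(rs$demo), 3)
  expect_equal(nrow(rs$drug), 4)       # one orphan DRUG row dropped
  expect_equal(rs$counters$orphans, 1L)
  expect_equal(rs$counters$malformed, 0L)

  # headers in any letter case and legacy ISR/CASE keys map identically
  q <- basic_quarter()
  names(q$demo) <- toupper(names(q$demo))
  names(q$demo)[1:2] <- c("ISR", "CASE")
  names(q$drug)[1] <- "PRIMARYID"
  paths2 <- write_quarter(q)
  rs2 <- parse_quarter(paths2, "2020Q1")
  expect_identical(rs2$demo$primaryid, rs$demo$primaryid)
  expect_identical(rs2$demo$caseid, rs$demo$caseid)

  # a missing mandatory column is a hard error naming the column
  q3 <- basic_quarter()
  q3$reac$pt <- NULL
  expect_error(parse_quarter(write_quarter(q3), "2020Q1"), "pt")
  expect_error(parse_quarter(write_quarter(basic_quarter()), "2020-01"), "YYYYQn")
})

test_that("malformed lines are counted and skipped, not fatal", {
  paths <- write_quarter(basic_quarter())
  cat("1$2$3$4$5$6$7$8$9$10\n", file = paths$demo, append = TRUE)
  rs <- parse_quarter(paths, "2020Q1")
  expect_equal(nrow(rs$demo), 3)
  expect_equal(rs$counters$malformed, 1L)
})

test_that("deduplication keeps the latest version, tie-broken by primaryid", {
  q <- basic_quarter()
  # add a revision of case 100 with a later receipt date
  q$demo <- rbind(q$demo,
                  demo_df(primaryid = "1002", caseid = "100",
                          fda_dt = "20200301", event_dt = "20200101",
                          age = "70", age_cod = "YR", sex = "M",
                          occr_country = "US"))
  q$drug <- rbind(q$drug,
                  demo_df(primaryid = "1002", caseid = "100", drug_seq = "1",
                          role_cod = "PS", drugname = "OPDIVO",
                          prod_ai = "NIVOLUMAB"))
  q$reac <- rbind(q$reac,
                  demo_df(primaryid = "1002", caseid = "100",
                          pt = "Atrial flutter"))
  rs <- deduplicate(parse_quarter(write_quarter(q), "2020Q1"))
  expect_equal(nrow(rs$demo), 3)
  expect_true("1002" %in% rs$demo$primaryid)
  expect_false("1001" %in% rs$demo$primaryid)
  expect_false(any(rs$drug$primaryid == "1001"))
  expect_equal(rs$counters$versions_dropped, 1L)

  # same receipt date on both versions: the higher primaryid wins
  q2 <- basic_quarter()
  q2$demo$fda_dt <- "20200110"
  q2$demo <- rbind(q2$demo,
                   demo_df(primaryid = "1010", caseid = "100",
                           fda_dt = "20200110", event_dt = "", age = "",
                           age_cod = "", sex = "M", occr_country = "US"))
  rs2 <- deduplicate(parse_quarter(write_quarter(q2), "2020Q1"))
  expect_true("1010" %in% rs2$demo$primaryid)
  expect_false("1001" %in% rs2$demo$primaryid)

  # without revisions, deduplication is the identity
  rs3 <- deduplicate(parse_quarter(write_quarter(basic_quarter()), "2020Q1"))
  expect_equal(rs3$counters$versions_dropped, 0L)
  expect_equal(nrow(rs3$demo), 3)
})

test_that("report building converts ages, maps countries and sets the death flag", {
  rs <- deduplicate(parse_quarter(write_quarter(basic_quarter()), "2020Q1"))
  rp <- build_reports(rs)
  cs <- rp$cases
  expect_equal(cs$age_years[cs$case_id == "100"], 70)   # 7 decades
  expect_equal(cs$age_years[cs$case_id == "300"], 65)   # 780 months
  expect_equal(cs$continent[cs$case_id == "100"], "America")
  expect_equal(cs$continent[cs$case_id == "300"], "Unknown")  # XX unmapped
  expect_identical(cs$died, cs$case_id == "200")
  expect_equal(cs$sex[cs$case_id == "300"], "U")
  # brand name with dosage suffix canonicalises by containment
  d <- rp$drugs
  expect_equal(d$substance[d$case_id == "100" & d$drug_seq == 1], "nivolumab")
  expect_equal(d$substance[d$verbatim_name == "ASPIRIN"], "other")

  # an unmappable age unit yields missing age with a warning
  q <- basic_quarter()
  q$demo$age_cod[2] <- "??"
  rs2 <- deduplicate(parse_quarter(write_quarter(q), "2020Q1"))
  expect_warning(rp2 <- build_reports(rs2), "unmappable")
  expect_true(is.na(rp2$cases$age_years[rp2$cases$case_id == "200"]))
  expect_equal(rp2$counters$bad_age_unit, 1L)
})

test_that("case selection requires an ICI primary suspect and a catalogue PT", {
  rs <- deduplicate(parse_quarter(write_quarter(basic_quarter()), "2020Q1"))
  rp <- build_reports(rs)
  sel <- select_cases(rp)
  # case 100: ICI PS + Atrial fibrillation -> retained
  # case 200: ICI PS + ATRIAL FIBRILLATION (case-insensitive) -> retained
  # case 300: ICI only as SS -> excluded
  expect_setequal(sel$cases$case_id, c("100", "200"))

  # idempotent and order-independent
  sel2 <- select_cases(sel)
  expect_identical(sel2$cases$case_id, sel$cases$case_id)
  perm <- rp
  ord <- c(3, 1, 2)
  perm$cases <- perm$cases[ord, ]
  expect_setequal(select_cases(perm)$cases$case_id, sel$cases$case_id)

  # ICI as PS but no qualifying PT -> excluded
  q <- basic_quarter()
  q$reac$pt[q$reac$caseid == "200"] <- "Nausea"
  rp3 <- build_reports(deduplicate(parse_quarter(write_quarter(q), "2020Q1")))
  expect_setequal(select_cases(rp3)$cases$case_id, "100")
})

test_that("regimen classification distinguishes classes and named pairs", {
  expect_equal(classify_regimen("nivolumab"),
               list(regimen = "nivolumab", class = "anti-PD-1", mono = TRUE))
  expect_equal(classify_regimen(c("ipilimumab", "nivolumab"))$regimen,
               "ipilimumab + nivolumab")
  expect_equal(classify_regimen(c("durvalumab", "tremelimumab"))$regimen,
               "tremelimumab + durvalumab")
  expect_equal(classify_regimen(c("nivolumab", "pembrolizumab", "ipilimumab")),
               list(regimen = "other combination", class = "combination",
                    mono = FALSE))
  expect_equal(classify_regimen("atezolizumab")$class, "anti-PD-L1")
  expect_equal(classify_regimen("ipilimumab")$class, "anti-CTLA-4")
  expect_error(classify_regimen("aspirin"), "select_cases")
})

test_that("time to onset uses full dates only and excludes negatives", {
  expect_equal(compute_tto(as.Date("2019-02-02"), "20190101"), 32)
  expect_true(is.na(compute_tto(as.Date("2019-07-01"), "201906")))
  expect_true(is.na(compute_tto(as.Date("2019-04-01"), "20190501")))
  expect_true(is.na(compute_tto(as.Date(NA), "20190101")))
  # earliest full start date wins when several drugs are present
  expect_equal(compute_tto(as.Date("2019-03-01"), c("20190201", "20190101")), 59)

  # vectorised path: negative TTO counted, partial start missing
  rp <- make_reports(c("nivolumab", "nivolumab", "nivolumab"),
                     "Atrial fibrillation")
  rp$cases$event_date <- as.Date(c("2019-02-02", "2018-12-01", NA))
  rp$drugs$start_raw <- c("20190101", "20190101", "20190101")
  rp <- add_tto(rp)
  expect_equal(rp$cases$tto_days, c(32, NA, NA))
  expect_equal(rp$counters$negative_tto, 1L)
})

test_that("interchange round trip is bit-identical", {
  sim <- simulate_reports(synthetic_config(n_reports = 300, seed = 11))
  rp <- classify_regimens(add_tto(sim$reports), strict = FALSE)
  dir <- tempfile()
  write_reports(rp, dir)
  back <- read_reports(dir)
  for (t in c("cases", "drugs", "reactions")) {
    expect_identical(back[[t]], rp[[t]], label = t)
  }
})

test_that("the death flag mirrors the DE outcome code across a synthetic database", {
  sim <- simulate_reports(synthetic_config(n_reports = 2000, seed = 5))
  cs <- sim$reports$cases
  has_de <- vapply(strsplit(cs$outcome_codes, ";", fixed = TRUE),
                   function(x) "DE" %in% x, logical(1))
  expect_identical(cs$died, has_de)
  expect_error(
    safety_reports(transform(cs, died = !died), sim$reports$drugs,
                   sim$reports$reactions),
    "died flag")
})
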