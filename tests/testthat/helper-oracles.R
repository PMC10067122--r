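# Independent oracles used to cross-check the estimator core.

# odds ratio + Wald CI via a weighted binomial GLM (independent route:
# IRLS maximum likelihood on the saturated 2x2, not the closed form)
glm_or_oracle <- function(a, b, c, d, z = 1.96) {
  df <- data.frame(drug = c(1, 1, 0, 0), event = c(1, 0, 1, 0),
                   w = c(a, b, c, d))
  fit <- suppressWarnings(stats::glm(event ~ drug, family = stats::binomial,
                                     data = df, weights = w,
                                     control = stats::glm.control(epsilon = 1e-13,
                                                                  maxit = 100)))
  co <- summary(fit)$coefficients
  est <- exp(co["drug", 1]); se <- co["drug", 2]
  c(or = est, low = exp(co["drug", 1] - z * se), high = exp(co["drug", 1] + z * se))
}

# brute-force ROR in log space (independent evaluation order)
log_or_oracle <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  lo <- (log(a) + log(d)) - (log(b) + log(c))
  se <- sqrt(sum(1 / c(a, b, c, d)))
  c(or = exp(lo), low = exp(lo - z * se), high = exp(lo + z * se))
}

# proportional reporting ratio via an independent factorisation
prr_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  if (a == 0) return(0)
  (a * (c + d)) / ((a + b) * c)
}

# Monte-Carlo 2.5% quantile of the IC posterior: the Poisson intensity
# ratio has a Gamma(a + 0.5, E + 0.5) posterior under the shrinkage prior
mc_ic025 <- function(a, b, c, d, ndraw = 20000, seed = 1) {
  E <- (a + b) * (a + c) / (a + b + c + d)
  set.seed(seed)
  draws <- log2(stats::rgamma(ndraw, shape = a + 0.5, rate = E + 0.5))
  unname(stats::quantile(draws, 0.025, type = 7))
}

# random strictly-positive 2x2 tables (reproducible)
random_tables <- function(n, seed, max_cell = 1e5) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, replace = TRUE),
             b = sample.int(max_cell, n, replace = TRUE),
             c = sample.int(max_cell, n, replace = TRUE),
             d = sample.int(max_cell, n, replace = TRUE))
}

# minimal valid safety_reports collection: one PS drug row and one reaction
# per case
make_reports <- function(substance, pt, died = FALSE,
                         sex = "M", age = 65, continent = "America",
                         tto = NA_real_, regimen_class = NULL) {
  n <- max(length(substance), length(pt), length(died))
  substance <- rep_len(substance, n); pt <- rep_len(pt, n)
  died <- rep_len(died, n)
  ids <- sprintf("X%06d", seq_len(n))
  tto <- rep_len(tto, n)
  start <- as.Date("2019-01-01")
  cases <- data.frame(
    case_id = ids, primary_id = paste0(ids, "1"),
    sex = rep_len(sex, n), age_years = rep_len(age, n),
    country = NA_character_, continent = rep_len(continent, n),
    report_date = as.Date("2020-06-01"),
    event_date = start + ifelse(is.na(tto), NA, tto),
    indication = "Lung cancer", indication_group = "Lung cancer",
    outcome_codes = ifelse(died, "DE", "HO"), died = died,
    tto_days = tto,
    stringsAsFactors = FALSE)
  drugs <- data.frame(
    case_id = ids, drug_seq = 1L,
    verbatim_name = toupper(substance), substance = substance, role = "PS",
    start_raw = "20190101", end_raw = NA_character_,
    stringsAsFactors = FALSE)
  reactions <- data.frame(case_id = ids, pt = pt, stringsAsFactors = FALSE)
  rp <- safety_reports(cases, drugs, reactions)
  if (!is.null(regimen_class)) {
    rp$cases$regimen <- rep_len(regimen_class, n)
    rp$cases$regimen_class <- rep_len(regimen_class, n)
  }
  rp
}

# write a tiny quarter of $-delimited tables; `rows` is a named list of
# data.frames (demo/drug/reac/...)
write_quarter <- function(rows, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (t in names(rows)) {
    p <- file.path(dir, paste0(t, ".txt"))
    tab <- rows[[t]]
    writeLines(c(paste(names(tab), collapse = "$"),
                 if (nrow(tab)) do.call(paste, c(unname(as.list(tab)), sep = "$"))),
               p)
    paths[[t]] <- p
  }
  paths
}
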