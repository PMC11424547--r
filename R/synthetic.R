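#' Default background adverse-event vocabulary for simulation
#'
#' A fixed table of MedDRA-style preferred terms with a primary system organ
#' class and a baseline per-report occurrence probability. Baselines span the
#' range seen for common and rare terms in spontaneous-report databases
#' (roughly 0.2%--8% of reports). The vocabulary leans on gastrointestinal,
#' infection and metabolic terms because those dominate short-bowel-syndrome
#' pharmacovigilance, but any tibble with columns `pt`, `soc`,
#' `baseline` can be supplied instead.
#'
#' @return A tibble with columns `pt`, `soc`, `baseline`.
#' @export
default_background_pts <- function() {
  tibble::tribble(
    ~pt, ~soc, ~baseline,
    "Abdominal pain", "Gastrointestinal disorders", 0.060,
    "Abdominal distension", "Gastrointestinal disorders", 0.030,
    "Nausea", "Gastrointestinal disorders", 0.080,
    "Vomiting", "Gastrointestinal disorders", 0.050,
    "Diarrhoea", "Gastrointestinal disorders", 0.055,
    "Flatulence", "Gastrointestinal disorders", 0.015,
    "Constipation", "Gastrointestinal disorders", 0.025,
    "Intestinal obstruction", "Gastrointestinal disorders", 0.006,
    "Abnormal faeces", "Gastrointestinal disorders", 0.004,
    "Crohn's disease", "Gastrointestinal disorders", 0.005,
    "Weight decreased", "Investigations", 0.040,
    "Weight increased", "Investigations", 0.030,
    "Blood magnesium decreased", "Investigations", 0.003,
    "Blood potassium decreased", "Investigations", 0.004,
    "Vascular device infection", "Infections and infestations", 0.004,
    "Device related infection", "Infections and infestations", 0.008,
    "Sepsis", "Infections and infestations", 0.012,
    "Pneumonia", "Infections and infestations", 0.020,
    "Staphylococcal infection", "Infections and infestations", 0.005,
    "Nasopharyngitis", "Infections and infestations", 0.015,
    "Urinary tract infection", "Infections and infestations", 0.012,
    "Dehydration", "Metabolism and nutrition disorders", 0.015,
    "Decreased appetite", "Metabolism and nutrition disorders", 0.020,
    "Fluid retention", "Metabolism and nutrition disorders", 0.005,
    "Malnutrition", "Metabolism and nutrition disorders", 0.003,
    "Hypokalaemia", "Metabolism and nutrition disorders", 0.006,
    "Nephrolithiasis", "Renal and urinary disorders", 0.004,
    "Acute kidney injury", "Renal and urinary disorders", 0.010,
    "Renal impairment", "Renal and urinary disorders", 0.006,
    "Fatigue", "General disorders and administration site conditions", 0.060,
    "Pyrexia", "General disorders and administration site conditions", 0.030,
    "Asthenia", "General disorders and administration site conditions", 0.025,
    "Injection site pain", "General disorders and administration site conditions", 0.010,
    "Complication associated with device", "General disorders and administration site conditions", 0.003,
    "Headache", "Nervous system disorders", 0.045,
    "Dizziness", "Nervous system disorders", 0.030,
    "Cholelithiasis", "Hepatobiliary disorders", 0.004,
    "Hepatic enzyme increased", "Hepatobiliary disorders", 0.006,
    "Stoma complication", "Injury, poisoning and procedural complications", 0.002,
    "Gastrointestinal stoma complication", "Injury, poisoning and procedural complications", 0.002,
    "Hospitalisation", "Surgical and medical procedures", 0.025,
    "Therapy interrupted", "Surgical and medical procedures", 0.008,
    "Rash", "Skin and subcutaneous tissue disorders", 0.020,
    "Arthralgia", "Musculoskeletal and connective tissue disorders", 0.018,
    "Dyspnoea", "Respiratory, thoracic and mediastinal disorders", 0.020
  )
}

#' Default demographic sampling distributions
#'
#' Marginal categorical distributions for sex, age group, reporter
#' occupation and occurrence country used by [sim_faers()]. The defaults
#' mirror the demographic mix typical of published teduglutide FAERS
#' cohorts: a female majority, a large unknown-age fraction, mostly
#' consumer reporters, and US-dominated reporting.
#'
#' @return A named list of named probability vectors (`sex`, `age_group`,
#'   `reporter`, `country`).
#' @export
default_demographics <- function() {
  list(
    sex = c(female = 0.565, male = 0.342, unknown = 0.093),
    age_group = c(
      "<18" = 0.081, "18-44" = 0.086, "45-64" = 0.235,
      "65-74" = 0.122, ">=75" = 0.052, "unknown" = 0.424
    ),
    reporter = c(
      consumer = 0.404, pharmacist = 0.026, physician = 0.158,
      other = 0.394, unknown = 0.018
    ),
    country = c(
      US = 0.727, DE = 0.071, FR = 0.066, JP = 0.025, CA = 0.022, GB = 0.089
    )
  )
}

#' Simulation configuration for a synthetic FAERS-style database
#'
#' Defines every knob of the spontaneous-report generator: database size,
#' the share of reports whose primary-suspect (PS) drug is the target drug,
#' the background adverse-event vocabulary, planted reporting-rate ratios,
#' demographic and outcome distributions, a time-to-onset distribution,
#' the duplicate-injection rate and per-field missingness. The generator is
#' fully deterministic given `seed`.
#'
#' Planted signals act multiplicatively: in target-drug reports a planted
#' term's occurrence probability is `baseline * rate_ratio`, clipped to 1.
#' A `rate_ratio` of 1 everywhere yields a null database.
#'
#' @param n_reports Number of distinct safety reports (before duplicate
#'   injection). Must be >= 1.
#' @param drug_share Fraction of reports whose PS drug is the target drug.
#' @param background_pts Tibble with `pt`, `soc`, `baseline` columns; see
#'   [default_background_pts()].
#' @param planted_signals Optional tibble with `pt`, `rate_ratio` columns
#'   (rate ratios >= 0); every `pt` must appear in `background_pts`.
#' @param demographics Named list of probability vectors, see
#'   [default_demographics()].
#' @param serious_outcome_probs Named per-outcome-code Bernoulli
#'   probabilities over the FAERS codes DE, LT, HO, DS, CA, RI, OT.
#' @param onset Named list describing the therapy-start-to-event delay:
#'   `dist = "lognormal"` with `meanlog`, `sdlog` (days). Onsets are drawn
#'   right-truncated at the observation-window length; the default is
#'   calibrated so the *observed* onset distribution has median ~390 days
#'   with quartiles near 100 and 1000 — the long-tailed profile reported
#'   for chronic-use drugs.
#' @param duplicate_rate Fraction of reports re-emitted under a fresh
#'   PRIMARYID/CASEID (suspected duplicates).
#' @param missing_rates Named fractions of values blanked per field; fields
#'   `event_dt`, `start_dt`, `country` are supported.
#' @param partial_date_rate Fraction of emitted non-missing dates truncated
#'   to month or year precision, exercising parser tolerance.
#' @param target_drug_names Character vector of name variants under which
#'   the target drug appears in DRUG rows.
#' @param seed Integer RNG seed.
#' @return A validated `sim_config` list.
#' @seealso [sim_faers()], [write_faers()]
#' @export
sim_config <- function(n_reports,
                       drug_share = 0.05,
                       background_pts = default_background_pts(),
                       planted_signals = NULL,
                       demographics = default_demographics(),
                       serious_outcome_probs = c(
                         DE = 0.05, LT = 0.014, HO = 0.37, DS = 0.006,
                         CA = 0.002, RI = 0.002, OT = 0.15
                       ),
                       onset = list(dist = "lognormal",
                                    meanlog = 6.438, sdlog = 2.165),
                       duplicate_rate = 0.05,
                       missing_rates = c(event_dt = 0.2, start_dt = 0.5,
                                         country = 0.02),
                       partial_date_rate = 0.05,
                       target_drug_names = c("TEDUGLUTIDE", "REVESTIVE", "GATTEX"),
                       seed = 1L) {
  n_reports <- check_count(n_reports, "n_reports", min = 1)
  check_prob(drug_share, "drug_share")
  check_prob(duplicate_rate, "duplicate_rate")
  check_prob(partial_date_rate, "partial_date_rate")
  check_prob(serious_outcome_probs, "serious_outcome_probs")
  check_prob(missing_rates, "missing_rates")

  if (!all(c("pt", "soc", "baseline") %in% names(background_pts))) {
    stop_config("`background_pts` needs columns pt, soc, baseline")
  }
  if (anyDuplicated(background_pts$pt)) {
    stop_config("`background_pts` has duplicated pt entries")
  }
  check_prob(background_pts$baseline, "background_pts$baseline")

  if (is.null(planted_signals)) {
    planted_signals <- tibble::tibble(pt = character(), rate_ratio = numeric())
  }
  if (!all(c("pt", "rate_ratio") %in% names(planted_signals))) {
    stop_config("`planted_signals` needs columns pt, rate_ratio")
  }
  if (any(planted_signals$rate_ratio < 0)) {
    stop_config("`planted_signals$rate_ratio` must be >= 0")
  }
  missing_pt <- setdiff(planted_signals$pt, background_pts$pt)
  if (length(missing_pt)) {
    stop_config("planted pt not in background_pts: %s",
                paste(missing_pt, collapse = ", "))
  }
  for (nm in c("sex", "age_group", "reporter", "country")) {
    p <- demographics[[nm]]
    if (is.null(p) || is.null(names(p))) {
      stop_config("`demographics$%s` must be a named probability vector", nm)
    }
    check_prob(p / sum(p), paste0("demographics$", nm))
  }
  if (!identical(onset$dist, "lognormal")) {
    stop_config("`onset$dist` must be \"lognormal\"")
  }
  if (!is.finite(onset$meanlog) || !is.finite(onset$sdlog) || onset$sdlog <= 0) {
    stop_config("`onset` meanlog/sdlog invalid")
  }
  if (!length(target_drug_names)) {
    stop_config("`target_drug_names` must be non-empty")
  }

  structure(
    list(
      n_reports = n_reports, drug_share = drug_share,
      background_pts = tibble::as_tibble(background_pts),
      planted_signals = tibble::as_tibble(planted_signals),
      demographics = demographics,
      serious_outcome_probs = serious_outcome_probs,
      onset = onset, duplicate_rate = duplicate_rate,
      missing_rates = missing_rates, partial_date_rate = partial_date_rate,
      target_drug_names = toupper(target_drug_names),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Midpoint age sampler: uniform within the sampled age band, in years.
sample_age_years <- function(group) {
  lo <- c("<18" = 0.5, "18-44" = 18, "45-64" = 45, "65-74" = 65, ">=75" = 75)
  hi <- c("<18" = 17.99, "18-44" = 44.99, "45-64" = 64.99,
          "65-74" = 74.99, ">=75" = 95)
  out <- rep(NA_real_, length(group))
  known <- group != "unknown"
  out[known] <- runif(sum(known), lo[group[known]], hi[group[known]])
  out
}

# Truncate a fraction of YYYYMMDD strings to YYYYMM or YYYY.
truncate_dates <- function(x, rate) {
  nonmiss <- which(x != "")
  if (!length(nonmiss) || rate <= 0) return(x)
  pick <- nonmiss[runif(length(nonmiss)) < rate]
  if (!length(pick)) return(x)
  to_month <- pick[seq_along(pick) %% 2 == 1]
  to_year <- setdiff(pick, to_month)
  x[to_month] <- substr(x[to_month], 1, 6)
  x[to_year] <- substr(x[to_year], 1, 4)
  x
}

#' Generate a synthetic FAERS-style database with known ground truth
#'
#' Draws `n_reports` spontaneous reports under the configuration, assembles
#' the five FAERS quarterly tables (DEMO, DRUG, REAC, OUTC, THER) and a
#' ground-truth manifest: the true per-term rate ratio, the injected
#' duplicate CASEID pairs, and each report's true serious flag. Every
#' report carries at least one preferred term, and every target-drug report
#' carries the target drug with role code `PS`. Injected duplicates are
#' exact copies of an original report except for PRIMARYID, CASEID and
#' FDA_DT (the copy's FDA_DT is later), so they exercise both the
#' key-field and the CASEID deduplication paths downstream.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `faers_sim`: a list with `tables` (named list
#'   of tibbles `demo`, `drug`, `reac`, `outc`, `ther`), `truth` (list of
#'   tibbles `pts`, `duplicates`, `reports`) and the echoed `config`.
#' @examples
#' sim <- sim_faers(sim_config(n_reports = 500, seed = 42))
#' dplyr::count(sim$tables$drug, role_cod)
#' @export
sim_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  bg <- config$background_pts

  caseid <- 10000000L + seq_len(n)
  primaryid <- caseid * 10L + 1L

  n_target <- round(n * config$drug_share)
  is_target <- rep(FALSE, n)
  if (n_target > 0) is_target[sample.int(n, n_target)] <- TRUE

  demo_cfg <- config$demographics
  sex <- sample_cat(n, demo_cfg$sex)
  age_group <- sample_cat(n, demo_cfg$age_group)
  age_years <- sample_age_years(age_group)
  reporter <- sample_cat(n, demo_cfg$reporter)
  country <- sample_cat(n, demo_cfg$country)

  # onset is drawn from the configured lognormal right-truncated at the
  # window length (inverse-CDF), then the therapy start is placed uniformly
  # so the event stays inside the observation window; this keeps the
  # *observed* onset distribution at the configured profile instead of
  # piling events up at the window end
  window_start <- as.Date("2013-01-01")
  window_end <- as.Date("2023-09-30")
  window_len <- as.numeric(window_end - window_start)
  f_max <- stats::plnorm(window_len, config$onset$meanlog, config$onset$sdlog)
  onset_days <- round(stats::qlnorm(runif(n, 0, f_max),
                                    config$onset$meanlog, config$onset$sdlog))
  start_date <- window_start +
    floor(runif(n, 0, window_len - onset_days + 1))
  event_date <- start_date + onset_days

  # per-term occurrence: baseline, multiplied by the planted rate ratio in
  # target-drug reports, clipped to a valid probability
  rr <- setNames(rep(1, nrow(bg)), bg$pt)
  if (nrow(config$planted_signals)) {
    rr[config$planted_signals$pt] <- config$planted_signals$rate_ratio
  }
  p_bg <- matrix(bg$baseline, nrow = n, ncol = nrow(bg), byrow = TRUE)
  p_bg[is_target, ] <- sweep(p_bg[is_target, , drop = FALSE], 2, rr[bg$pt], `*`)
  p_bg <- pmin(p_bg, 1)
  hit <- matrix(runif(n * nrow(bg)), n) < p_bg
  none <- which(rowSums(hit) == 0L)
  if (length(none)) {
    forced <- sample.int(nrow(bg), length(none), replace = TRUE,
                         prob = bg$baseline)
    hit[cbind(none, forced)] <- TRUE
  }
  hit_idx <- which(hit, arr.ind = TRUE)
  hit_idx <- hit_idx[order(hit_idx[, 1], hit_idx[, 2]), , drop = FALSE]
  reac <- tibble::tibble(
    primaryid = primaryid[hit_idx[, 1]],
    pt = bg$pt[hit_idx[, 2]]
  )

  # outcomes: independent Bernoulli per code
  oc <- config$serious_outcome_probs
  outc_hit <- matrix(runif(n * length(oc)), n) <
    matrix(oc, nrow = n, ncol = length(oc), byrow = TRUE)
  oc_idx <- which(outc_hit, arr.ind = TRUE)
  oc_idx <- oc_idx[order(oc_idx[, 1], oc_idx[, 2]), , drop = FALSE]
  outc <- tibble::tibble(
    primaryid = primaryid[oc_idx[, 1]],
    outc_cod = names(oc)[oc_idx[, 2]]
  )
  serious_true <- rowSums(outc_hit[, names(oc) %in% c("DE", "LT", "HO", "DS"),
                                   drop = FALSE]) > 0

  # drug rows: one PS drug per report; target reports carry the target drug
  # under a random name variant. A minority of reports add a concomitant
  # row; occasionally that concomitant is the target drug, so role filtering
  # is exercised.
  other_drugs <- sprintf("COMPARATOR_%02d", 1:20)
  ps_name <- ifelse(
    is_target,
    sample(config$target_drug_names, n, replace = TRUE),
    sample(other_drugs, n, replace = TRUE)
  )
  drug <- tibble::tibble(
    primaryid = primaryid, drug_seq = 1L, role_cod = "PS", drugname = ps_name
  )
  conc <- which(runif(n) < 0.3)
  if (length(conc)) {
    conc_name <- sample(other_drugs, length(conc), replace = TRUE)
    swap <- !is_target[conc] & runif(length(conc)) < 0.02
    conc_name[swap] <- sample(config$target_drug_names, sum(swap), replace = TRUE)
    drug <- dplyr::bind_rows(drug, tibble::tibble(
      primaryid = primaryid[conc], drug_seq = 2L,
      role_cod = "C", drugname = conc_name
    ))
  }
  # age emitted with a unit code: infants in months, a sprinkle of days
  age_cod <- ifelse(is.na(age_years), "",
                    ifelse(age_years < 2, "MON", "YR"))
  in_days <- which(age_cod == "YR" & runif(n) < 0.02)
  age_cod[in_days] <- "DY"
  age_val <- dplyr::case_when(
    is.na(age_years) ~ "",
    age_cod == "MON" ~ as.character(round(age_years * 12)),
    age_cod == "DY" ~ as.character(round(age_years * 365.25)),
    TRUE ~ as.character(round(age_years))
  )

  sex_cod <- c(female = "F", male = "M", unknown = "")[sex]
  occp_cod <- c(consumer = "CN", pharmacist = "PH", physician = "MD",
                other = "HP", unknown = "")[reporter]

  # originals are made pairwise distinct on the duplicate-screening key
  # (age, sex, country, event date) by nudging colliding event dates, so
  # the injected duplicates are the complete key-sharing ground truth
  # reports with a missing age or sex can never be dropped by the rule, so
  # they get unique sentinel keys and are left untouched
  complete_key <- age_val != "" & sex_cod != ""
  for (i in 1:50) {
    key <- paste(age_val, sex_cod, country, as.integer(event_date))
    key[!complete_key] <- paste0("incomplete_", which(!complete_key))
    clash <- which(duplicated(key))
    if (!length(clash)) break
    shift <- ifelse(event_date[clash] < window_end, 1, -1)
    event_date[clash] <- event_date[clash] + shift
    onset_days[clash] <- pmax(0, as.numeric(event_date[clash] -
                                              start_date[clash]))
  }

  fda_date <- pmin(event_date + floor(runif(n, 0, 181)), window_end)

  # field-level missingness, then partial-date truncation, on emitted text
  mr <- config$missing_rates
  event_txt <- format_faers_date(event_date)
  start_txt <- format_faers_date(start_date)
  country_txt <- country
  if (!is.na(mr["event_dt"]) && mr["event_dt"] > 0) {
    event_txt[runif(n) < mr["event_dt"]] <- ""
  }
  if (!is.na(mr["start_dt"]) && mr["start_dt"] > 0) {
    start_txt[runif(n) < mr["start_dt"]] <- ""
  }
  if (!is.na(mr["country"]) && mr["country"] > 0) {
    country_txt[runif(n) < mr["country"]] <- ""
  }
  event_txt <- truncate_dates(event_txt, config$partial_date_rate)
  start_txt <- truncate_dates(start_txt, config$partial_date_rate)

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format_faers_date(fda_date),
    event_dt = event_txt,
    age = age_val, age_cod = age_cod, sex = sex_cod,
    occp_cod = occp_cod, occr_country = country_txt
  )
  ther <- tibble::tibble(primaryid = primaryid, dsg_seq = 1L,
                         start_dt = start_txt)

  # duplicate injection: exact copies except PRIMARYID/CASEID/FDA_DT
  n_dup <- round(n * config$duplicate_rate)
  dup_pairs <- tibble::tibble(caseid_original = integer(),
                              caseid_duplicate = integer(),
                              primaryid_original = integer(),
                              primaryid_duplicate = integer())
  if (n_dup > 0) {
    src <- sample.int(n, n_dup)
    dup_caseid <- 90000000L + seq_len(n_dup)
    dup_primaryid <- dup_caseid * 10L + 1L
    dup_fda <- format_faers_date(
      pmin(fda_date[src] + 1 + floor(runif(n_dup, 0, 60)),
           window_end + 90)
    )
    dup_demo <- demo[src, ]
    dup_demo$primaryid <- dup_primaryid
    dup_demo$caseid <- dup_caseid
    dup_demo$fda_dt <- dup_fda
    demo <- dplyr::bind_rows(demo, dup_demo)

    remap <- function(tbl) {
      idx <- match(tbl$primaryid, primaryid[src])
      sub <- tbl[!is.na(idx), ]
      sub$primaryid <- dup_primaryid[idx[!is.na(idx)]]
      dplyr::bind_rows(tbl, sub)
    }
    drug <- remap(drug)
    reac <- remap(reac)
    outc <- remap(outc)
    ther <- remap(ther)

    dup_pairs <- tibble::tibble(
      caseid_original = caseid[src], caseid_duplicate = dup_caseid,
      primaryid_original = primaryid[src], primaryid_duplicate = dup_primaryid
    )
  }

  truth <- list(
    pts = dplyr::mutate(bg, rate_ratio = unname(rr[bg$pt])),
    duplicates = dup_pairs,
    reports = tibble::tibble(
      primaryid = primaryid, caseid = caseid,
      is_target = is_target, serious = serious_true,
      onset_days = as.integer(as.numeric(event_date - start_date))
    )
  )

  structure(
    list(
      tables = list(demo = demo, drug = drug, reac = reac,
                    outc = outc, ther = ther),
      truth = truth, config = config
    ),
    class = "faers_sim"
  )
}

#' Write tables in the FAERS quarterly ASCII dialect
#'
#' Writes one `$`-delimited file per table (`DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `OUTC.txt`, `THER.txt`) with a header row, exactly as the
#' public quarterly extracts are distributed. The dialect has no quoting
#' mechanism, so any field containing the `$` delimiter is rejected. When a
#' full simulation object is given, the ground-truth manifest (planted rate
#' ratios, duplicate pairs, per-report flags) is written as TSV alongside,
#' plus a YAML echo of the scalar simulation settings.
#'
#' @param x A `faers_sim` object or a named list of tables
#'   (`demo`, `drug`, `reac`, `outc`, `ther`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of files written.
#' @export
write_faers <- function(x, dir) {
  tables <- if (inherits(x, "faers_sim")) x$tables else x
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", dir))
  }
  files <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
             outc = "OUTC.txt", ther = "THER.txt")
  written <- character()
  for (nm in names(files)) {
    tbl <- tables[[nm]]
    if (is.null(tbl)) next
    chr <- dplyr::mutate(tbl, dplyr::across(
      dplyr::everything(), ~ ifelse(is.na(.x), "", as.character(.x))
    ))
    if (any(vapply(chr, function(col) any(grepl("$", col, fixed = TRUE)),
                   logical(1)))) {
      abort(sprintf(
        "table '%s' contains the '$' delimiter in a field; the FAERS ASCII dialect has no quoting",
        nm
      ), class = "faersignal_config_error")
    }
    path <- file.path(dir, files[[nm]])
    lines <- c(
      paste(names(chr), collapse = "$"),
      if (nrow(chr)) do.call(paste, c(unname(as.list(chr)), sep = "$"))
    )
    writeLines(lines, path)
    written[nm] <- path
  }
  if (inherits(x, "faers_sim")) {
    readr::write_tsv(x$truth$pts, file.path(dir, "GROUND_TRUTH_PTS.tsv"))
    readr::write_tsv(x$truth$duplicates,
                     file.path(dir, "GROUND_TRUTH_DUPLICATES.tsv"))
    readr::write_tsv(x$truth$reports,
                     file.path(dir, "GROUND_TRUTH_REPORTS.tsv"))
    readr::write_tsv(
      dplyr::select(x$truth$pts, "pt", "soc"),
      file.path(dir, "PT_SOC_MAP.tsv")
    )
    cfg <- x$config
    yaml::write_yaml(
      list(
        n_reports = cfg$n_reports, drug_share = cfg$drug_share,
        duplicate_rate = cfg$duplicate_rate,
        partial_date_rate = cfg$partial_date_rate,
        missing_rates = as.list(cfg$missing_rates),
        serious_outcome_probs = as.list(cfg$serious_outcome_probs),
        onset = cfg$onset,
        target_drug_names = as.list(cfg$target_drug_names),
        seed = cfg$seed
      ),
      file.path(dir, "sim_config.yaml")
    )
    written["config"] <- file.path(dir, "sim_config.yaml")
  }
  invisible(written)
}
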