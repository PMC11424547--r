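# Parsing and harmonisation of FAERS-dialect quarterly tables.

# age-unit codes -> multiplier converting the stored value to years
AGE_UNIT_TO_YEARS <- c(
  DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143,
  DY = 1 / 365.25, HR = 1 / 8766
)

AGE_GROUP_LEVELS <- c("<18", "18-44", "45-64", "65-74", ">=75", "unknown")
SERIOUS_OUTCOMES <- c("DE", "LT", "HO", "DS")

read_dollar_file <- function(path, required) {
  if (!file.exists(path)) {
    stop_schema("file '%s' not found", path)
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_schema("file '%s' is empty (no header row)", path)
  header <- strsplit(lines[[1]], "$", fixed = TRUE)[[1]]
  miss <- setdiff(required, header)
  if (length(miss)) {
    stop_schema("file '%s' is missing mandatory column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  # count delimiters to judge the field count: strsplit drops trailing
  # empty fields, which are legitimate
  nf <- stringr::str_count(body, stringr::fixed("$")) + 1L
  good <- nf == length(header)
  n_malformed <- sum(!good)
  fields <- strsplit(body[good], "$", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    c(f, rep("", length(header) - length(f)))
  })
  mat <- do.call(rbind, fields)
  tbl <- if (is.null(mat)) {
    tibble::as_tibble(setNames(
      replicate(length(header), character(0), simplify = FALSE), header
    ))
  } else {
    tibble::as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE),
                               header))
  }
  attr(tbl, "n_malformed") <- n_malformed
  tbl
}

#' Read a directory of FAERS-dialect quarterly tables
#'
#' Reads `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt` and `THER.txt`
#' (`$`-delimited, header row) and harmonises them into analysis-ready
#' tibbles:
#'
#' * `reports` — one row per raw report (one per PRIMARYID), with parsed
#'   dates, sex, age harmonised to years via the age-unit code
#'   (DEC x 10, YR x 1, MON / 12, WK / 52.143, DY / 365.25, HR / 8766),
#'   age group in completed years, reporter occupation, occurrence country,
#'   the outcome-code set and the derived `serious` flag (death,
#'   life-threatening, hospitalisation, disability).
#' * `drugs` — drug mentions with role code and therapy start date
#'   (joined from THER).
#' * `reactions` — one row per (report, preferred term), case-normalised.
#'
#' Rows with the wrong field count are skipped and counted; the counts are
#' returned in the `malformed` element so nothing is dropped silently.
#'
#' @param dir Directory containing the five files.
#' @return A list with elements `reports`, `drugs`, `reactions`,
#'   `malformed` (named integer vector).
#' @export
read_faers <- function(dir) {
  demo <- read_dollar_file(file.path(dir, "DEMO.txt"),
                           c("primaryid", "caseid", "fda_dt"))
  drug <- read_dollar_file(file.path(dir, "DRUG.txt"),
                           c("primaryid", "role_cod", "drugname"))
  reac <- read_dollar_file(file.path(dir, "REAC.txt"), c("primaryid", "pt"))
  outc <- read_dollar_file(file.path(dir, "OUTC.txt"),
                           c("primaryid", "outc_cod"))
  ther <- read_dollar_file(file.path(dir, "THER.txt"), c("primaryid"))

  malformed <- c(
    demo = attr(demo, "n_malformed"), drug = attr(drug, "n_malformed"),
    reac = attr(reac, "n_malformed"), outc = attr(outc, "n_malformed"),
    ther = attr(ther, "n_malformed")
  )

  list(
    reports = harmonize_demo(demo, outc),
    drugs = harmonize_drug(drug, ther),
    reactions = harmonize_reac(reac),
    malformed = malformed
  )
}

harmonize_demo <- function(demo, outc) {
  fda <- parse_faers_date(demo$fda_dt)
  event <- parse_faers_date(demo[["event_dt"]] %||% rep("", nrow(demo)))

  age_raw <- suppressWarnings(as.numeric(demo[["age"]] %||% NA))
  age_cod <- toupper(demo[["age_cod"]] %||% "")
  mult <- unname(AGE_UNIT_TO_YEARS[age_cod])
  mult[is.na(mult) & !is.na(age_raw)] <- 1  # blank unit: assume years
  age_years <- age_raw * mult
  age_years[!is.na(age_years) & age_years < 0] <- NA_real_

  sex <- dplyr::case_when(
    toupper(demo[["sex"]] %||% "") == "F" ~ "female",
    toupper(demo[["sex"]] %||% "") == "M" ~ "male",
    TRUE ~ "unknown"
  )
  reporter <- dplyr::case_when(
    toupper(demo[["occp_cod"]] %||% "") == "CN" ~ "consumer",
    toupper(demo[["occp_cod"]] %||% "") == "PH" ~ "pharmacist",
    toupper(demo[["occp_cod"]] %||% "") == "MD" ~ "physician",
    toupper(demo[["occp_cod"]] %||% "") %in% c("HP", "OT", "LW") ~
      "other health professional",
    TRUE ~ "unknown"
  )
  country <- stringr::str_trim(demo[["occr_country"]] %||% "")
  if (!is.null(demo[["reporter_country"]])) {
    fallback <- stringr::str_trim(demo[["reporter_country"]])
    country <- ifelse(country == "", fallback, country)
  }
  country[country == ""] <- NA_character_

  outcome_sets <- outc |>
    dplyr::mutate(primaryid = as.integer(.data$primaryid),
                  outc_cod = toupper(.data$outc_cod)) |>
    dplyr::distinct(.data$primaryid, .data$outc_cod) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcomes = list(sort(.data$outc_cod)), .groups = "drop")

  tibble::tibble(
    primaryid = as.integer(demo$primaryid),
    caseid = as.integer(demo$caseid),
    fda_dt = fda$key,
    event_dt = event$key,
    event_precision = event$precision,
    event_date = event$date,
    sex = sex,
    age_years = age_years,
    age_group = age_group_of(age_years),
    reporter = reporter,
    country = country
  ) |>
    dplyr::left_join(outcome_sets,
                     by = dplyr::join_by("primaryid" == "primaryid")) |>
    dplyr::mutate(
      outcomes = purrr::map(.data$outcomes, ~ .x %||% character()),
      serious = purrr::map_lgl(.data$outcomes,
                               ~ length(intersect(.x, SERIOUS_OUTCOMES)) > 0),
      year = as.integer(.data$fda_dt %/% 10000L)
    )
}

harmonize_drug <- function(drug, ther) {
  start <- if ("start_dt" %in% names(ther)) {
    st <- parse_faers_date(ther$start_dt)
    tibble::tibble(
      primaryid = as.integer(ther$primaryid),
      dsg_seq = as.integer(ther[["dsg_seq"]] %||% 1L),
      start_dt = st$key, start_date = st$date
    )
  } else {
    tibble::tibble(primaryid = integer(), dsg_seq = integer(),
                   start_dt = integer(), start_date = as.Date(character()))
  }
  tibble::tibble(
    primaryid = as.integer(drug$primaryid),
    drug_seq = as.integer(drug[["drug_seq"]] %||% 1L),
    role = toupper(stringr::str_trim(drug$role_cod)),
    drugname = stringr::str_squish(drug$drugname)
  ) |>
    dplyr::left_join(start, by = dplyr::join_by("primaryid" == "primaryid",
                                                "drug_seq" == "dsg_seq"))
}

harmonize_reac <- function(reac) {
  tibble::tibble(
    primaryid = as.integer(reac$primaryid),
    pt = normalize_pt(reac$pt)
  ) |>
    dplyr::filter(.data$pt != "") |>
    dplyr::distinct()
}

# MedDRA preferred terms are stored with inconsistent casing across
# quarters; normalise to sentence case on squished whitespace.
normalize_pt <- function(x) {
  x <- stringr::str_squish(x)
  out <- stringr::str_to_lower(x)
  substr(out, 1, 1) <- toupper(substr(out, 1, 1))
  out
}

#' Assign the standard age strata used in FAERS demographic tables
#'
#' Boundaries in completed years: `<18`, `18-44`, `45-64`, `65-74`, `>=75`;
#' missing ages map to `"unknown"`. 17.9 years is `<18`.
#'
#' @param age_years Numeric vector of ages in years (NA allowed).
#' @return Character vector of age-group labels.
#' @export
age_group_of <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "<18",
    age_years < 45 ~ "18-44",
    age_years < 65 ~ "45-64",
    age_years < 75 ~ "65-74",
    TRUE ~ ">=75"
  )
}

#' Keep the most recent report per case
#'
#' FAERS cases are versioned: a CASEID can recur across quarters as the
#' report is updated. Following FDA guidance, only the entry with the
#' maximal FDA_DT is kept per CASEID; with identical CASEID and FDA_DT the
#' highest PRIMARYID wins. The operation is idempotent.
#'
#' @param reports Harmonised report tibble (see [read_faers()]).
#' @return The deduplicated tibble, one row per CASEID.
#' @export
dedup_reports <- function(reports) {
  reports |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$fda_dt),
                   dplyr::desc(.data$primaryid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE)
}

#' Drop suspected duplicates that share all key fields
#'
#' Distinct cases describing the same adverse event are screened by the key
#' fields age, sex, country and event date. Among reports agreeing on all
#' four fields — each non-missing — only one survivor is kept: the earliest
#' FDA_DT, ties broken by the lowest PRIMARYID. Reports with any missing
#' key field are never dropped. Intended to run after [dedup_reports()] and
#' within the target-drug report set.
#'
#' @param reports Deduplicated report tibble.
#' @return Tibble with suspected field-level duplicates removed; the number
#'   removed is available as `attr(, "n_dropped")`.
#' @export
drop_field_duplicates <- function(reports) {
  complete <- !is.na(reports$age_years) & reports$sex != "unknown" &
    !is.na(reports$country) & !is.na(reports$event_dt)
  keep_always <- reports[!complete, ]
  candidates <- reports[complete, ]
  survivors <- candidates |>
    dplyr::arrange(.data$fda_dt, .data$primaryid) |>
    dplyr::distinct(.data$age_years, .data$sex, .data$country,
                    .data$event_dt, .keep_all = TRUE)
  out <- dplyr::bind_rows(keep_always, survivors) |>
    dplyr::arrange(.data$primaryid)
  attr(out, "n_dropped") <- nrow(reports) - nrow(out)
  out
}

#' Select reports naming the target drug as primary suspect
#'
#' A report is selected iff at least one of its drug records has role `PS`
#' and a drug name matching one of the synonyms, case-insensitively on
#' trimmed names. Exact matching is the default; `substring = TRUE` also
#' accepts names that merely contain a synonym (e.g. trade name plus
#' strength). Adding synonyms can only grow the selected set.
#'
#' @param reports Report tibble.
#' @param drugs Drug-record tibble (from [read_faers()]).
#' @param synonyms Non-empty character vector of drug-name keywords.
#' @param substring Match synonyms as substrings of the drug name.
#' @return The subset of `reports` that are target-drug reports.
#' @export
select_target_reports <- function(reports, drugs, synonyms,
                                  substring = FALSE) {
  if (!length(synonyms)) {
    stop_config("`synonyms` must be a non-empty character vector")
  }
  syn <- toupper(stringr::str_trim(synonyms))
  nm <- toupper(stringr::str_trim(drugs$drugname))
  hit <- if (substring) {
    Reduce(`|`, lapply(syn, function(s) {
      stringr::str_detect(nm, stringr::fixed(s))
    }))
  } else {
    nm %in% syn
  }
  ids <- unique(drugs$primaryid[hit & drugs$role == "PS"])
  dplyr::filter(reports, .data$primaryid %in% ids)
}

#' Load a preferred-term to system-organ-class mapping
#'
#' Reads a two-column TSV (`pt`, `soc`) giving each preferred term its
#' primary system organ class — a simplified two-level stand-in for the
#' licensed MedDRA hierarchy. Duplicate PT keys are a load error because
#' the map must be a function.
#'
#' @param path Path to the TSV file (header row `pt<TAB>soc`).
#' @return A tibble with normalised `pt` and `soc` columns.
#' @export
read_pt_soc_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("pt", "soc") %in% names(map))) {
    stop_schema("PT->SOC map '%s' must have columns pt, soc", path)
  }
  map <- dplyr::mutate(map, pt = normalize_pt(.data$pt),
                       soc = stringr::str_squish(.data$soc))
  if (anyDuplicated(map$pt)) {
    stop_schema("PT->SOC map '%s' has duplicate pt keys", path)
  }
  dplyr::select(map, "pt", "soc")
}

#' Annotate reactions with their system organ class
#'
#' @param reactions Reaction tibble with a `pt` column.
#' @param pt_soc_map Mapping tibble from [read_pt_soc_map()] (or any tibble
#'   with unique `pt` plus `soc`).
#' @param unmapped Policy for PTs absent from the map: `"keep"` annotates
#'   them with the sentinel SOC `"UNMAPPED"`; `"strict"` raises an error.
#' @return `reactions` with a `soc` column; the number of unmapped PT rows
#'   is available as `attr(, "n_unmapped")`.
#' @export
map_pts <- function(reactions, pt_soc_map, unmapped = c("keep", "strict")) {
  unmapped <- match.arg(unmapped)
  if (anyDuplicated(pt_soc_map$pt)) {
    stop_schema("PT->SOC map has duplicate pt keys")
  }
  out <- dplyr::left_join(reactions, pt_soc_map,
                          by = dplyr::join_by("pt" == "pt"))
  n_un <- sum(is.na(out$soc))
  if (n_un > 0 && unmapped == "strict") {
    bad <- unique(out$pt[is.na(out$soc)])
    stop_schema("unmapped preferred term(s): %s",
                paste(head(bad, 5), collapse = ", "))
  }
  out$soc[is.na(out$soc)] <- "UNMAPPED"
  attr(out, "n_unmapped") <- n_un
  out
}
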