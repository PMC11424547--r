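test_that("compact dates parse at day, month and year precision", {
  out <- parse_faers_date(c("20230301", "202303", "2023", "", "20231340", "20xx"))
  expect_equal(out$precision,
               c("day", "month", "year", NA, NA, NA))
  expect_equal(out$key[1:3], c(20230301L, 20230300L, 20230000L))
  expect_equal(out$date[[1]], as.Date("2023-03-01"))
  expect_true(all(is.na(out$date[-1])))
  # partial dates sort before complete dates of the same year-month
  expect_lt(parse_faers_date("202303")$key, parse_faers_date("20230301")$key)
})

test_that("age is harmonised to years via the unit code", {
  d <- withr::local_tempdir()
  demo <- tibble::tibble(
    primaryid = as.character(1:7), caseid = as.character(1:7),
    fda_dt = "20230101",
    age = c("540", "45", "4.5", "1043", "9131", "394470", "-3"),
    age_cod = c("MON", "YR", "DEC", "WK", "DY", "HR", "YR"),
    sex = "F", occp_cod = "MD", occr_country = "US"
  )
  write_faers(list(
    demo = demo,
    drug = tibble::tibble(primaryid = "1", role_cod = "PS", drugname = "X"),
    reac = tibble::tibble(primaryid = "1", pt = "Nausea"),
    outc = tibble::tibble(primaryid = character(), outc_cod = character()),
    ther = tibble::tibble(primaryid = character(), start_dt = character())
  ), d)
  rep <- read_faers(d)$reports
  expect_equal(rep$age_years[1], 45)
  expect_equal(rep$age_years[2], 45)
  expect_equal(rep$age_years[3], 45)
  expect_equal(rep$age_years[4], 1043 / 52.143, tolerance = 1e-10)
  expect_equal(rep$age_years[5], 9131 / 365.25, tolerance = 1e-10)
  expect_equal(rep$age_years[6], 394470 / 8766, tolerance = 1e-10)
  expect_true(is.na(rep$age_years[7]))  # negative age is treated as missing
})

test_that("year-precision event dates are kept but excluded from day arithmetic", {
  out <- parse_faers_date("2023")
  expect_equal(out$key, 20230000L)
  expect_true(is.na(out$date))
})

test_that("rows with the wrong field count are counted and skipped", {
  d <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt",
               "11$1$20230101",
               "bad$row",
               "21$2$20230201"), file.path(d, "DEMO.txt"))
  for (f in c("DRUG.txt", "REAC.txt", "OUTC.txt", "THER.txt")) {
    hdr <- c(DRUG.txt = "primaryid$role_cod$drugname",
             REAC.txt = "primaryid$pt", OUTC.txt = "primaryid$outc_cod",
             THER.txt = "primaryid$start_dt")[[f]]
    writeLines(hdr, file.path(d, f))
  }
  raw <- read_faers(d)
  expect_equal(unname(raw$malformed["demo"]), 1L)
  expect_equal(nrow(raw$reports), 2)
})

test_that("a missing mandatory column raises a schema error naming it", {
  d <- withr::local_tempdir()
  writeLines("primaryid$caseid", file.path(d, "DEMO.txt"))
  expect_error(read_faers(d), "fda_dt", class = "faersignal_schema_error")
})

test_that("case-level dedup keeps max fda_dt, then max primaryid, and is idempotent", {
  reps <- mk_reports(4,
    primaryid = c(17L, 23L, 31L, 40L),
    caseid = c(1L, 1L, 1L, 2L),
    fda_dt = c(20230301L, 20230301L, 20230101L, 20230501L)
  )
  out <- dedup_reports(reps)
  expect_equal(sort(out$primaryid), c(23L, 40L))   # ties broken by primaryid
  expect_equal(out$fda_dt[out$caseid == 1], 20230301L)
  expect_identical(dedup_reports(out), out)        # idempotent
  expect_equal(anyDuplicated(out$caseid), 0L)

  uniq <- mk_reports(3, caseid = 1:3)
  expect_identical(dedup_reports(uniq) |> dplyr::arrange(primaryid), uniq)
  expect_equal(nrow(dedup_reports(mk_reports(0))), 0)
})

test_that("field-level dedup keeps the earliest fda_dt and never drops incomplete keys", {
  reps <- mk_reports(5,
    primaryid = c(11L, 21L, 31L, 41L, 51L),
    caseid = 1:5,
    fda_dt = c(20230301L, 20230101L, 20230101L, 20230601L, 20230601L),
    country = c("US", "US", "US", NA, NA)
  )
  out <- drop_field_duplicates(reps)
  # rows 1-3 share all four key fields: survivor is earliest fda_dt with
  # the lowest primaryid on ties (rows 2 vs 3 tie at 20230101 -> 21)
  expect_true(21L %in% out$primaryid)
  expect_false(any(c(11L, 31L) %in% out$primaryid))
  # rows 4-5 agree on the keys but country is missing: both kept
  expect_true(all(c(41L, 51L) %in% out$primaryid))
  expect_equal(attr(out, "n_dropped"), 2L)
  expect_lte(nrow(out), nrow(reps))
  expect_true(all(out$primaryid %in% reps$primaryid))
  expect_equal(nrow(drop_field_duplicates(mk_reports(0))), 0)
})

test_that("target selection needs role PS and a synonym match", {
  reps <- mk_reports(4)
  drugs <- dplyr::bind_rows(
    mk_drugs(11L, role = "PS", drugname = "Gattex"),
    mk_drugs(21L, role = "C", drugname = "TEDUGLUTIDE"),
    mk_drugs(31L, role = "PS", drugname = "REVESTIVE 5MG"),
    mk_drugs(41L, role = "PS", drugname = "METFORMIN")
  )
  syn <- c("TEDUGLUTIDE", "REVESTIVE", "GATTEX")
  exact <- select_target_reports(reps, drugs, syn)
  expect_setequal(exact$primaryid, 11L)            # case-insensitive match
  sub <- select_target_reports(reps, drugs, syn, substring = TRUE)
  expect_setequal(sub$primaryid, c(11L, 31L))      # trade name + strength
  expect_error(select_target_reports(reps, drugs, character()),
               class = "faersignal_config_error")
})

test_that("adding synonyms never shrinks the target set", {
  sim <- small_planted_sim(seed = 77, n = 1000)
  h <- harmonize_sim(sim)
  reports <- dedup_reports(h$reports)
  s1 <- select_target_reports(reports, h$drugs, "TEDUGLUTIDE")
  s2 <- select_target_reports(reports, h$drugs, c("TEDUGLUTIDE", "GATTEX"))
  s3 <- select_target_reports(reports, h$drugs,
                              c("TEDUGLUTIDE", "GATTEX", "REVESTIVE"))
  expect_true(all(s1$primaryid %in% s2$primaryid))
  expect_true(all(s2$primaryid %in% s3$primaryid))
})

test_that("PT-to-SOC mapping applies the unmapped policy", {
  map <- tibble::tibble(pt = c("Nephrolithiasis", "Nausea"),
                        soc = c("Renal and urinary disorders",
                                "Gastrointestinal disorders"))
  rx <- mk_reactions(c(11L, 21L), c("Nephrolithiasis", "Pyrexia"))
  out <- map_pts(rx, map, unmapped = "keep")
  expect_equal(out$soc, c("Renal and urinary disorders", "UNMAPPED"))
  expect_equal(attr(out, "n_unmapped"), 1L)
  expect_error(map_pts(rx, map, unmapped = "strict"), "Pyrexia",
               class = "faersignal_schema_error")

  dup_map <- tibble::tibble(pt = c("Nausea", "Nausea"), soc = c("A", "B"))
  expect_error(map_pts(rx, dup_map), class = "faersignal_schema_error")
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dup_map, f)
  expect_error(read_pt_soc_map(f), class = "faersignal_schema_error")
})

test_that("generated duplicates are exactly the reports the dedup stages remove", {
  cfg <- sim_config(n_reports = 800, drug_share = 0.3, duplicate_rate = 0.15,
                    missing_rates = c(event_dt = 0, start_dt = 0, country = 0),
                    partial_date_rate = 0, seed = 21)
  sim <- sim_faers(cfg)
  h <- harmonize_sim(sim)
  out <- dedup_reports(h$reports)
  # CASEID stage alone removes nothing here (each duplicate has a fresh
  # CASEID); the field stage, run within the target drug, must remove
  # precisely the injected copies of target reports
  target <- select_target_reports(out, h$drugs,
                                  c("TEDUGLUTIDE", "REVESTIVE", "GATTEX"))
  dedup2 <- drop_field_duplicates(target)
  removed <- setdiff(target$primaryid, dedup2$primaryid)
  injected <- sim$truth$duplicates$primaryid_duplicate
  # injected copies carry a later fda_dt, so originals survive; only
  # copies with all four key fields present are removable
  complete_keys <- !is.na(h$reports$age_years) & h$reports$sex != "unknown" &
    !is.na(h$reports$country) & !is.na(h$reports$event_dt)
  expected_removed <- intersect(
    injected[complete_keys[match(injected, h$reports$primaryid)]],
    target$primaryid
  )
  expect_gt(length(expected_removed), 0)
  expect_setequal(removed, expected_removed)
  # idempotence of both stages
  expect_identical(drop_field_duplicates(dedup2)$primaryid, dedup2$primaryid)
})
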