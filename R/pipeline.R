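# End-to-end runs: simulate -> ingest -> dedup -> tables -> statistics ->
# screen -> rank, with an auditable stage-count manifest. These functions
# back the command-line entry points in inst/cli/faersignal.R.

#' Simulate a synthetic database to disk
#'
#' Wraps [sim_faers()] + [write_faers()]; the ground-truth manifest and a
#' YAML echo of the configuration are written alongside the five quarterly
#' tables.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, the named vector of files written.
#' @export
run_simulate <- function(config, dir) {
  sim <- sim_faers(config)
  files <- write_faers(sim, dir)
  invisible(files)
}

#' Harmonise an in-memory simulation without a disk round trip
#'
#' Applies the same field harmonisation as [read_faers()] directly to the
#' tables of a [sim_faers()] object, for simulation studies where writing
#' the FAERS-dialect files is unnecessary.
#'
#' @param sim A `faers_sim` object.
#' @return A list with `reports`, `drugs`, `reactions`, `malformed`
#'   (all-zero) — the same shape as [read_faers()].
#' @export
harmonize_sim <- function(sim) {
  stopifnot(inherits(sim, "faers_sim"))
  list(
    reports = harmonize_demo(sim$tables$demo, sim$tables$outc),
    drugs = harmonize_drug(sim$tables$drug, sim$tables$ther),
    reactions = harmonize_reac(sim$tables$reac),
    malformed = c(demo = 0L, drug = 0L, reac = 0L, outc = 0L, ther = 0L)
  )
}

# shared ingest + dedup + target selection front-end
ingest_stage <- function(input_dir, synonyms, substring = FALSE) {
  raw <- if (inherits(input_dir, "faers_sim")) {
    harmonize_sim(input_dir)
  } else {
    read_faers(input_dir)
  }
  n_parsed <- nrow(raw$reports)
  reports <- dedup_reports(raw$reports)
  n_dedup <- nrow(reports)

  target0 <- select_target_reports(reports, raw$drugs, synonyms,
                                   substring = substring)
  target <- drop_field_duplicates(target0)
  dropped <- setdiff(target0$primaryid, target$primaryid)
  reports <- dplyr::filter(reports, !.data$primaryid %in% dropped)

  manifest <- tibble::tibble(
    stage = c("parsed", "malformed_rows", "caseid_deduplicated",
              "target_before_field_dedup", "field_duplicates_dropped",
              "target", "database_total"),
    n = c(n_parsed, sum(raw$malformed), n_dedup, nrow(target0),
          length(dropped), nrow(target), nrow(reports))
  )
  list(reports = reports, target = target, drugs = raw$drugs,
       reactions = raw$reactions, manifest = manifest)
}

resolve_map <- function(pt_soc_map, input_dir) {
  if (is.data.frame(pt_soc_map)) return(pt_soc_map)
  if (is.character(pt_soc_map)) return(read_pt_soc_map(pt_soc_map))
  if (inherits(input_dir, "faers_sim")) {
    map <- dplyr::select(input_dir$truth$pts, "pt", "soc")
    return(dplyr::mutate(map, pt = normalize_pt(.data$pt)))
  }
  default <- file.path(input_dir, "PT_SOC_MAP.tsv")
  if (file.exists(default)) return(read_pt_soc_map(default))
  NULL
}

#' Run the disproportionality signal pipeline
#'
#' Ingests a FAERS-dialect directory, deduplicates (CASEID stage, then the
#' key-field stage within the target drug), selects primary-suspect target
#' reports, builds contingency tables at the requested level, computes all
#' four statistics, screens against the threshold policy and ranks. The
#' PT-level default policy is the all-four consensus rule; at SOC level
#' the customary any-one rule applies.
#'
#' @param input_dir Directory of FAERS-dialect files, or a `faers_sim`
#'   object to analyse in memory.
#' @param synonyms Target-drug name keywords.
#' @param pt_soc_map Mapping tibble, a TSV path, or `NULL` to use
#'   `PT_SOC_MAP.tsv` in `input_dir` when present.
#' @param level `"pt"` or `"soc"`.
#' @param policy A [threshold_policy()]; defaults to all-four at PT level
#'   and any-one at SOC level.
#' @param min_count Minimum report count per term.
#' @param unit Counting denominator, `"report"` or `"pair"`.
#' @param substring Substring drug-name matching.
#' @param correction,yates,bcpnn Statistic options, see
#'   [disprop_scores()].
#' @param top_k Rows in the ranked tables.
#' @param out_dir Optional output directory for TSV results.
#' @return A list: `scores`, `screened`, `by_count`, `by_ebgm`,
#'   `manifest`, `prior`.
#' @export
run_signals <- function(input_dir,
                        synonyms = c("TEDUGLUTIDE", "REVESTIVE", "GATTEX"),
                        pt_soc_map = NULL, level = c("pt", "soc"),
                        policy = NULL, min_count = 5,
                        unit = c("report", "pair"), substring = FALSE,
                        correction = TRUE, yates = FALSE,
                        bcpnn = bcpnn_priors(), top_k = 30,
                        out_dir = NULL) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  policy <- policy %||% threshold_policy(
    min_count = min_count,
    combination = if (level == "pt") "all_four" else "any_one"
  )

  st <- ingest_stage(input_dir, synonyms, substring = substring)
  if (!nrow(st$target)) {
    abort("no target-drug reports after selection and deduplication",
          class = "faersignal_data_error")
  }
  reactions <- st$reactions
  map <- resolve_map(pt_soc_map, input_dir)
  if (!is.null(map)) reactions <- map_pts(reactions, map)
  if (level == "soc" && is.null(map)) {
    stop_config("SOC-level screening needs a PT->SOC map")
  }

  ct <- build_contingency(st$reports, reactions, st$target$primaryid,
                          level = level, min_count = min_count, unit = unit)
  if (!nrow(ct)) {
    abort("no terms reach the minimum report count",
          class = "faersignal_data_error")
  }
  scores <- disprop_scores(ct, correction = correction, yates = yates,
                           bcpnn = bcpnn)
  screened <- screen_signals(scores, policy)
  by_count <- rank_signals(screened, by = "report_count", top_k = top_k)
  by_ebgm <- rank_signals(screened, by = "ebgm", top_k = top_k) |>
    dplyr::filter(.data$ebgm05 > policy$ebgm05_gt)

  manifest <- dplyr::bind_rows(
    st$manifest,
    tibble::tibble(stage = "terms_tested", n = nrow(ct)),
    tibble::tibble(stage = "terms_flagged", n = sum(screened$signal))
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(screened,
                     file.path(out_dir, sprintf("signals_%s.tsv", level)))
    readr::write_tsv(by_count, file.path(out_dir, "top_by_count.tsv"))
    readr::write_tsv(by_ebgm, file.path(out_dir, "top_by_ebgm.tsv"))
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }

  list(scores = scores, screened = screened, by_count = by_count,
       by_ebgm = by_ebgm, manifest = manifest,
       prior = attr(scores, "prior"))
}

#' Run the descriptive cohort analyses
#'
#' Demographic summary, time-to-onset analysis, serious vs non-serious
#' contrasts and pediatric-vs-adult subgroup disproportionality for the
#' target-drug report set, with the same ingest front-end and stage
#' manifest as [run_signals()].
#'
#' @inheritParams run_signals
#' @param cutoff_age Pediatric cutoff in years.
#' @return A list: `demographics`, `onset` (records), `onset_summary`,
#'   `serious`, `subgroup`, `manifest`.
#' @export
run_descriptives <- function(input_dir,
                             synonyms = c("TEDUGLUTIDE", "REVESTIVE", "GATTEX"),
                             substring = FALSE, top_k = 30,
                             cutoff_age = 18, out_dir = NULL) {
  st <- ingest_stage(input_dir, synonyms, substring = substring)
  if (!nrow(st$target)) {
    abort("no target-drug reports after selection and deduplication",
          class = "faersignal_data_error")
  }
  demo <- demographic_summary(st$target)
  onset <- onset_records(st$target, st$drugs)
  osum <- onset_summary(onset)
  serious <- serious_contrast(st$target, st$reactions, top_k = top_k)
  subgroup <- subgroup_disprop(st$target, st$reactions,
                               cutoff_age = cutoff_age)
  excl <- attr(onset, "exclusions")
  manifest <- dplyr::bind_rows(
    st$manifest,
    tibble::tibble(
      stage = c("onset_computable", "onset_missing", "onset_negative"),
      n = c(nrow(onset), excl[["missing"]], excl[["negative"]])
    )
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(demo, file.path(out_dir, "demographics.tsv"))
    readr::write_tsv(osum$summary, file.path(out_dir, "onset_summary.tsv"))
    readr::write_tsv(osum$bins, file.path(out_dir, "onset_bins.tsv"))
    readr::write_tsv(serious, file.path(out_dir, "serious_contrast.tsv"))
    readr::write_tsv(subgroup, file.path(out_dir, "subgroup_disprop.tsv"))
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }

  list(demographics = demo, onset = onset, onset_summary = osum,
       serious = serious, subgroup = subgroup, manifest = manifest)
}
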