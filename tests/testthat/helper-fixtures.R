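# Shared fixture builders. All data are generated in code at test time.

# Minimal harmonised report tibble with sensible defaults; override any
# column by name.
mk_reports <- function(n = 1, ...) {
  over <- list(...)
  base <- tibble::tibble(
    primaryid = seq_len(n) * 10L + 1L,
    caseid = seq_len(n),
    fda_dt = rep(20230101L, n),
    event_dt = rep(20220601L, n),
    event_precision = rep("day", n),
    event_date = rep(as.Date("2022-06-01"), n),
    sex = rep("female", n),
    age_years = rep(50, n),
    age_group = rep("45-64", n),
    reporter = rep("consumer", n),
    country = rep("US", n),
    outcomes = replicate(n, character(), simplify = FALSE),
    serious = rep(FALSE, n),
    year = rep(2023L, n)
  )
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

mk_drugs <- function(primaryid, role = "PS", drugname = "TEDUGLUTIDE",
                     start_date = as.Date(NA)) {
  tibble::tibble(
    primaryid = primaryid,
    drug_seq = 1L,
    role = rep(role, length.out = length(primaryid)),
    drugname = rep(drugname, length.out = length(primaryid)),
    start_dt = NA_integer_,
    start_date = rep(start_date, length.out = length(primaryid))
  )
}

mk_reactions <- function(primaryid, pt) {
  tibble::tibble(primaryid = primaryid, pt = pt)
}

# A small simulated database with one strongly planted signal, shared by
# several integration tests.
small_planted_sim <- function(seed = 101, n = 4000) {
  sim_config(
    n_reports = n, drug_share = 0.1,
    planted_signals = tibble::tibble(pt = "Decreased appetite",
                                     rate_ratio = 8),
    duplicate_rate = 0.03, seed = seed
  ) |> sim_faers()
}

# Run the in-memory signal pipeline on a simulation and return the
# screened tibble.
screen_sim <- function(sim, min_count = 5,
                       policy = threshold_policy(min_count = min_count)) {
  h <- harmonize_sim(sim)
  reports <- dedup_reports(h$reports)
  target0 <- select_target_reports(reports, h$drugs,
                                   c("TEDUGLUTIDE", "REVESTIVE", "GATTEX"))
  target <- drop_field_duplicates(target0)
  dropped <- setdiff(target0$primaryid, target$primaryid)
  reports <- dplyr::filter(reports, !primaryid %in% dropped)
  ct <- build_contingency(reports, h$reactions, target$primaryid,
                          min_count = min_count)
  screen_signals(disprop_scores(ct), policy)
}
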