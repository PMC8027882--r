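# Shared in-code fixtures. Everything is generated programmatically; no data
# files are read from disk except through tempfiles created here.

# A tiny hand-made paired design: two conditions, each with one 13C sample
# and its 12C heavy control, plus a 12C light sample for pooling tests.
tiny_design <- function() {
  counts <- tibble::tibble(
    feature_id = c("taxA", "taxB", "taxC"),
    s13_p = c(10, 2, 0),
    ctl_p = c(3, 5, 4),
    s13_q = c(4, 4, 4),
    ctl_q = c(4, 4, 4),
    light_p = c(1, 2, 17),
    light_q = c(4, 4, 12)
  )
  meta <- tibble::tibble(
    sample_id = c("s13_p", "ctl_p", "s13_q", "ctl_q", "light_p", "light_q"),
    location = "L1",
    land_use = c("P", "P", "PF", "PF", "P", "PF"),
    substrate = "CH4",
    isotope = c("13C", "12C", "13C", "12C", "12C", "12C"),
    fraction = c("heavy", "heavy", "heavy", "heavy", "light", "light"),
    core = c("c1", "c0", "c1", "c0", "c0", "c0"),
    control_id = c("ctl_p", NA, "ctl_q", NA, NA, NA)
  )
  list(counts = counts, meta = meta)
}

# Small, fast simulation parameter sets reused across tests.
small_preset <- function(seed = 1L) {
  sim_params(n_taxa = 60, n_guild_methanogen = 8, n_guild_methanotroph = 6,
             depth = 4000, n_replicate_cores = 2,
             active_methanogens = c(PF = 3, P = 6, SF = 3),
             active_methanotrophs = c(PF = 4, P = 4, SF = 4),
             guild_fold = list(P = c(methanogen = 5)),
             n_other_consumers = 4, seed = seed)
}

null_params <- function(seed = 1L, n_replicate_cores = 2, depth = 4000) {
  sim_params(n_taxa = 60, n_guild_methanogen = 8, n_guild_methanotroph = 6,
             depth = depth, n_replicate_cores = n_replicate_cores,
             atom_excess = 0, guild_fold = list(),
             core_concentration = Inf,
             n_other_consumers = 4, seed = seed)
}

# Activity calls built directly (bypassing count tables) for summary-level
# tests where only the classification matters.
fake_calls <- function(df) {
  base <- tibble::tibble(feature_id = character(), sample_id = character(),
                         count13 = numeric(), count12 = numeric(),
                         depth13 = numeric(), depth12 = numeric(),
                         p_value = numeric(), active = logical(),
                         norm_value = numeric())
  out <- dplyr::bind_rows(base, df)
  structure(out, alpha = 0.05, alternative = "greater", p_adjust = "none",
            class = c("sip_activity", class(out)))
}

# Valid metadata for hand-built 13C sample ids of the form "<landuse>_c<k>",
# adding one 12C heavy control per land use so the linkage invariants hold.
fake_meta <- function(sample_ids, substrate = "CO2", location = "L1") {
  lus <- sub("_.*", "", sample_ids)
  lab <- tibble::tibble(
    sample_id = sample_ids, location = location, land_use = lus,
    substrate = substrate, isotope = "13C", fraction = "heavy",
    core = sub(".*_", "", sample_ids),
    control_id = paste0("ctl_", lus))
  ctl <- tibble::tibble(
    sample_id = paste0("ctl_", unique(lus)), location = location,
    land_use = unique(lus), substrate = substrate, isotope = "12C",
    fraction = "heavy", core = "c0", control_id = NA_character_)
  dplyr::bind_rows(lab, ctl)
}

# Independent brute-force oracle for the one-sided enrichment p-value:
# enumerate the full hypergeometric support with choose() products and
# normalize within the support (no log-space, no lchoose).
oracle_fisher_greater <- function(c13, d13, c12, d12) {
  m <- c13 + c12
  k <- max(0, m - d12):min(d13, m)
  pmf <- choose(d13, k) * choose(d12, m - k)
  pmf <- pmf / sum(pmf)
  sum(pmf[k >= c13])
}
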