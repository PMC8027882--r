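#' Parameters for a synthetic SIP incubation experiment
#'
#' Defines the generative model used by [simulate_sip_experiment()]. The
#' simulated design mirrors a paired-control DNA-SIP study: for every
#' (location x land use x substrate) combination there are
#' `n_replicate_cores` \eqn{^{13}}C-labeled cores whose heavy gradient
#' fraction is sequenced, plus one \eqn{^{12}}C control core sequenced in both
#' its heavy and light fractions. Density is abstracted to a single
#' heavy/light partition probability per taxon,
#' \deqn{h_i = \mathrm{logistic}(\kappa (g_i + \delta a_i - g_0)),}
#' where \eqn{g_i} is the taxon's GC content, \eqn{a_i} its atom excess
#' (`atom_excess` for taxa active under the sample's condition, 0 otherwise),
#' \eqn{\delta} the density-shift scale and \eqn{g_0}, \eqn{\kappa} the
#' logistic midpoint and steepness. Unlabeled high-GC taxa therefore leak
#' into heavy fractions — exactly the background the \eqn{^{12}}C control
#' design corrects for.
#'
#' Which guild is active depends on the substrate: CH4 feeds methanotrophs;
#' CO2 and sodium acetate feed methanogens plus `n_other_consumers`
#' non-methanogen consumers. Active sets are nested across land uses (a land
#' use with a larger count contains the sets of smaller ones), so enrichment
#' presets can make one land use's active community a strict superset of
#' another's.
#'
#' @param n_taxa Number of taxa.
#' @param n_guild_methanogen,n_guild_methanotroph Guild sizes.
#' @param location_levels,landuse_levels,substrate_levels Factor levels. The
#'   land-use defaults are primary forest (`PF`), pasture (`P`) and secondary
#'   forest (`SF`); substrates are `CH4`, `CO2` and `NaAOc` (sodium acetate).
#' @param n_replicate_cores Labeled cores per (location x land use x
#'   substrate); one additional `12C` control core is always added.
#' @param depth Reads per sequenced sample (multinomial total).
#' @param lognormal_sigma Dispersion of baseline relative abundances.
#' @param guild_share Named numeric vector: total baseline community share of
#'   the methanogen and methanotroph guilds. Methane-cycling guilds are
#'   rare-biosphere members of soil communities (on the order of one percent
#'   of annotations), so the guild blocks are pinned to a small fixed share —
#'   within-guild composition still follows the lognormal — which also keeps
#'   the total isotope-labeled share of the community realistic.
#' @param gc_mean,gc_sd Per-taxon GC-content distribution (proportions).
#' @param kappa,g0 Steepness and midpoint of the GC-to-heavy logistic. The
#'   default midpoint sits well above the mean GC content so that a typical
#'   unlabeled genome partitions only a few percent of its DNA into the heavy
#'   window while high-GC genomes leak in progressively more — the background
#'   a \eqn{^{12}}C control is sequenced to measure — and the labeled density
#'   shift (`delta * atom_excess`) carries active taxa across the midpoint.
#' @param atom_excess Label incorporation in \[0, 1\] for active taxa.
#' @param delta Density shift per unit atom excess, in GC-equivalent units.
#' @param guild_fold Named list: per land use, a named numeric vector of
#'   multiplicative abundance folds per guild, e.g.
#'   `list(P = c(methanogen = 6))`. Unlisted combinations default to 1.
#' @param active_methanogens,active_methanotrophs Named integer vectors (one
#'   entry per land use): how many guild members are active there.
#' @param n_other_consumers Non-guild taxa active under CO2/NaAOc.
#' @param core_concentration Dirichlet concentration for per-core biological
#'   noise around the site profile; `Inf` disables core-to-core variation
#'   (used for exchangeable null scenarios).
#' @param seed Integer seed.
#' @return A validated parameter list of class `sip_sim_params`.
#' @export
sim_params <- function(n_taxa = 300,
                       n_guild_methanogen = 25,
                       n_guild_methanotroph = 20,
                       location_levels = "SiteA",
                       landuse_levels = c("PF", "P", "SF"),
                       substrate_levels = c("CH4", "CO2", "NaAOc"),
                       n_replicate_cores = 3,
                       depth = 50000,
                       lognormal_sigma = 1.5,
                       guild_share = c(methanogen = 0.015, methanotroph = 0.015),
                       gc_mean = 0.5,
                       gc_sd = 0.05,
                       kappa = 30,
                       g0 = 0.62,
                       atom_excess = 0.5,
                       delta = 0.3,
                       guild_fold = list(),
                       active_methanogens = NULL,
                       active_methanotrophs = NULL,
                       n_other_consumers = 10,
                       core_concentration = 5e5,
                       seed = 1L) {
  if (is.null(active_methanogens)) {
    active_methanogens <- stats::setNames(rep(n_guild_methanogen, length(landuse_levels)),
                                          landuse_levels)
  }
  if (is.null(active_methanotrophs)) {
    active_methanotrophs <- stats::setNames(rep(n_guild_methanotroph, length(landuse_levels)),
                                            landuse_levels)
  }
  p <- list(n_taxa = n_taxa,
            n_guild_methanogen = n_guild_methanogen,
            n_guild_methanotroph = n_guild_methanotroph,
            location_levels = location_levels,
            landuse_levels = landuse_levels,
            substrate_levels = substrate_levels,
            n_replicate_cores = n_replicate_cores,
            depth = depth,
            lognormal_sigma = lognormal_sigma,
            guild_share = guild_share,
            gc_mean = gc_mean, gc_sd = gc_sd,
            kappa = kappa, g0 = g0,
            atom_excess = atom_excess, delta = delta,
            guild_fold = guild_fold,
            active_methanogens = active_methanogens,
            active_methanotrophs = active_methanotrophs,
            n_other_consumers = n_other_consumers,
            core_concentration = core_concentration,
            seed = as.integer(seed))
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  pos <- c("n_taxa", "n_guild_methanogen", "n_guild_methanotroph",
           "n_replicate_cores", "depth")
  for (f in pos) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v)) {
      stop(f, " must be a single positive integer", call. = FALSE)
    }
  }
  if (p$n_guild_methanogen + p$n_guild_methanotroph > p$n_taxa) {
    stop("guild sizes exceed n_taxa", call. = FALSE)
  }
  if (p$atom_excess < 0 || p$atom_excess > 1) stop("atom_excess must lie in [0, 1]", call. = FALSE)
  if (p$lognormal_sigma < 0) stop("lognormal_sigma must be non-negative", call. = FALSE)
  if (!setequal(names(p$guild_share), c("methanogen", "methanotroph")) ||
      any(p$guild_share <= 0) || sum(p$guild_share) >= 1) {
    stop("guild_share must name methanogen and methanotroph, be positive, ",
         "and sum to less than 1", call. = FALSE)
  }
  if (p$gc_sd < 0) stop("gc_sd must be non-negative", call. = FALSE)
  if (p$delta < 0) stop("delta must be non-negative", call. = FALSE)
  if (!(is.infinite(p$core_concentration) || p$core_concentration > 0)) {
    stop("core_concentration must be positive or Inf", call. = FALSE)
  }
  bad <- setdiff(names(p$guild_fold), p$landuse_levels)
  if (length(bad)) stop("guild_fold names unknown land use(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (lu in names(p$guild_fold)) {
    g <- p$guild_fold[[lu]]
    bad <- setdiff(names(g), c("methanogen", "methanotroph", "other"))
    if (length(bad)) stop("guild_fold[", lu, "] has unknown guild(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(g <= 0)) stop("guild_fold values must be positive", call. = FALSE)
  }
  for (nm in c("active_methanogens", "active_methanotrophs")) {
    v <- p[[nm]]
    if (!setequal(names(v), p$landuse_levels)) {
      stop(nm, " must be named by the land-use levels", call. = FALSE)
    }
    lim <- if (nm == "active_methanogens") p$n_guild_methanogen else p$n_guild_methanotroph
    if (any(v < 0) || any(v > lim)) stop(nm, " out of range [0, guild size]", call. = FALSE)
  }
  if (p$n_other_consumers < 0 ||
      p$n_other_consumers > p$n_taxa - p$n_guild_methanogen - p$n_guild_methanotroph) {
    stop("n_other_consumers out of range", call. = FALSE)
  }
  structure(p, class = "sip_sim_params")
}

#' Preset: methanogen enrichment after pasture conversion
#'
#' A documented scenario in which pasture (`P`) soils host both a larger
#' active methanogen community (20 of 25 methanogens active, versus the first
#' 8 in primary and secondary forest — a strict superset by nesting) and a
#' six-fold abundance enrichment of the methanogen guild, while the active
#' methanotroph community (12 taxa, under CH4 only) is unchanged across land
#' uses. Used for parameter-recovery and headline-pattern tests: a correct
#' pipeline must report pasture as the land use with the highest active
#' methanogen richness.
#'
#' @param seed Integer seed.
#' @return A `sip_sim_params` object.
#' @export
preset_pasture_enrichment <- function(seed = 1L) {
  sim_params(
    n_taxa = 300,
    n_guild_methanogen = 25,
    n_guild_methanotroph = 20,
    n_replicate_cores = 3,
    depth = 50000,
    atom_excess = 0.5,
    guild_fold = list(P = c(methanogen = 6)),
    active_methanogens = c(PF = 8, P = 20, SF = 8),
    active_methanotrophs = c(PF = 12, P = 12, SF = 12),
    n_other_consumers = 10,
    seed = seed
  )
}

#' Simulate a paired-control SIP experiment with known ground truth
#'
#' Draws a fraction-resolved count table under the generative model described
#' in [sim_params()]. Baseline relative abundances come from a normalized
#' lognormal; land-use-specific guild folds are applied and renormalized;
#' replicate cores redraw their community from a Dirichlet centered on the
#' site profile; heavy and light fraction counts are multinomial with
#' probabilities proportional to \eqn{w_i h_i} and \eqn{w_i (1 - h_i)}
#' respectively, so every sample's column sum equals `depth` exactly.
#'
#' @param params A `sip_sim_params` object from [sim_params()].
#' @return A list of class `sip_simulation` with elements
#'   \describe{
#'     \item{counts}{count table tibble (all samples)}
#'     \item{metadata}{sample metadata with control linkage}
#'     \item{guilds}{guild catalog}
#'     \item{truth}{ground truth (class `sip_truth`): `active` — tibble of
#'       (land_use, substrate, feature_id) designated active; `taxa` — per
#'       taxon GC content, baseline weight and heavy-partition probabilities
#'       with (`heavy_prob_13C`) and without (`heavy_prob_12C`) full label
#'       incorporation; `folds` — realized per-(taxon, land use) abundance
#'       fold relative to baseline}
#'   }
#' @export
simulate_sip_experiment <- function(params) {
  p <- validate_sim_params(params)
  withr::with_seed(p$seed, simulate_sip_impl(p))
}

simulate_sip_impl <- function(p) {
  n <- p$n_taxa
  ids <- sprintf("taxon_%04d", seq_len(n))
  guild <- rep("other", n)
  guild[seq_len(p$n_guild_methanogen)] <- "methanogen"
  guild[p$n_guild_methanogen + seq_len(p$n_guild_methanotroph)] <- "methanotroph"
  mg_ids <- ids[guild == "methanogen"]
  mt_ids <- ids[guild == "methanotroph"]
  other_ids <- ids[guild == "other"]

  pathways <- sample(c("hydrogenotrophic", "acetoclastic", "methylotrophic", "multiple"),
                     p$n_guild_methanogen, replace = TRUE)
  types <- sample(c("I", "II", "III"), p$n_guild_methanotroph, replace = TRUE,
                  prob = c(0.45, 0.45, 0.1))
  guilds <- tibble::tibble(
    feature_id = ids,
    guild = guild,
    methanotroph_type = ifelse(guild == "methanotroph",
                               types[match(ids, mt_ids)], "none"),
    methanogenesis_pathway = ifelse(guild == "methanogen",
                                    pathways[match(ids, mg_ids)], "none")
  )

  gc <- pmin(0.75, pmax(0.25, stats::rnorm(n, p$gc_mean, p$gc_sd)))
  w0 <- stats::rlnorm(n, 0, p$lognormal_sigma)
  # pin each guild block to its fixed community share; lognormal shapes the
  # composition within each block
  for (g in c("methanogen", "methanotroph")) {
    in_g <- guild == g
    w0[in_g] <- w0[in_g] / sum(w0[in_g]) * p$guild_share[[g]]
  }
  in_other <- guild == "other"
  w0[in_other] <- w0[in_other] / sum(w0[in_other]) * (1 - sum(p$guild_share))

  # land-use site profiles: guild folds applied, then renormalized
  profiles <- lapply(p$landuse_levels, function(lu) {
    fold <- rep(1, n)
    lf <- p$guild_fold[[lu]]
    for (g in names(lf)) fold[guild == g] <- lf[[g]]
    w <- w0 * fold
    w / sum(w)
  })
  names(profiles) <- p$landuse_levels

  # designated active sets: top guild members by baseline abundance, so the
  # sets are nested across land uses by construction. Active populations
  # grow over the incubation, so by sequencing time the active guild members
  # are its abundant ones. The CO2/acetate consumers are typical-abundance
  # heterotrophs: the background taxa closest to the median background weight.
  mg_by_abundance <- mg_ids[order(-w0[guild == "methanogen"])]
  mt_by_abundance <- mt_ids[order(-w0[guild == "methanotroph"])]
  w_other <- w0[in_other]
  near_median <- order(abs(log(w_other) - stats::median(log(w_other))))
  consumers <- sort(other_ids[near_median[seq_len(p$n_other_consumers)]])
  active_set <- function(lu, substrate) {
    if (substrate == "CH4") {
      mt_by_abundance[seq_len(p$active_methanotrophs[[lu]])]
    } else {
      c(mg_by_abundance[seq_len(p$active_methanogens[[lu]])], consumers)
    }
  }

  h12 <- stats::plogis(p$kappa * (gc - p$g0))
  h13_full <- stats::plogis(p$kappa * (gc + p$delta * p$atom_excess - p$g0))

  draw_core_weights <- function(w) {
    if (is.infinite(p$core_concentration)) return(w)
    a <- stats::rgamma(n, shape = p$core_concentration * w, rate = 1)
    if (sum(a) == 0) return(w)
    a / sum(a)
  }
  draw_sample <- function(w, h) {
    pr <- w * h
    as.numeric(stats::rmultinom(1, p$depth, pr / sum(pr)))
  }

  cols <- list()
  meta <- list()
  active_rows <- list()
  for (loc in p$location_levels) {
    for (lu in p$landuse_levels) {
      for (su in p$substrate_levels) {
        act <- active_set(lu, su)
        active_rows[[paste(loc, lu, su)]] <-
          tibble::tibble(location = loc, land_use = lu, substrate = su, feature_id = act)
        a <- ifelse(ids %in% act, p$atom_excess, 0)
        h13 <- stats::plogis(p$kappa * (gc + p$delta * a - p$g0))
        base <- paste(loc, lu, su, sep = "_")

        # one 12C control core, heavy + light fractions sequenced
        wc <- draw_core_weights(profiles[[lu]])
        ctl_heavy <- paste0(base, "_12C_heavy_core0")
        ctl_light <- paste0(base, "_12C_light_core0")
        cols[[ctl_heavy]] <- draw_sample(wc, h12)
        cols[[ctl_light]] <- draw_sample(wc, 1 - h12)
        meta[[ctl_heavy]] <- tibble::tibble(
          sample_id = ctl_heavy, location = loc, land_use = lu, substrate = su,
          isotope = "12C", fraction = "heavy", core = "core0", control_id = NA_character_)
        meta[[ctl_light]] <- tibble::tibble(
          sample_id = ctl_light, location = loc, land_use = lu, substrate = su,
          isotope = "12C", fraction = "light", core = "core0", control_id = NA_character_)

        # labeled cores, heavy fraction sequenced
        for (r in seq_len(p$n_replicate_cores)) {
          wr <- draw_core_weights(profiles[[lu]])
          sid <- paste0(base, "_13C_heavy_core", r)
          cols[[sid]] <- draw_sample(wr, h13)
          meta[[sid]] <- tibble::tibble(
            sample_id = sid, location = loc, land_use = lu, substrate = su,
            isotope = "13C", fraction = "heavy", core = paste0("core", r),
            control_id = ctl_heavy)
        }
      }
    }
  }

  counts <- tibble::tibble(feature_id = ids)
  for (s in names(cols)) counts[[s]] <- cols[[s]]

  folds <- dplyr::bind_rows(lapply(p$landuse_levels, function(lu) {
    tibble::tibble(feature_id = ids, land_use = lu,
                   realized_fold = profiles[[lu]] / w0)
  }))

  truth <- structure(list(
    active = dplyr::bind_rows(active_rows),
    taxa = tibble::tibble(feature_id = ids, gc = gc, baseline_weight = w0,
                          heavy_prob_12C = h12, heavy_prob_13C = h13_full),
    folds = folds,
    params = p
  ), class = "sip_truth")

  structure(list(counts = counts,
                 metadata = dplyr::bind_rows(meta),
                 guilds = guilds,
                 truth = truth),
            class = "sip_simulation")
}

#' Write all components of a simulated experiment as TSV files
#'
#' @param sim A `sip_simulation` from [simulate_sip_experiment()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sip_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             guilds = file.path(dir, "guilds.tsv"),
             truth_active = file.path(dir, "truth_active.tsv"),
             truth_taxa = file.path(dir, "truth_taxa.tsv"),
             truth_folds = file.path(dir, "truth_folds.tsv"))
  write_count_table(sim$counts, paths["counts"])
  readr::write_tsv(sim$metadata, paths["metadata"], progress = FALSE)
  readr::write_tsv(sim$guilds, paths["guilds"], progress = FALSE)
  readr::write_tsv(sim$truth$active, paths["truth_active"], progress = FALSE)
  readr::write_tsv(sim$truth$taxa, paths["truth_taxa"], progress = FALSE)
  readr::write_tsv(sim$truth$folds, paths["truth_folds"], progress = FALSE)
  invisible(paths)
}
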