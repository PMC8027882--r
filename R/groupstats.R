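#' One-way ANOVA with eta-squared effect size
#'
#' Classical fixed-effects one-way analysis of variance, reported with the
#' eta-squared effect size (between-group sum of squares over total sum of
#' squares). Degenerate inputs are handled explicitly: zero total variance
#' yields a "no-test" result (`F` and `p` are `NA`, `note = "no-test"`); zero
#' within-group variance with distinct means yields `F = Inf`, `p = 0`,
#' `eta_squared = 1`.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor).
#' @return An object of class `sip_anova`: a list with `F`, `p_value`,
#'   `eta_squared`, `df_between`, `df_within`, `ss_between`, `ss_within`,
#'   `group_means` (tibble), `note`.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  if (length(values) != length(g)) stop("values and groups lengths differ", call. = FALSE)
  ok <- is.finite(values)
  if (!all(ok)) stop("values must be finite", call. = FALSE)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  n <- length(values)
  k <- nlevels(g)
  if (n - k < 1L) stop("no residual degrees of freedom", call. = FALSE)

  means <- tapply(values, g, mean)
  sizes <- tabulate(g)
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- ss_total - ss_between
  group_means <- tibble::tibble(group = levels(g), n = sizes, mean = as.numeric(means))

  if (ss_total <= 0 || isTRUE(all.equal(ss_total, 0))) {
    out <- list(F = NA_real_, p_value = NA_real_, eta_squared = NA_real_,
                df_between = k - 1L, df_within = n - k,
                ss_between = 0, ss_within = 0,
                group_means = group_means, note = "no-test")
    return(structure(out, class = "sip_anova"))
  }

  if (ss_within <= ss_total * 1e-12) {
    out <- list(F = Inf, p_value = 0, eta_squared = 1,
                df_between = k - 1L, df_within = n - k,
                ss_between = ss_between, ss_within = 0,
                group_means = group_means, note = "separated")
    return(structure(out, class = "sip_anova"))
  }

  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  pv <- tab[["Pr(>F)"]][1]
  out <- list(F = Fv, p_value = pv,
              eta_squared = ss_between / ss_total,
              df_between = k - 1L, df_within = n - k,
              ss_between = ss_between, ss_within = ss_within,
              group_means = group_means, note = NA_character_)
  structure(out, class = "sip_anova")
}

#' Tukey-Kramer pairwise comparisons
#'
#' All-pairs comparisons after a one-way ANOVA using the studentized-range
#' statistic with the Tukey-Kramer harmonic adjustment for unbalanced groups:
#' \deqn{q_{ij} = |\bar y_i - \bar y_j| / \sqrt{\mathrm{MSW}/2\,(1/n_i + 1/n_j)},}
#' with p-values from the studentized-range distribution on (k, df) degrees
#' of freedom. When the within-group mean square is zero, unequal means give
#' `p = 0` and equal means a no-test `NA`.
#'
#' @inheritParams anova_oneway
#' @return An object of class `sip_tukey`: a tibble with one row per pair:
#'   `group1`, `group2`, `diff` (mean1 - mean2), `q`, `p_tukey`.
#' @export
tukey_kramer <- function(values, groups) {
  fit <- anova_oneway(values, groups)
  gm <- fit$group_means
  k <- nrow(gm)
  msw <- if (fit$df_within > 0) fit$ss_within / fit$df_within else NA_real_
  pairs <- utils::combn(seq_len(k), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- gm$mean[i1] - gm$mean[i2]
    if (!is.finite(msw) || msw <= 0) {
      if (abs(d) > 0) {
        q <- Inf; p <- 0
      } else {
        q <- NA_real_; p <- NA_real_
      }
    } else {
      se <- sqrt(msw / 2 * (1 / gm$n[i1] + 1 / gm$n[i2]))
      q <- abs(d) / se
      # with two means the studentized range is exactly sqrt(2)|t|, so the
      # closed t-form avoids the quadrature error of ptukey()
      p <- if (k == 2L) {
        2 * stats::pt(q / sqrt(2), df = fit$df_within, lower.tail = FALSE)
      } else {
        stats::ptukey(q, nmeans = k, df = fit$df_within, lower.tail = FALSE)
      }
    }
    tibble::tibble(group1 = gm$group[i1], group2 = gm$group[i2],
                   diff = d, q = q, p_tukey = p)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, anova = fit, class = c("sip_tukey", class(out)))
}

# Which group is "significantly higher": the unique top mean must beat every
# other group in its Tukey pairwise test. Ties or any non-significant pair
# give no association.
association_from <- function(group_means, pairwise, alpha) {
  gm <- group_means[order(-group_means$mean), ]
  top <- gm$group[1]
  if (nrow(gm) > 1 && gm$mean[1] <= gm$mean[2]) return(NA_character_)
  for (other in gm$group[-1]) {
    row <- pairwise[(pairwise$group1 == top & pairwise$group2 == other) |
                      (pairwise$group2 == top & pairwise$group1 == other), ]
    if (!nrow(row) || !is.finite(row$p_tukey[1]) || row$p_tukey[1] >= alpha) {
      return(NA_character_)
    }
  }
  top
}

#' Compare control-normalized feature abundances across land uses
#'
#' Within each (location, substrate) stratum, every feature's
#' control-normalized abundances are compared across land uses by one-way
#' ANOVA with Tukey-Kramer post hoc tests. A feature is reported when its
#' ANOVA p-value is below `report_p`; its *land-use association* is the land
#' use whose mean is highest and significantly higher (each Tukey pairwise
#' `p < alpha`) than every other land use. Each associated feature is then
#' re-checked against the activity calls: it must have been called active in
#' at least one sample of the associated land use (`active_confirmed`);
#' unconfirmed features are dropped unless `keep_unconfirmed = TRUE`.
#'
#' @param normalized A `sip_normalized` table from [control_normalize()].
#' @param calls Activity calls from [call_active()].
#' @param meta Sample metadata.
#' @param guilds Optional guild catalog; adds a `guild` column.
#' @param alpha Significance threshold for the ANOVA and Tukey tests.
#' @param report_p Reporting threshold on the ANOVA p-value (defaults to
#'   `alpha`; may be set higher to list borderline features).
#' @param keep_unconfirmed Keep rows that fail the activity re-check.
#' @return A tibble (class `sip_feature_comparison`): `location`, `substrate`,
#'   `feature_id`, `guild`, `p_anova`, `eta_squared`, `association`,
#'   `active_confirmed`, and one `mean_<land use>` column per land use.
#' @export
compare_active_features <- function(normalized, calls, meta, guilds = NULL,
                                    alpha = 0.05, report_p = alpha,
                                    keep_unconfirmed = FALSE) {
  if (!inherits(normalized, "sip_normalized")) {
    stop("normalized must come from control_normalize()", call. = FALSE)
  }
  meta <- validate_sample_metadata(meta)
  ids <- sample_ids(normalized)
  m <- meta[match(ids, meta$sample_id), ]
  if (anyNA(m$sample_id)) stop("normalized sample(s) missing from metadata", call. = FALSE)

  strata <- split(m$sample_id, paste(m$location, m$substrate, sep = "\r"))
  guild_map <- if (!is.null(guilds)) {
    validate_guild_catalog(guilds)[, c("feature_id", "guild")]
  } else {
    tibble::tibble(feature_id = character(), guild = character())
  }

  active_by <- calls |>
    dplyr::filter(.data$active) |>
    dplyr::left_join(meta[, c("sample_id", "land_use")], by = "sample_id") |>
    dplyr::distinct(.data$feature_id, .data$land_use)

  out <- list()
  for (key in sort(names(strata))) {
    ss <- sort(strata[[key]])
    lus <- m$land_use[match(ss, m$sample_id)]
    if (length(unique(lus)) < 2L) {
      stop("stratum with a single land use: ",
           gsub("\r", " / ", key), call. = FALSE)
    }
    loc <- m$location[match(ss[1], m$sample_id)]
    su <- m$substrate[match(ss[1], m$sample_id)]
    vals <- as.matrix(normalized[, ss, drop = FALSE])
    for (i in seq_len(nrow(normalized))) {
      y <- vals[i, ]
      if (all(y == y[1])) next                     # zero variance: no test
      fit <- anova_oneway(y, lus)
      if (!is.finite(fit$p_value) || fit$p_value >= report_p) next
      tk <- tukey_kramer(y, lus)
      # association requires ANOVA significance at alpha (report_p only
      # widens which rows are listed, not which get an association)
      assoc <- if (is.finite(fit$p_value) && fit$p_value < alpha) {
        association_from(fit$group_means, tk, alpha)
      } else NA_character_
      fid <- normalized$feature_id[i]
      confirmed <- !is.na(assoc) &&
        nrow(dplyr::filter(active_by, .data$feature_id == fid,
                           .data$land_use == assoc)) > 0
      if (!keep_unconfirmed && !confirmed) next
      row <- tibble::tibble(location = loc, substrate = su, feature_id = fid,
                            p_anova = fit$p_value, eta_squared = fit$eta_squared,
                            association = assoc, active_confirmed = confirmed)
      for (j in seq_len(nrow(fit$group_means))) {
        row[[paste0("mean_", fit$group_means$group[j])]] <- fit$group_means$mean[j]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) {
    res <- dplyr::left_join(res, guild_map, by = "feature_id")
    res$guild[is.na(res$guild)] <- "other"
    res <- dplyr::relocate(res, "guild", .after = "feature_id")
    res <- dplyr::arrange(res, .data$location, .data$substrate, .data$p_anova)
  }
  structure(res, alpha = alpha, report_p = report_p,
            class = c("sip_feature_comparison", class(res)))
}

#' Compare active guild richness across land uses
#'
#' Within each (location, substrate) stratum, the per-sample number of
#' distinct active features of a guild is compared across land uses by
#' one-way ANOVA with Tukey-Kramer post hoc tests.
#'
#' @param calls Activity calls from [call_active()].
#' @param meta Sample metadata.
#' @param guilds Guild catalog.
#' @param guild Guild to count (`"methanogen"`, `"methanotroph"`, `"other"`).
#' @param alpha Significance threshold used for the association rule.
#' @return A tibble (class `sip_group_comparison`) with one row per stratum:
#'   `location`, `substrate`, `guild`, `F`, `p_anova`, `eta_squared`,
#'   `association`, plus list-columns `means` (per-group sizes and means)
#'   and `pairwise` (Tukey table).
#' @export
richness_comparison <- function(calls, meta, guilds, guild = "methanogen",
                                alpha = 0.05) {
  meta <- validate_sample_metadata(meta)
  summ <- active_summary(calls, guilds)
  summ <- summ[summ$guild == guild, ]
  m <- meta[match(summ$sample_id, meta$sample_id), ]
  if (anyNA(m$sample_id)) stop("call sample(s) missing from metadata", call. = FALSE)
  summ$location <- m$location
  summ$substrate <- m$substrate
  summ$land_use <- m$land_use

  out <- summ |>
    dplyr::group_by(.data$location, .data$substrate) |>
    dplyr::group_map(function(d, k) {
      if (length(unique(d$land_use)) < 2L) {
        stop("stratum with a single land use: ", k$location, " / ", k$substrate,
             call. = FALSE)
      }
      fit <- anova_oneway(d$richness, d$land_use)
      if (identical(fit$note, "no-test")) {
        return(tibble::tibble(location = k$location, substrate = k$substrate,
                              guild = guild, F = NA_real_, p_anova = NA_real_,
                              eta_squared = NA_real_, association = NA_character_,
                              means = list(fit$group_means), pairwise = list(NULL)))
      }
      tk <- tukey_kramer(d$richness, d$land_use)
      assoc <- if (is.finite(fit$p_value) && fit$p_value < alpha ||
                   identical(fit$note, "separated")) {
        association_from(fit$group_means, tk, alpha)
      } else NA_character_
      tibble::tibble(location = k$location, substrate = k$substrate,
                     guild = guild, F = fit$F, p_anova = fit$p_value,
                     eta_squared = fit$eta_squared, association = assoc,
                     means = list(fit$group_means),
                     pairwise = list(tibble::as_tibble(tk)))
    }) |>
    dplyr::bind_rows()
  structure(out, alpha = alpha,
            class = c("sip_group_comparison", class(out)))
}

#' Pearson correlation with t-distributed p-value
#'
#' Thin tidy wrapper around [stats::cor.test()] for environmental covariate
#' analyses (e.g., relating active guild abundance to soil chemistry).
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-constant).
#' @return A one-row tibble: `r`, `p_value`, `df`, `n`, `conf_low`, `conf_high`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate),
                 p_value = ct$p.value,
                 df = unname(ct$parameter),
                 n = length(x),
                 conf_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
                 conf_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_)
}
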