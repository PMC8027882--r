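#' One-sided Fisher exact test for enrichment in a 13C sample
#'
#' Tests whether a feature is over-represented in a \eqn{^{13}}C sample
#' relative to its \eqn{^{12}}C control, conditioning on both sequencing
#' depths. The 2x2 table is
#' `[count13, depth13 - count13; count12, depth12 - count12]` and the p-value
#' is the upper hypergeometric tail P(X >= count13), accumulated in log space
#' for numerical stability. A two-sided variant (summing all tables whose
#' probability does not exceed that of the observed table, the
#' minimum-likelihood rule) is available via `alternative = "two.sided"`.
#'
#' All four arguments are vectorized and recycled to a common length.
#'
#' @param count13,count12 Feature counts in the labeled sample and control.
#' @param depth13,depth12 Total annotation counts (column sums) of each.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return Vector of p-values in (0, 1].
#' @export
fisher_exact_enrichment <- function(count13, depth13, count12, depth12,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(count13), length(depth13), length(count12), length(depth12))
  c13 <- rep_len(as.numeric(count13), n)
  d13 <- rep_len(as.numeric(depth13), n)
  c12 <- rep_len(as.numeric(count12), n)
  d12 <- rep_len(as.numeric(depth12), n)
  if (any(d13 <= 0 | d12 <= 0)) stop("depths must be positive", call. = FALSE)
  if (any(c13 < 0 | c12 < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(c13 > d13 | c12 > d12)) stop("count exceeds depth", call. = FALSE)
  vapply(seq_len(n), function(i) {
    fisher_one(c13[i], d13[i], c12[i], d12[i], alternative)
  }, numeric(1))
}

fisher_one <- function(c13, d13, c12, d12, alternative) {
  m <- c13 + c12                      # fixed feature margin
  lo <- max(0, m - d12)
  hi <- min(d13, m)
  if (alternative == "greater") {
    if (c13 <= lo) return(1)          # tail spans the whole support
    k <- c13:hi
    lp <- lchoose(d13, k) + lchoose(d12, m - k) - lchoose(d13 + d12, m)
    return(min(1, exp(logsumexp(lp))))
  }
  k <- lo:hi
  lp <- lchoose(d13, k) + lchoose(d12, m - k) - lchoose(d13 + d12, m)
  obs <- lp[k == c13]
  min(1, exp(logsumexp(lp[lp <= obs + 1e-7])))
}

#' Classify features as active by paired 13C-versus-control exact tests
#'
#' A feature is called *active* in a \eqn{^{13}}C sample when it is
#' significantly more abundant there than in the matched \eqn{^{12}}C control
#' (one-sided Fisher exact test, `p < alpha`, and a strictly greater observed
#' proportion). Heavy-fraction enrichment of unlabeled high-GC DNA is the
#' confounder the paired control subtracts. Features with zero counts in both
#' members of a pair carry no information and are skipped; they are reported
#' in the `untested` attribute and excluded from richness denominators.
#'
#' Following common practice for this design, raw p-values are compared
#' against `alpha` with no multiple-testing correction by default;
#' `p_adjust = "BH"` applies a Benjamini-Hochberg correction per sample and
#' is a deliberate deviation from that convention.
#'
#' @param table Count table with all 13C samples and controls rarefied to a
#'   common depth.
#' @param pairing Output of [link_controls()].
#' @param alpha Significance threshold, compared strictly (`p < alpha`).
#' @param alternative Sidedness passed to [fisher_exact_enrichment()].
#' @param p_adjust `"none"` (default) or a method name for [stats::p.adjust()].
#' @return A tibble (class `sip_activity`) with one row per tested
#'   (feature, 13C sample): `feature_id`, `sample_id`, `count13`, `count12`,
#'   `depth13`, `depth12`, `p_value`, `active`, and the control-normalized
#'   value `norm_value = max(0, count13 - count12)`.
#' @export
call_active <- function(table, pairing, alpha = 0.05,
                        alternative = c("greater", "two.sided"),
                        p_adjust = "none") {
  validate_count_table(table)
  alternative <- match.arg(alternative)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  need <- union(pairing$sample_id, pairing$control_id)
  miss <- setdiff(need, sample_ids(table))
  if (length(miss)) stop("sample(s) absent from table: ", paste(miss, collapse = ", "), call. = FALSE)
  totals <- vapply(need, function(s) sum(table[[s]]), numeric(1))
  if (length(unique(totals)) != 1L) {
    stop("samples are not at a common depth; rarefy() first", call. = FALSE)
  }

  res <- vector("list", nrow(pairing))
  untested <- vector("list", nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    s <- pairing$sample_id[i]
    ctl <- pairing$control_id[i]
    c13 <- table[[s]]
    c12 <- table[[ctl]]
    d13 <- sum(c13)
    d12 <- sum(c12)
    tested <- c13 > 0 | c12 > 0
    untested[[i]] <- tibble::tibble(feature_id = table$feature_id[!tested],
                                    sample_id = s)
    p <- fisher_exact_enrichment(c13[tested], d13, c12[tested], d12,
                                 alternative = alternative)
    if (p_adjust != "none") p <- stats::p.adjust(p, method = p_adjust)
    res[[i]] <- tibble::tibble(
      feature_id = table$feature_id[tested],
      sample_id = s,
      count13 = c13[tested],
      count12 = c12[tested],
      depth13 = d13,
      depth12 = d12,
      p_value = p,
      active = p < alpha & c13[tested] / d13 > c12[tested] / d12,
      norm_value = pmax(0, c13[tested] - c12[tested])
    )
  }
  out <- dplyr::bind_rows(res)
  structure(out,
            alpha = alpha,
            alternative = alternative,
            p_adjust = p_adjust,
            pairing = pairing,
            untested = dplyr::bind_rows(untested),
            class = c("sip_activity", class(out)))
}

#' Summarize active features per sample and guild
#'
#' For each sample and guild, *richness* is the number of distinct features
#' called active and *abundance* is the sum of their control-normalized
#' values. Features absent from the guild catalog are counted under guild
#' `"other"` with a warning.
#'
#' @param calls Output of [call_active()].
#' @param guilds Guild catalog tibble, or `NULL` to treat every feature as
#'   guild `"other"`.
#' @return A tibble (class `sip_active_summary`) with columns `sample_id`,
#'   `guild`, `richness`, `abundance`, complete over all samples and guilds
#'   present (zero rows filled in).
#' @export
active_summary <- function(calls, guilds = NULL) {
  if (!inherits(calls, "sip_activity")) stop("calls must come from call_active()", call. = FALSE)
  if (is.null(guilds)) {
    map <- tibble::tibble(feature_id = unique(calls$feature_id), guild = "other")
  } else {
    guilds <- validate_guild_catalog(guilds)
    map <- guilds[, c("feature_id", "guild")]
    missing <- setdiff(unique(calls$feature_id), map$feature_id)
    if (length(missing)) {
      warning(length(missing), " feature(s) absent from guild catalog; counted as 'other'",
              call. = FALSE)
      map <- dplyr::bind_rows(map, tibble::tibble(feature_id = missing, guild = "other"))
    }
  }
  all_guilds <- sort(unique(map$guild))
  out <- calls |>
    dplyr::left_join(map, by = "feature_id") |>
    dplyr::filter(.data$active) |>
    dplyr::group_by(.data$sample_id, .data$guild) |>
    dplyr::summarise(richness = dplyr::n_distinct(.data$feature_id),
                     abundance = sum(.data$norm_value), .groups = "drop") |>
    tidyr::complete(sample_id = unique(calls$sample_id),
                    guild = all_guilds,
                    fill = list(richness = 0L, abundance = 0)) |>
    dplyr::arrange(.data$sample_id, .data$guild)
  structure(out, class = c("sip_active_summary", class(out)))
}
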