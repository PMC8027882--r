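#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA result
#'
#' @param x A `sip_permanova` object.
#' @param ... Unused.
#' @return Tibble with one row per term plus Residual and Total rows.
#' @export
tidy.sip_permanova <- function(x, ...) x$table

#' @rdname tidy.sip_permanova
#' @export
glance.sip_permanova <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, exhaustive = x$exhaustive, seed = x$seed)
}

#' Tidy a PERMDISP result
#'
#' @param x A `sip_permdisp` object.
#' @param ... Unused.
#' @return Tibble of per-sample distances to the group centroid.
#' @export
tidy.sip_permdisp <- function(x, ...) x$distances

#' @rdname tidy.sip_permdisp
#' @export
glance.sip_permdisp <- function(x, ...) {
  tibble::tibble(F = x$F, p_perm = x$p_perm, n_perm = x$n_perm, seed = x$seed)
}

#' Tidy a one-way ANOVA result
#'
#' @param x A `sip_anova` object.
#' @param ... Unused.
#' @return Tibble of per-group sizes and means.
#' @export
tidy.sip_anova <- function(x, ...) x$group_means

#' @rdname tidy.sip_anova
#' @export
glance.sip_anova <- function(x, ...) {
  tibble::tibble(F = x$F, p_value = x$p_value, eta_squared = x$eta_squared,
                 df_between = x$df_between, df_within = x$df_within,
                 note = x$note)
}

#' @export
print.sip_anova <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      format(x$F, digits = 4), ", p = ", format(x$p_value, digits = 4),
      ", eta^2 = ", format(x$eta_squared, digits = 3),
      if (!is.na(x$note)) paste0(" [", x$note, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
print.sip_permanova <- function(x, ...) {
  cat("PERMANOVA (", if (x$exhaustive) "exhaustive, " else "",
      x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @export
print.sip_permdisp <- function(x, ...) {
  cat("PERMDISP: F = ", format(x$F, digits = 4),
      ", p = ", format(x$p_perm, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
print.sip_sim_params <- function(x, ...) {
  cat("SIP simulation parameters: ", x$n_taxa, " taxa (",
      x$n_guild_methanogen, " methanogens, ", x$n_guild_methanotroph,
      " methanotrophs), depth ", x$depth, ", atom excess ", x$atom_excess,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
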