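#' Read a feature-by-sample count table from TSV
#'
#' Count tables hold annotation counts (taxa or functional categories) with
#' features as rows and samples as columns. The first column carries the
#' feature identifiers (opaque, case-sensitive strings); the header row holds
#' sample identifiers. Cells must be non-negative integers.
#'
#' Feature order is preserved exactly as it appears in the file; no silent
#' reordering takes place anywhere in the package.
#'
#' @param path Path to a tab-delimited UTF-8 file.
#' @return A tibble with `feature_id` first, one numeric column per sample.
#' @seealso [write_count_table()], [read_count_table_biom()]
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       name_repair = "minimal", progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    stop("malformed count table '", path, "': ",
         prob$expected[1], " vs ", prob$actual[1], " at row ", prob$row[1],
         call. = FALSE)
  }
  names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  validate_count_table(x, arg = path)
  tibble::as_tibble(x, .name_repair = "minimal")
}

#' Write a count table to TSV
#'
#' @param table Count table tibble (see [read_count_table()]).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(table)
}

#' Read a count table from a BIOM v1 (JSON) file
#'
#' Produces the same tibble layout as [read_count_table()], so TSV and BIOM
#' inputs with identical content yield identical tables.
#'
#' @param path Path to a BIOM v1 JSON file.
#' @return A count table tibble.
#' @export
read_count_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the 'biomformat' package is required for BIOM input", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  x <- count_tbl(m)
  validate_count_table(x, arg = path)
  x
}

#' Read and validate sample metadata
#'
#' Metadata links each sequenced sample to its experimental factors and, for
#' \eqn{^{13}}C samples, to the matched \eqn{^{12}}C control. Required columns:
#' `sample_id`, `location`, `land_use`, `substrate`, `isotope` (`12C`/`13C`),
#' `fraction` (`heavy`/`light`), `core`, `control_id` (empty for controls).
#'
#' @param path Path to a tab-delimited file.
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(m)
}

#' @rdname read_sample_metadata
#' @param meta A metadata data frame to validate in place.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "location", "land_use", "substrate",
            "isotope", "fraction", "core", "control_id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  meta <- tibble::as_tibble(meta)
  meta$control_id[!is.na(meta$control_id) & meta$control_id == ""] <- NA_character_
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  bad_iso <- setdiff(unique(meta$isotope), c("12C", "13C"))
  if (length(bad_iso)) stop("unknown isotope label(s): ", paste(bad_iso, collapse = ", "), call. = FALSE)
  bad_fr <- setdiff(unique(meta$fraction), c("heavy", "light", "total"))
  if (length(bad_fr)) stop("unknown fraction label(s): ", paste(bad_fr, collapse = ", "), call. = FALSE)

  ctrl <- meta$control_id[meta$isotope == "12C"]
  if (any(!is.na(ctrl))) stop("12C controls must have empty control_id", call. = FALSE)

  lab <- meta[meta$isotope == "13C", ]
  if (nrow(lab)) {
    if (anyNA(lab$control_id)) {
      stop("13C sample(s) without control_id: ",
           paste(lab$sample_id[is.na(lab$control_id)], collapse = ", "), call. = FALSE)
    }
    idx <- match(lab$control_id, meta$sample_id)
    if (anyNA(idx)) {
      stop("control_id not found in metadata for sample(s): ",
           paste(lab$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    ctl <- meta[idx, ]
    if (any(ctl$isotope != "12C")) {
      stop("control_id of sample(s) ",
           paste(lab$sample_id[ctl$isotope != "12C"], collapse = ", "),
           " does not point to a 12C sample", call. = FALSE)
    }
    mismatch <- ctl$location != lab$location | ctl$land_use != lab$land_use |
      ctl$substrate != lab$substrate
    if (any(mismatch)) {
      stop("13C sample(s) paired to a control from a different ",
           "location/land_use/substrate: ",
           paste(lab$sample_id[mismatch], collapse = ", "), call. = FALSE)
    }
  }
  meta
}

#' Read a guild catalog
#'
#' The catalog maps features to methane-cycling guilds. Columns: `feature_id`,
#' `guild` (`methanogen`, `methanotroph`, `other`), `methanotroph_type`
#' (`I`, `II`, `III` for methanotrophs, `none` otherwise), and
#' `methanogenesis_pathway` (`hydrogenotrophic`, `acetoclastic`,
#' `methylotrophic`, `multiple` for methanogens, `none` otherwise).
#'
#' @param path Path to a tab-delimited file.
#' @return A validated tibble.
#' @export
read_guild_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  validate_guild_catalog(g)
}

#' @rdname read_guild_catalog
#' @param guilds A guild catalog data frame to validate in place.
#' @export
validate_guild_catalog <- function(guilds) {
  need <- c("feature_id", "guild", "methanotroph_type", "methanogenesis_pathway")
  miss <- setdiff(need, names(guilds))
  if (length(miss)) stop("guild catalog missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  guilds <- tibble::as_tibble(guilds)
  if (anyDuplicated(guilds$feature_id)) stop("duplicate feature_id in guild catalog", call. = FALSE)
  bad <- setdiff(unique(guilds$guild), c("methanogen", "methanotroph", "other"))
  if (length(bad)) stop("unknown guild label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad_t <- setdiff(unique(guilds$methanotroph_type), c("I", "II", "III", "none"))
  if (length(bad_t)) stop("unknown methanotroph_type: ", paste(bad_t, collapse = ", "), call. = FALSE)
  bad_p <- setdiff(unique(guilds$methanogenesis_pathway),
                   c("hydrogenotrophic", "acetoclastic", "methylotrophic", "multiple", "none"))
  if (length(bad_p)) stop("unknown methanogenesis_pathway: ", paste(bad_p, collapse = ", "), call. = FALSE)
  off <- (guilds$guild == "methanotroph") != (guilds$methanotroph_type != "none")
  if (any(off)) {
    stop("methanotroph_type must be set iff guild is methanotroph: ",
         paste(guilds$feature_id[off], collapse = ", "), call. = FALSE)
  }
  off <- (guilds$guild == "methanogen") != (guilds$methanogenesis_pathway != "none")
  if (any(off)) {
    stop("methanogenesis_pathway must be set iff guild is methanogen: ",
         paste(guilds$feature_id[off], collapse = ", "), call. = FALSE)
  }
  guilds
}

#' @rdname read_guild_catalog
#' @param guilds Guild catalog tibble.
#' @export
write_guild_catalog <- function(guilds, path) {
  readr::write_tsv(validate_guild_catalog(guilds), path, progress = FALSE)
  invisible(guilds)
}

#' @rdname read_sample_metadata
#' @param meta Metadata tibble.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(validate_sample_metadata(meta), path, progress = FALSE)
  invisible(meta)
}

#' Pair each 13C sample in a count table with its 12C control
#'
#' Pairing is driven entirely by the `control_id` metadata key — never by
#' sample naming conventions — and therefore does not depend on the order of
#' the table's columns. Each \eqn{^{13}}C heavy-fraction sample is matched to
#' the \eqn{^{12}}C heavy-fraction control of the same location, land use and
#' substrate.
#'
#' @param table Count table containing both the 13C samples and their controls.
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @return A tibble with one row per 13C sample present in `table`:
#'   `sample_id`, `control_id`, `location`, `land_use`, `substrate`, `core`.
#' @export
link_controls <- function(table, meta) {
  validate_count_table(table)
  meta <- validate_sample_metadata(meta)
  ids <- sample_ids(table)
  known <- meta[match(ids, meta$sample_id), ]
  if (anyNA(known$sample_id)) {
    stop("sample(s) in count table missing from metadata: ",
         paste(ids[is.na(known$sample_id)], collapse = ", "), call. = FALSE)
  }
  lab <- known[known$isotope == "13C", ]
  if (!nrow(lab)) stop("no 13C samples found in count table", call. = FALSE)
  missing_ctl <- setdiff(lab$control_id, ids)
  if (length(missing_ctl)) {
    bad <- lab$sample_id[lab$control_id %in% missing_ctl]
    stop("control sample(s) absent from count table for 13C sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # canonical order so that the pairing is invariant to column permutations
  out <- lab[order(lab$sample_id),
             c("sample_id", "control_id", "location", "land_use", "substrate", "core")]
  tibble::as_tibble(out)
}
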