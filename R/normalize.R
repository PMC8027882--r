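#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, so that
#' every column sums exactly to `depth`. Each sample draws from its own RNG
#' stream derived deterministically from `(seed, sample_id)`; reordering the
#' table's columns therefore cannot change any sample's rarefied counts.
#'
#' Amplicon (16S) analyses conventionally use `depth = 20000`; for metagenome
#' annotation tables a common choice is the minimum column sum of the compared
#' set (see [run_pipeline()], which applies that default).
#'
#' @param table Count table tibble.
#' @param depth Target number of annotations per sample (positive integer).
#' @param seed Master integer seed.
#' @param if_shallow What to do with samples whose total is below `depth`:
#'   `"error"` (default) fails naming the sample, `"drop"` removes it.
#' @return A rarefied count table; attribute `depth` records the depth used.
#' @export
rarefy <- function(table, depth, seed, if_shallow = c("error", "drop")) {
  validate_count_table(table)
  if_shallow <- match.arg(if_shallow)
  if (length(depth) != 1L || !is.finite(depth) || depth <= 0 || depth != round(depth)) {
    stop("depth must be a single positive integer", call. = FALSE)
  }
  ids <- sample_ids(table)
  totals <- vapply(ids, function(s) sum(table[[s]]), numeric(1))
  shallow <- ids[totals < depth]
  if (length(shallow)) {
    if (if_shallow == "error") {
      stop("sample(s) with fewer than ", depth, " annotations: ",
           paste(shallow, collapse = ", "),
           " (use if_shallow = \"drop\" to discard them)", call. = FALSE)
    }
    ids <- setdiff(ids, shallow)
    if (!length(ids)) stop("all samples are below the rarefaction depth", call. = FALSE)
  }
  out <- table[, c("feature_id", ids)]
  for (s in ids) {
    out[[s]] <- rarefy_one(table[[s]], depth, derive_seed(seed, s))
  }
  attr(out, "depth") <- as.integer(depth)
  attr(out, "seed") <- as.integer(seed)
  out
}

# Draw `depth` reads without replacement from one sample's counts.
rarefy_one <- function(counts, depth, subseed) {
  n <- sum(counts)
  if (n == depth) return(counts)
  cum <- cumsum(counts)
  idx <- withr::with_seed(subseed, sample.int(n, depth))
  tabulate(findInterval(idx, cum, left.open = TRUE) + 1L, nbins = length(counts))
}

#' Pool heavy and light gradient fractions into "total" samples
#'
#' Adds, per feature, the counts of the heavy and light fraction samples that
#' share the same location, land use, substrate, isotope and core —
#' reconstructing the total community a core contributed to the gradient.
#' Pooled sample identifiers are the two member identifiers joined with `"+"`
#' in sorted order, so the result does not depend on which fraction comes
#' first.
#'
#' @param table Count table containing heavy and light fraction samples.
#' @param meta Sample metadata.
#' @return A count table of pooled samples; attribute `metadata` holds the
#'   corresponding pooled metadata rows (fraction set to `"total"`).
#' @export
pool_fractions <- function(table, meta) {
  validate_count_table(table)
  meta <- validate_sample_metadata(meta)
  ids <- sample_ids(table)
  m <- meta[match(ids, meta$sample_id), ]
  if (anyNA(m$sample_id)) {
    stop("sample(s) missing from metadata: ",
         paste(ids[is.na(m$sample_id)], collapse = ", "), call. = FALSE)
  }
  if (!all(m$fraction %in% c("heavy", "light"))) {
    stop("pool_fractions expects heavy/light fraction samples only", call. = FALSE)
  }
  key <- paste(m$location, m$land_use, m$substrate, m$isotope, m$core, sep = "\r")
  groups <- split(m$sample_id, key)
  bad <- groups[vapply(groups, length, integer(1)) != 2L]
  if (length(bad)) {
    stop("missing partner fraction for sample(s): ",
         paste(unlist(bad), collapse = ", "), call. = FALSE)
  }
  # deterministic output order: by sorted pooled id
  pooled_ids <- vapply(groups, function(g) paste(sort(g), collapse = "+"), character(1))
  ord <- order(pooled_ids)
  groups <- groups[ord]
  pooled_ids <- pooled_ids[ord]

  out <- tibble::tibble(feature_id = table$feature_id)
  meta_rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    out[[pooled_ids[i]]] <- table[[g[1]]] + table[[g[2]]]
    row <- m[m$sample_id == g[1], ]
    row$sample_id <- pooled_ids[i]
    row$fraction <- "total"
    row$control_id <- NA_character_
    meta_rows[[i]] <- row
  }
  attr(out, "metadata") <- dplyr::bind_rows(meta_rows)
  out
}

#' Normalize 13C samples against their 12C controls
#'
#' For every feature and every \eqn{^{13}}C sample, the control-normalized
#' abundance is `max(0, count13 - count12)`: the count in the labeled sample
#' minus the count in its matched \eqn{^{12}}C heavy-fraction control, with
#' features less abundant in the labeled sample floored at zero. The
#' subtraction is only meaningful when both members of a pair carry the same
#' sequencing effort, so both must first be rarefied to one common depth.
#'
#' @param table Rarefied count table containing the 13C samples and controls.
#' @param pairing Output of [link_controls()].
#' @return A tibble (class `sip_normalized`) with `feature_id` and one column
#'   per 13C sample; attributes `depth` and `pairing` record provenance.
#' @export
control_normalize <- function(table, pairing) {
  validate_count_table(table)
  ids <- sample_ids(table)
  need <- union(pairing$sample_id, pairing$control_id)
  miss <- setdiff(need, ids)
  if (length(miss)) {
    stop("sample(s) in pairing absent from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  totals <- vapply(need, function(s) sum(table[[s]]), numeric(1))
  if (length(unique(totals)) != 1L) {
    stop("samples are not at a common depth (column sums differ); ",
         "rarefy() all samples and controls to one depth first", call. = FALSE)
  }
  out <- tibble::tibble(feature_id = table$feature_id)
  for (i in seq_len(nrow(pairing))) {
    s <- pairing$sample_id[i]
    ctl <- pairing$control_id[i]
    out[[s]] <- pmax(0, table[[s]] - table[[ctl]])
  }
  structure(out,
            depth = unname(totals[1]),
            pairing = pairing,
            class = c("sip_normalized", class(out)))
}

#' Write a normalized table as TSV with a provenance header
#'
#' @param x A `sip_normalized` table from [control_normalize()].
#' @param path Output path.
#' @param seed Optional seed to record in the header comment.
#' @export
write_normalized_table <- function(x, path, seed = NULL) {
  hdr <- paste0("# sipcall normalized table; depth=", attr(x, "depth") %||% "NA",
                if (!is.null(seed)) paste0("; seed=", seed))
  writeLines(hdr, path)
  readr::write_tsv(tibble::as_tibble(x), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(x)
}
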