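# Internal helpers shared across modules.

# Deterministic 31-ary rolling hash of a string, in [0, 2^31 - 2].
# Used to derive per-sample RNG streams so that results cannot depend on
# sample order (all arithmetic stays below 2^53, exact in doubles).
hash_string <- function(x) {
  stopifnot(length(x) == 1L, is.character(x))
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% m
  h
}

# Sub-seed for a named stream under one master seed.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + hash_string(as.character(key))) %% 2147483647)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# A count table is a tibble whose first column ("feature_id") holds unique
# feature labels and whose remaining columns are integer counts per sample.
validate_count_table <- function(x, arg = "table") {
  if (!is.data.frame(x)) stop(arg, " must be a data frame", call. = FALSE)
  if (ncol(x) < 2L) stop(arg, " needs a feature_id column plus at least one sample", call. = FALSE)
  if (names(x)[1] != "feature_id") stop(arg, " must have 'feature_id' as its first column", call. = FALSE)
  ids <- x$feature_id
  if (anyDuplicated(ids)) {
    stop(arg, ": duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samp <- names(x)[-1]
  if (anyDuplicated(samp)) {
    stop(arg, ": duplicate sample ids: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "), call. = FALSE)
  }
  for (s in samp) {
    v <- x[[s]]
    if (!is.numeric(v)) stop(arg, ": sample '", s, "' has non-numeric counts", call. = FALSE)
    if (anyNA(v)) stop(arg, ": sample '", s, "' has missing counts", call. = FALSE)
    if (any(v < 0)) stop(arg, ": sample '", s, "' has negative counts", call. = FALSE)
    if (!all(is_wholenumber(v))) stop(arg, ": sample '", s, "' has non-integer counts", call. = FALSE)
  }
  invisible(x)
}

# tibble <-> features x samples integer matrix
as_count_matrix <- function(x) {
  validate_count_table(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

count_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

sample_ids <- function(x) names(x)[-1]

`%||%` <- function(a, b) if (is.null(a)) b else a
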