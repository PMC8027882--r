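#' Bray-Curtis dissimilarity matrix
#'
#' Computes pairwise Bray-Curtis dissimilarities between samples,
#' \eqn{d(x, y) = \sum_f |x_f - y_f| / \sum_f (x_f + y_f)}, from a count
#' table or a control-normalized table. Values lie in \[0, 1\], the diagonal
#' is zero, and the result is invariant to feature order.
#'
#' @param table Count table or `sip_normalized` table.
#' @return A symmetric matrix of class `sip_dist` with sample ids as
#'   dimnames; use [stats::as.dist()] or pass directly to [permanova()].
#' @export
bray_curtis <- function(table) {
  m <- if (is.data.frame(table)) {
    mm <- as.matrix(table[, -1, drop = FALSE])
    rownames(mm) <- table[[1]]
    mm
  } else as.matrix(table)
  if (ncol(m) < 2L) stop("need at least two samples", call. = FALSE)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ", paste(colnames(m)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  structure(d, class = c("sip_dist", class(d)))
}

#' @export
as.dist.sip_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass(m), diag = diag, upper = upper)
}

# Gower-centered inner-product matrix from a distance matrix:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n)
gower_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, colMeans(a)) + mean(a)
}

# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a distance matrix among crossed factors with sequential
#' (Type I) sums of squares, in the order the terms are given. The squared
#' distance matrix is Gower-centered; each term's sum of squares is the
#' increment in `tr(H G)` between nested hat matrices; pseudo-F and R-squared
#' follow. Significance comes from free (unrestricted) permutation of the
#' samples, the same permutation stream being applied to every term. When
#' the total number of permutations `n!` does not exceed `exhaustive_limit`,
#' the full permutation distribution is enumerated and the p-value is the
#' exact proportion of permutations (the identity included) with
#' `F >= F_obs`; otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)`.
#'
#' @param dm A `sip_dist`, [stats::dist] object or symmetric matrix.
#' @param data Data frame with a `sample_id` column and the factor columns;
#'   rows are matched to the distance matrix by sample id.
#' @param terms Character vector of factor names, in model order; interaction
#'   terms may be written `"a:b"`.
#' @param n_perm Number of random permutations (default 999, giving a p-value
#'   floor of 0.001).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive_limit Enumerate exactly when `n! <=` this value.
#' @return An object of class `sip_permanova`: list with `table` (tibble of
#'   term, df, SS, pseudo_F, R2, p_perm plus Residual and Total rows),
#'   `n_perm`, `seed`, `exhaustive`.
#' @export
permanova <- function(dm, data, terms, n_perm = 999, seed = 1L,
                      exhaustive_limit = 10000) {
  d <- as.matrix(dm)
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must carry sample ids as dimnames", call. = FALSE)
  data <- as.data.frame(data)
  idx <- match(ids, data$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) missing from data: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  df_meta <- data[idx, , drop = FALSE]
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(base_vars, names(df_meta))
  if (length(miss)) stop("term variable(s) not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  for (v in base_vars) {
    df_meta[[v]] <- factor(df_meta[[v]])
    if (nlevels(df_meta[[v]]) < 2L) {
      stop("factor '", v, "' has fewer than two levels", call. = FALSE)
    }
    if (min(table(df_meta[[v]])) < 2L) {
      stop("factor '", v, "' has a singleton level", call. = FALSE)
    }
  }
  if (n_perm < 99) warning("n_perm < 99 gives a very coarse permutation p-value")

  G <- gower_center(d)
  ss_total <- sum(diag(G))

  # nested hat matrices in term order; df from rank increments
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  prev_rank <- 1L   # intercept
  for (j in seq_along(terms)) {
    f <- stats::reformulate(terms[seq_len(j)])
    X <- stats::model.matrix(f, df_meta)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    dfs[j] <- q$rank - prev_rank
    prev_rank <- q$rank
  }
  if (any(dfs == 0L)) {
    stop("term(s) aliased with earlier terms: ",
         paste(terms[dfs == 0L], collapse = ", "), call. = FALSE)
  }
  df_res <- n - prev_rank
  if (df_res < 1L) stop("model saturates the samples: no residual degrees of freedom",
                        call. = FALSE)

  tol <- 1e-10 * max(abs(ss_total), .Machine$double.eps)
  stat_fun <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    # perfect fits leave a residual that is zero up to rounding; floor it so
    # fully separated groups report F = Inf rather than noise-signed ratios
    if (ss_res < tol) {
      ss_res <- 0
      Fv <- ifelse(ss > tol, Inf, NaN)
    } else {
      Fv <- (ss / dfs) / (ss_res / df_res)
    }
    list(ss = ss, ss_res = ss_res, F = Fv)
  }
  obs <- stat_fun(G)

  exhaustive <- factorial(n) <= exhaustive_limit
  if (exhaustive) {
    perms <- all_permutations(n)
  } else {
    perms <- withr::with_seed(as.integer(seed), {
      t(replicate(n_perm, sample.int(n)))
    })
  }
  ge <- numeric(length(terms))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    Fp <- stat_fun(G[p, p])$F
    hit <- Fp >= obs$F * (1 - 1e-12) - 1e-12
    ge <- ge + ifelse(is.na(hit), FALSE, hit)
  }
  p_perm <- if (exhaustive) ge / nrow(perms) else (1 + ge) / (n_perm + 1)
  # under random sampling the identity is not drawn, hence the +1; under
  # exhaustive enumeration it is one of the n! permutations already

  tab <- tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(obs$ss, obs$ss_res, ss_total),
    pseudo_F = c(obs$F, NA_real_, NA_real_),
    R2 = c(obs$ss / ss_total, obs$ss_res / ss_total, 1),
    p_perm = c(p_perm, NA_real_, NA_real_)
  )
  structure(list(table = tab,
                 n_perm = if (exhaustive) nrow(perms) else n_perm,
                 seed = as.integer(seed),
                 exhaustive = exhaustive),
            class = "sip_permanova")
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates (keeping real and
#' imaginary axes separately), computes each sample's distance to its group
#' spatial centroid with the imaginary-axis correction
#' \eqn{z_i = \sqrt{\max(0, d^2_{real} - d^2_{imag})}}, and tests equality of
#' mean dispersion across groups with a one-way F statistic whose null
#' distribution comes from permuting group labels over the `z` values.
#'
#' @param dm Distance matrix (`sip_dist`, `dist`, or symmetric matrix).
#' @param groups Grouping vector, or the name of a column in `data`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param data Optional data frame with `sample_id` and the grouping column.
#' @return An object of class `sip_permdisp`: list with `distances` (tibble
#'   of sample_id, group, distance), `F`, `p_perm`, `eigenvalues`, `coords`
#'   (real-axis principal coordinates), `n_perm`, `seed`.
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = 1L, data = NULL) {
  d <- as.matrix(dm)
  n <- nrow(d)
  ids <- rownames(d)
  if (!is.null(data) && is.character(groups) && length(groups) == 1L) {
    groups <- data[[groups]][match(ids, data$sample_id)]
  }
  g <- factor(groups)
  if (length(g) != n) stop("groups length must match the distance matrix", call. = FALSE)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (min(table(g)) < 2L) stop("every group needs at least two members", call. = FALSE)

  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  cr <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  ci <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))

  z <- numeric(n)
  for (lev in levels(g)) {
    in_g <- g == lev
    cen_r <- colMeans(cr[in_g, , drop = FALSE])
    d2r <- rowSums(sweep(cr[in_g, , drop = FALSE], 2, cen_r)^2)
    d2i <- 0
    if (ncol(ci)) {
      cen_i <- colMeans(ci[in_g, , drop = FALSE])
      d2i <- rowSums(sweep(ci[in_g, , drop = FALSE], 2, cen_i)^2)
    }
    z[in_g] <- sqrt(pmax(0, d2r - d2i))
  }

  f_stat <- function(zz, gg) {
    mg <- tapply(zz, gg, mean)
    ng <- tabulate(gg)
    grand <- mean(zz)
    ssb <- sum(ng * (mg - grand)^2)
    ssw <- sum((zz - mg[gg])^2)
    dfb <- nlevels(gg) - 1L
    dfw <- length(zz) - nlevels(gg)
    if (ssw <= 0) return(if (ssb > 0) Inf else NA_real_)
    (ssb / dfb) / (ssw / dfw)
  }
  Fobs <- f_stat(z, g)
  perm_F <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) f_stat(z[sample.int(n)], g), numeric(1))
  })
  p <- if (is.na(Fobs)) NA_real_ else (1 + sum(perm_F >= Fobs - 1e-12, na.rm = TRUE)) / (n_perm + 1)

  structure(list(distances = tibble::tibble(sample_id = ids %||% as.character(seq_len(n)),
                                            group = as.character(g), distance = z),
                 F = Fobs, p_perm = p,
                 eigenvalues = e$values,
                 coords = cr,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "sip_permdisp")
}

#' Principal-coordinate (PCoA) sample coordinates for plotting
#'
#' @param dm Distance matrix.
#' @param k Number of axes to return.
#' @return Tibble with `sample_id`, `PCo1..PCok`; attribute `eig_fraction`
#'   gives the fraction of positive eigenvalue sum per axis.
#' @export
pcoa_coordinates <- function(dm, k = 2) {
  d <- as.matrix(dm)
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > max(abs(e$values)) * 1e-8)
  k <- min(k, length(pos))
  axes <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  out <- tibble::as_tibble(axes, .name_repair = ~ paste0("PCo", seq_len(k)))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(d)), out)
  attr(out, "eig_fraction") <- e$values[pos[seq_len(k)]] / sum(e$values[pos])
  out
}

#' Per-sample fractions of Type I / II / III methanotrophs
#'
#' Divides the control-normalized abundance of each methanotroph type by the
#' total methanotroph normalized abundance of the sample. Fractions sum to 1
#' wherever any methanotroph signal remains; samples with zero methanotroph
#' total are flagged `defined = FALSE` with `NA` fractions rather than 0/0.
#'
#' @param normalized A `sip_normalized` table.
#' @param guilds Guild catalog.
#' @return Tibble: `sample_id`, `type`, `value` (summed normalized
#'   abundance), `fraction`, `defined`.
#' @export
methanotroph_type_fractions <- function(normalized, guilds) {
  guilds <- validate_guild_catalog(guilds)
  mt <- guilds[guilds$guild == "methanotroph", c("feature_id", "methanotroph_type")]
  ids <- sample_ids(normalized)
  sub <- dplyr::inner_join(tibble::as_tibble(normalized), mt, by = "feature_id")
  out <- lapply(ids, function(s) {
    by_type <- tapply(sub[[s]], factor(sub$methanotroph_type, levels = c("I", "II", "III")),
                      sum, default = 0)
    total <- sum(by_type)
    tibble::tibble(sample_id = s, type = c("I", "II", "III"),
                   value = as.numeric(by_type),
                   fraction = if (total > 0) as.numeric(by_type) / total else NA_real_,
                   defined = total > 0)
  })
  dplyr::bind_rows(out)
}

#' Total-community comparison for fraction-resolved 16S data
#'
#' Reconstructs each core's "total" community by pooling its light and heavy
#' gradient fractions, rarefies every pooled sample to a common depth
#' (default 20000 annotations), builds a Bray-Curtis dissimilarity matrix,
#' and runs PERMANOVA over the design factors and (optionally) their pairwise
#' interactions. Factors with fewer than two levels in the data are dropped
#' with a message; the executed stage order is recorded in the `stages`
#' attribute of the result.
#'
#' @param table Fraction-resolved 16S count table.
#' @param meta Sample metadata.
#' @param depth Rarefaction depth (default 20000).
#' @param n_perm,seed Permutation settings for [permanova()].
#' @param terms Candidate design factors, tested in this order.
#' @param interactions Include pairwise interactions of retained factors.
#' @return A `sip_permanova` object with attribute `stages`.
#' @export
total_community_comparison <- function(table, meta, depth = 20000,
                                       n_perm = 999, seed = 1L,
                                       terms = c("location", "substrate", "land_use"),
                                       interactions = TRUE) {
  meta <- validate_sample_metadata(meta)
  # keep only cores with both fractions sequenced (in the SIP design usually
  # just the 12C controls); labeled cores with heavy-only data are dropped
  ids <- sample_ids(table)
  m <- meta[match(ids, meta$sample_id), ]
  key <- paste(m$location, m$land_use, m$substrate, m$isotope, m$core, sep = "\r")
  complete <- stats::ave(seq_along(key), key, FUN = length) == 2L
  if (any(!complete)) {
    message("dropping ", sum(!complete), " sample(s) without a partner fraction")
    table <- table[, c("feature_id", ids[complete])]
  }
  pooled <- pool_fractions(table, meta)
  pmeta <- attr(pooled, "metadata")
  rare <- rarefy(pooled, depth, seed)
  dm <- bray_curtis(rare)

  keep <- terms[vapply(terms, function(v) length(unique(pmeta[[v]])) >= 2L, logical(1))]
  dropped <- setdiff(terms, keep)
  if (length(dropped)) {
    message("dropping single-level factor(s): ", paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no design factor with two or more levels", call. = FALSE)
  model_terms <- keep
  if (interactions && length(keep) >= 2L) {
    model_terms <- c(keep, utils::combn(keep, 2, paste, collapse = ":"))
  }
  res <- tryCatch(
    permanova(dm, pmeta, model_terms, n_perm = n_perm, seed = seed),
    error = function(e) {
      # interactions can be aliased in nested designs; fall back to main effects
      if (interactions) permanova(dm, pmeta, keep, n_perm = n_perm, seed = seed) else stop(e)
    })
  attr(res, "stages") <- c("pool_fractions", "rarefy", "bray_curtis", "permanova")
  res
}
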