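test_that("Bray-Curtis reproduces hand-computed dissimilarities", {
  tbl <- tibble::tibble(feature_id = c("f1", "f2"),
                        x = c(6, 2), y = c(2, 2), z = c(6, 2))
  d <- as.matrix(bray_curtis(tbl))
  expect_equal(d["x", "y"], 4 / 12, tolerance = 1e-12)
  expect_equal(d["x", "z"], 0)
  disjoint <- tibble::tibble(feature_id = c("f1", "f2"), a = c(2, 0), b = c(0, 2))
  expect_equal(as.matrix(bray_curtis(disjoint))["a", "b"], 1)
})

test_that("Bray-Curtis satisfies its structural invariants on random tables", {
  withr::with_seed(50, {
    for (i in 1:10) {
      m <- matrix(rpois(8 * 6, 5), 8, 6,
                  dimnames = list(paste0("f", 1:8), paste0("s", 1:6)))
      m[1, ] <- m[1, ] + 1   # guard against all-zero samples
      tbl <- tibble::as_tibble(m, rownames = "feature_id")
      d <- as.matrix(bray_curtis(tbl))
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0 & d <= 1))
      # invariance to feature order
      d2 <- as.matrix(bray_curtis(tbl[sample(8), ]))
      expect_equal(d2, d)
    }
  })
  zero <- tibble::tibble(feature_id = "f1", ok = 3, empty = 0)
  expect_error(bray_curtis(zero), "empty")
})

test_that("PERMANOVA sums of squares match adonis2 and R2 sums to one", {
  withr::with_seed(51, {
    m <- matrix(rpois(30 * 12, 20), 30, 12,
                dimnames = list(paste0("f", 1:30), paste0("s", 1:12)))
    tbl <- tibble::as_tibble(m, rownames = "feature_id")
    dm <- bray_curtis(tbl)
    meta <- data.frame(sample_id = colnames(m),
                       g = rep(c("a", "b", "c"), each = 4),
                       h = rep(c("x", "y"), 6))
    res <- permanova(dm, meta, c("g", "h"), n_perm = 499, seed = 2)
    ad <- vegan::adonis2(as.dist(dm) ~ g + h, data = meta,
                         permutations = 499, by = "terms")
    expect_equal(res$table$SS[1:2], ad$SumOfSqs[1:2], tolerance = 1e-10)
    expect_equal(res$table$pseudo_F[1:2], ad$F[1:2], tolerance = 1e-10)
    expect_equal(res$table$R2[1:2], ad$R2[1:2], tolerance = 1e-10)
    r2 <- res$table$R2
    expect_equal(sum(r2[res$table$term != "Total"]), 1, tolerance = 1e-9)
    expect_true(all(res$table$p_perm[1:2] >= 1 / 500))
  })
})

test_that("exhaustive PERMANOVA equals a brute-force enumeration", {
  withr::with_seed(52, {
    m <- matrix(rpois(20 * 6, 15), 20, 6,
                dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
    tbl <- tibble::as_tibble(m, rownames = "feature_id")
    dm <- bray_curtis(tbl)
    meta <- data.frame(sample_id = colnames(m), g = rep(c("a", "b"), each = 3))
    res <- permanova(dm, meta, "g")
    expect_true(res$exhaustive)
    expect_equal(res$n_perm, 720)
    # independent oracle: group-sum formula for one factor, all 720 label
    # permutations
    d2 <- as.matrix(dm)^2
    n <- 6
    ss_tot <- sum(d2) / (2 * n)
    ssw_of <- function(gg) {
      s <- 0
      for (lev in unique(gg)) {
        idx <- which(gg == lev)
        s <- s + sum(d2[idx, idx]) / (2 * length(idx))
      }
      s
    }
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      }
      out
    }
    g <- meta$g
    F_of <- function(gg) {
      ssw <- ssw_of(gg)
      ((ss_tot - ssw) / 1) / (ssw / (n - 2))
    }
    F_obs <- F_of(g)
    Fs <- vapply(perms(1:6), function(p) F_of(g[p]), numeric(1))
    expect_equal(res$table$pseudo_F[1], F_obs, tolerance = 1e-10)
    expect_equal(res$table$p_perm[1], mean(Fs >= F_obs - 1e-12),
                 tolerance = 1e-12)
  })
})

test_that("maximally separated identical-point groups give the minimal exact p", {
  # two groups of coincident points: only permutations preserving the
  # partition (3!*3!*2 = 72 of 720) reach the observed F
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  meta <- data.frame(sample_id = paste0("s", 1:6), g = rep(c("a", "b"), each = 3))
  res <- permanova(d, meta, "g")
  expect_true(res$exhaustive)
  expect_equal(res$table$p_perm[1], 72 / 720, tolerance = 1e-12)
})

test_that("PERMANOVA p is invariant to group-preserving relabeling", {
  withr::with_seed(53, {
    m <- matrix(rpois(15 * 8, 10), 15, 8,
                dimnames = list(paste0("f", 1:15), paste0("s", 1:8)))
    tbl <- tibble::as_tibble(m, rownames = "feature_id")
    dm <- bray_curtis(tbl)
    meta <- data.frame(sample_id = colnames(m), g = rep(c("a", "b"), each = 4))
    r1 <- permanova(dm, meta, "g", n_perm = 199, seed = 9)
    meta2 <- meta
    meta2$g <- ifelse(meta$g == "a", "zzz", "aaa")   # rename levels only
    r2 <- permanova(dm, meta2, "g", n_perm = 199, seed = 9)
    expect_equal(r1$table$p_perm[1], r2$table$p_perm[1])
    expect_equal(r1$table$SS[1], r2$table$SS[1], tolerance = 1e-12)
  })
})

test_that("PERMANOVA validates its design", {
  d <- matrix(0.5, 5, 5); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  meta <- data.frame(sample_id = paste0("s", 1:5),
                     g = c("a", "a", "b", "b", "c"))
  expect_error(permanova(d, meta, "g"), "singleton")
  meta$g <- "a"
  expect_error(permanova(d, meta, "g"), "two levels")
  meta$g <- c("a", "a", "a", "b", "b")
  expect_warning(permanova(d, meta, "g", n_perm = 50), "coarse")
})

test_that("PERMDISP distances are zero iff group points coincide", {
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  res <- permdisp(d, rep(c("a", "b"), each = 3), n_perm = 99, seed = 1)
  expect_equal(res$distances$distance, rep(0, 6), tolerance = 1e-8)
})

test_that("PERMDISP on Euclidean input needs no imaginary correction and matches betadisper", {
  withr::with_seed(54, {
    pts <- matrix(rnorm(20), 10, 2)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
    g <- rep(c("a", "b"), each = 5)
    res <- permdisp(d, g, n_perm = 199, seed = 3)
    # Euclidean distances embed exactly: no meaningfully negative eigenvalues
    expect_gt(min(res$eigenvalues), -max(res$eigenvalues) * 1e-8)
    bd <- vegan::betadisper(as.dist(d), g, type = "centroid")
    expect_equal(res$distances$distance, as.numeric(bd$distances),
                 tolerance = 1e-8)
    expect_equal(res$F, anova(bd)[["F value"]][1], tolerance = 1e-8)
  })
})

test_that("PERMDISP matches betadisper distances on non-Euclidean Bray-Curtis input", {
  sim <- simulate_sip_experiment(small_preset(55))
  sub <- sim$counts[, 1:13]
  dm <- bray_curtis(sub)
  g <- rep(c("a", "b"), each = 6)
  res <- permdisp(dm, g, n_perm = 99, seed = 4)
  bd <- vegan::betadisper(as.dist(dm), g, type = "centroid")
  expect_equal(res$distances$distance, as.numeric(bd$distances), tolerance = 1e-8)
})

test_that("methanotroph type fractions normalize within samples", {
  guilds <- tibble::tibble(
    feature_id = c("t1", "t2", "t3", "m1"),
    guild = c("methanotroph", "methanotroph", "methanotroph", "methanogen"),
    methanotroph_type = c("I", "II", "III", "none"),
    methanogenesis_pathway = c("none", "none", "none", "acetoclastic"))
  norm <- tibble::tibble(feature_id = c("t1", "t2", "t3", "m1"),
                         s1 = c(2, 6, 0, 50),
                         s2 = c(0, 0, 4, 3),
                         s3 = c(0, 0, 0, 9))
  class(norm) <- c("sip_normalized", class(norm))
  fr <- methanotroph_type_fractions(norm, guilds)
  s1 <- fr[fr$sample_id == "s1", ]
  expect_equal(s1$fraction, c(0.25, 0.75, 0))
  s2 <- fr[fr$sample_id == "s2", ]
  expect_equal(s2$fraction[s2$type == "III"], 1)
  s3 <- fr[fr$sample_id == "s3", ]
  expect_true(all(!s3$defined) && all(is.na(s3$fraction)))
})

test_that("type fractions sum to one across a simulated run", {
  sim <- simulate_sip_experiment(small_preset(56))
  pairing <- link_controls(sim$counts, sim$metadata)
  rare <- sim$counts[, c("feature_id", union(pairing$sample_id, pairing$control_id))]
  norm <- control_normalize(rare, pairing)
  fr <- methanotroph_type_fractions(norm, sim$guilds)
  sums <- dplyr::summarise(dplyr::group_by(fr[fr$defined, ], sample_id),
                           total = sum(fraction))
  expect_true(all(abs(sums$total - 1) < 1e-12))
})

test_that("total-community comparison runs pool -> rarefy -> distance -> test", {
  sim <- simulate_sip_experiment(small_preset(57))
  res <- suppressMessages(
    total_community_comparison(sim$counts, sim$metadata, depth = 2000,
                               n_perm = 99, seed = 5))
  expect_identical(attr(res, "stages"),
                   c("pool_fractions", "rarefy", "bray_curtis", "permanova"))
  expect_s3_class(res, "sip_permanova")
  expect_true(all(c("substrate", "land_use") %in% res$table$term))
  r2 <- res$table$R2[res$table$term != "Total"]
  expect_equal(sum(r2), 1, tolerance = 1e-9)
})
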