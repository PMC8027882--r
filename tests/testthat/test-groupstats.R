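test_that("one-way ANOVA matches the direct textbook formulas", {
  withr::with_seed(40, {
    for (i in 1:10) {
      g <- rep(c("a", "b", "c"), each = 5)
      y <- rnorm(15, mean = rep(runif(3, 0, 3), each = 5))
      fit <- anova_oneway(y, g)
      # independent hand computation
      means <- tapply(y, g, mean)
      ssb <- sum(5 * (means - mean(y))^2)
      ssw <- sum((y - rep(means, each = 5))^2)
      F_hand <- (ssb / 2) / (ssw / 12)
      expect_equal(fit$F, F_hand, tolerance = 1e-10)
      expect_equal(fit$p_value, pf(F_hand, 2, 12, lower.tail = FALSE),
                   tolerance = 1e-10)
      expect_equal(fit$eta_squared, ssb / (ssb + ssw), tolerance = 1e-10)
    }
  })
})

test_that("ANOVA degenerate cases are reported explicitly", {
  # perfect separation: zero within-group variance
  fit <- anova_oneway(c(1, 1, 3, 3), c("a", "a", "b", "b"))
  expect_equal(fit$eta_squared, 1)
  expect_equal(fit$p_value, 0)
  # all observations equal: no test possible
  fit0 <- anova_oneway(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_identical(fit0$note, "no-test")
  expect_true(is.na(fit0$F))
  expect_error(anova_oneway(1:5, rep("a", 5)), "two groups")
})

test_that("eta squared lies in [0,1] and is 0 for equal group means", {
  withr::with_seed(41, {
    for (i in 1:20) {
      y <- rnorm(12)
      g <- rep(c("a", "b", "c"), 4)
      e <- anova_oneway(y, g)$eta_squared
      expect_gte(e, 0); expect_lte(e, 1)
    }
  })
  # equal means by construction: a=(1,5), b=(2,4), c=(0,6), all means 3
  y <- c(1, 5, 2, 4, 0, 6)
  expect_equal(anova_oneway(y, rep(c("a", "b", "c"), each = 2))$eta_squared, 0)
})

test_that("two-group Tukey reduces to the pooled two-sided t-test", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      y <- c(rnorm(n1, 0), rnorm(n2, 0.8))
      g <- rep(c("a", "b"), c(n1, n2))
      tk <- tukey_kramer(y, g)
      tt <- t.test(y ~ g, var.equal = TRUE)
      expect_equal(tk$q, sqrt(2) * abs(tt$statistic), ignore_attr = TRUE,
                   tolerance = 1e-10)
      expect_equal(tk$p_tukey, tt$p.value, tolerance = 1e-8)
    }
  })
})

test_that("Tukey-Kramer agrees with TukeyHSD on unbalanced data", {
  withr::with_seed(43, {
    for (i in 1:10) {
      sizes <- sample(3:7, 3, replace = TRUE)
      g <- factor(rep(c("a", "b", "c"), sizes))
      y <- rnorm(sum(sizes), mean = as.numeric(g))
      tk <- tukey_kramer(y, g)
      hsd <- TukeyHSD(aov(y ~ g))$g
      for (j in seq_len(nrow(tk))) {
        key <- paste0(tk$group2[j], "-", tk$group1[j])
        expect_equal(tk$p_tukey[j], hsd[key, "p adj"], tolerance = 1e-8)
      }
    }
  })
})

test_that("Tukey is symmetric in group order and degenerate-safe", {
  y <- c(1.2, 1.4, 5.1, 5.3, 9.0, 9.4)
  g <- rep(c("a", "b", "c"), each = 2)
  tk1 <- tukey_kramer(y, g)
  tk2 <- tukey_kramer(rev(y), rev(g))
  expect_equal(sort(tk1$p_tukey), sort(tk2$p_tukey), tolerance = 1e-12)
  expect_true(all(tk1$p_tukey <= 1))
  # zero within-group variance: distinct means give p = 0, equal means no-test
  tk0 <- tukey_kramer(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(tk0$p_tukey, 0)
  tke <- tukey_kramer(c(2, 2, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.na(tke$p_tukey))
})

test_that("richness comparison recovers a constructed land-use difference", {
  # per-sample active methanogen richness: PF=(2,2,2), P=(8,8,8), SF=(2,2,2)
  guilds <- tibble::tibble(feature_id = paste0("m", 1:8),
                           guild = "methanogen", methanotroph_type = "none",
                           methanogenesis_pathway = "hydrogenotrophic")
  rows <- list()
  for (lu in c("PF", "P", "SF")) {
    for (core in 1:3) {
      k <- if (lu == "P") 8 else 2
      rows[[paste(lu, core)]] <- tibble::tibble(
        feature_id = paste0("m", 1:k),
        sample_id = paste0(lu, "_c", core),
        count13 = 10, count12 = 1, depth13 = 100, depth12 = 100,
        p_value = 0.001, active = TRUE, norm_value = 9)
    }
  }
  calls <- fake_calls(dplyr::bind_rows(rows))
  meta <- fake_meta(unique(calls$sample_id))
  res <- richness_comparison(calls, meta, guilds, "methanogen")
  expect_equal(res$association, "P")
  pw <- res$pairwise[[1]]
  p_vs_pf <- pw$p_tukey[(pw$group1 == "P" & pw$group2 == "PF") |
                          (pw$group2 == "P" & pw$group1 == "PF")]
  expect_lt(p_vs_pf, 0.05)
})

test_that("identical richness everywhere yields a no-test result", {
  guilds <- tibble::tibble(feature_id = "m1", guild = "methanogen",
                           methanotroph_type = "none",
                           methanogenesis_pathway = "multiple")
  rows <- lapply(c("PF_c1", "PF_c2", "P_c1", "P_c2"), function(s)
    tibble::tibble(feature_id = "m1", sample_id = s, count13 = 10, count12 = 1,
                   depth13 = 100, depth12 = 100, p_value = 0.001, active = TRUE,
                   norm_value = 9))
  calls <- fake_calls(dplyr::bind_rows(rows))
  meta <- fake_meta(unique(calls$sample_id))
  res <- richness_comparison(calls, meta, guilds, "methanogen")
  expect_true(is.na(res$p_anova))
  expect_true(is.na(res$association))
})

test_that("feature comparison associates pasture-enriched features and rechecks activity", {
  # one feature higher in P and active there; one differing but never active
  set.seed(44)
  samples <- c(paste0("PF_c", 1:3), paste0("P_c", 1:3), paste0("SF_c", 1:3))
  lus <- rep(c("PF", "P", "SF"), each = 3)
  norm <- tibble::tibble(feature_id = c("hit", "ghost", "flat"))
  vals_hit <- c(1, 2, 1, 30, 28, 33, 2, 1, 2)
  vals_ghost <- c(0, 1, 0, 14, 15, 16, 1, 0, 1)
  vals_flat <- rep(5, 9)
  for (i in seq_along(samples)) {
    norm[[samples[i]]] <- c(vals_hit[i], vals_ghost[i], vals_flat[i])
  }
  attr(norm, "depth") <- 100
  class(norm) <- c("sip_normalized", class(norm))
  calls <- fake_calls(tibble::tibble(
    feature_id = "hit", sample_id = paste0("P_c", 1:3),
    count13 = 30, count12 = 1, depth13 = 100, depth12 = 100,
    p_value = 1e-6, active = TRUE, norm_value = c(30, 28, 33)))
  meta <- fake_meta(samples)
  res <- compare_active_features(norm, calls, meta, alpha = 0.05)
  expect_equal(res$feature_id, "hit")
  expect_equal(res$association, "P")
  expect_true(res$active_confirmed)
  expect_gt(res$mean_P, res$mean_PF)
  # the never-active feature appears only when explicitly kept
  all_rows <- compare_active_features(norm, calls, meta, alpha = 0.05,
                                      keep_unconfirmed = TRUE)
  expect_true("ghost" %in% all_rows$feature_id)
  expect_false(all_rows$active_confirmed[all_rows$feature_id == "ghost"])
})

test_that("feature comparison is invariant to row and column permutations", {
  sim <- simulate_sip_experiment(small_preset(45))
  pairing <- link_controls(sim$counts, sim$metadata)
  rare <- sim$counts[, c("feature_id", union(pairing$sample_id, pairing$control_id))]
  norm <- control_normalize(rare, pairing)
  calls <- call_active(rare, pairing)
  base <- compare_active_features(norm, calls, sim$metadata, sim$guilds)
  perm_rows <- withr::with_seed(5, sample(nrow(norm)))
  perm_cols <- withr::with_seed(6, sample(seq_len(ncol(norm) - 1)))
  shuffled <- norm[perm_rows, c(1, 1 + perm_cols)]
  attr(shuffled, "depth") <- attr(norm, "depth")
  class(shuffled) <- class(norm)
  again <- compare_active_features(shuffled, calls, sim$metadata, sim$guilds)
  expect_equal(dplyr::arrange(as.data.frame(again), feature_id),
               dplyr::arrange(as.data.frame(base), feature_id))
})

test_that("pearson correlation matches the closed-form t computation", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1)
  withr::with_seed(46, {
    x <- rnorm(10); y <- rnorm(10)
    out <- pearson_correlation(x, y)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r * sqrt(8 / (1 - r^2))
    expect_equal(out$r, r, tolerance = 1e-12)
    expect_equal(out$p_value, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  })
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "3 observations")
})
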