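test_that("Welch t matches the closed-form formula", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- welch_t(a, b)
  # hand evaluation of the Welch statistic and Satterthwaite df
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$mean_a, 2)
  expect_equal(res$n_b, 3L)
})

test_that("Welch t is translation-invariant and antisymmetric", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(10, 0.5)
  r1 <- welch_t(a, b)
  r2 <- welch_t(a + 100, b + 100)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
  r3 <- welch_t(b, a)
  expect_equal(r3$statistic, -r1$statistic)
  expect_equal(r3$p_value, r1$p_value)
})

test_that("Welch t handles degenerate inputs per contract", {
  res <- welch_t(c(2, 2, 2), c(2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "constant")
  # identical samples: t = 0, p = 1
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("Mann-Whitney U reports min(U_a, U_b) with exact p when small", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$U_a + res$U_b, 9)
  expect_equal(res$p_value, 0.1)       # 2/20 rank assignments as extreme
  expect_true(res$exact)
  # identical multisets: U = n_a * n_b / 2
  r2 <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$statistic, 8)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p equals full-permutation p (no ties)", {
  set.seed(11)
  sizes <- list(c(3, 4), c(4, 4), c(5, 5), c(4, 6))
  for (sz in sizes) {
    a <- round(rnorm(sz[1]), 4)
    b <- round(rnorm(sz[2], 0.8), 4)
    res <- mann_whitney_u(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, perm_mwu_p(a, b), tolerance = 1e-12)
  }
})

test_that("ties and large samples fall back to the corrected approximation", {
  a <- c(1, 2, 2, 3, 5, 6, 7, 8)
  b <- c(2, 3, 4, 4, 6, 9, 10, 11)
  res <- mann_whitney_u(a, b)
  expect_false(res$exact)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(res$p_value, ref$p.value)
})

test_that("Pearson r matches its covariance formula and transforms", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  set.seed(9)
  u <- rnorm(10); v <- 0.6 * u + rnorm(10, 0, 0.5)
  res <- pearson_r(u, v)
  r_hand <- cov(u, v) / (sd(u) * sd(v))
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(res$statistic, r_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(abs(t_hand), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  # positive affine invariance; sign flip under negation
  expect_equal(pearson_r(3 * u + 2, v)$statistic, r_hand, tolerance = 1e-12)
  expect_equal(pearson_r(u, -v)$statistic, -r_hand, tolerance = 1e-12)
  expect_error(pearson_r(u, rep(1, 10)), "zero variance")
  expect_error(pearson_r(u, v[1:5]), "equal length")
})

test_that("group analysis builds the four report families", {
  # hand-built metrics table: 6 + 6 subjects, 2 bands, strong group effect
  set.seed(21)
  subjects <- sprintf("S%02d", 1:12)
  grp <- rep(c("a", "b"), each = 6)
  mk <- function(base, shift) c(rnorm(6, base, 0.02),
                                rnorm(6, base + shift, 0.02))
  metrics <- rbind(
    tibble::tibble(subject_id = subjects, band = "lower_alpha",
                   global_mean_pli = mk(0.5, -0.3),
                   C = mk(0.5, -0.3), L = mk(2, 1),
                   short_left_frontal = mk(0.5, -0.3)),
    tibble::tibble(subject_id = subjects, band = "beta",
                   global_mean_pli = mk(0.3, 0),
                   C = mk(0.3, 0), L = mk(3, 0),
                   short_left_frontal = mk(0.3, 0))
  )
  manifest <- tibble::tibble(subject_id = subjects, group = grp,
                             score = 20 + 10 * metrics$C[1:12] +
                               rnorm(12, 0, 0.1))
  rep <- run_group_analysis(metrics, manifest)
  expect_named(rep, c("global_pli_tests", "distance_tests", "graph_tests",
                      "correlations"))
  expect_equal(nrow(rep$global_pli_tests), 2)
  expect_equal(nrow(rep$distance_tests), 2)
  expect_equal(nrow(rep$graph_tests), 4)
  expect_equal(nrow(rep$correlations), 4)
  la <- rep$global_pli_tests[rep$global_pli_tests$band == "lower_alpha", ]
  expect_true(la$significant)
  expect_gt(la$mean_a, la$mean_b)
  # graph metrics use the rank test
  expect_true(all(rep$graph_tests$statistic_name == "mann_whitney_u"))
  # correlation of C with score is positive in the affected band
  rc <- rep$correlations[rep$correlations$band == "lower_alpha" &
                           rep$correlations$measure == "C", ]
  expect_gt(rc$statistic, 0)
  # FDR column appears on request only
  expect_false("p_bh" %in% names(rep$global_pli_tests))
  rep_fdr <- run_group_analysis(metrics, manifest, fdr = TRUE)
  expect_true("p_bh" %in% names(rep_fdr$global_pli_tests))
  expect_error(
    run_group_analysis(metrics[metrics$subject_id != "S01", ], manifest),
    "S01")
})

test_that("group analysis is reproducible byte for byte", {
  set.seed(5)
  subjects <- sprintf("S%02d", 1:8)
  metrics <- tibble::tibble(subject_id = subjects, band = "theta",
                            global_mean_pli = runif(8),
                            C = runif(8), L = 1 + runif(8))
  manifest <- tibble::tibble(subject_id = subjects,
                             group = rep(c("a", "b"), 4),
                             score = rnorm(8, 25))
  f1 <- tempfile(); f2 <- tempfile()
  for (f in c(f1, f2)) {
    rep <- run_group_analysis(metrics, manifest)
    utils::write.table(rep$global_pli_tests, f, sep = "\t",
                       row.names = FALSE)
  }
  expect_identical(readLines(f1), readLines(f2))
})
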