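two_strata_data <- function(seed = 1, n_genes = 200, pairs_per_period = 12,
                            ...) {
  make_dataset(n_genes = n_genes, strata = c("A", "B"),
               pairs_per_period = pairs_per_period, seed = seed, ...)
}

test_that("the curve-group variable is the gene-set mean for every pair", {
  d <- two_strata_data(seed = 2, n_signal = 20, delta = 1, noise_sd = 0.5)
  v <- build_curve_group_variable(d$x, d$annotation, "123", "A", m = 10)
  expect_length(v$genes, 10)
  expect_equal(v$z, colMeans(d$x[v$genes, ]))
  expect_length(v$z, ncol(d$x))  # computed for pairs of every stratum

  # m above the ordering's gene count: all carriers used, divisor adapts
  v_all <- build_curve_group_variable(d$x, d$annotation, "123", "A", m = 10000)
  expect_lt(length(v_all$genes), nrow(d$x))
  expect_equal(v_all$z, colMeans(d$x[v_all$genes, ]))
})

test_that("requesting an ordering no gene carries is an error naming it", {
  cfg <- simulation_config(3, uniform_design("A", 3, 6), n_signal = 3,
                           signal_labels = "123", delta = 5, noise_sd = 0.05,
                           seed = 4)
  d <- generate_dataset(cfg)
  expect_error(build_curve_group_variable(d$x, d$annotation, "231", "A"),
               "231.*stratum 'A'")
  expect_error(build_curve_group_variable(d$x, d$annotation, "999", "A"),
               "not a valid curve-group label")
})

test_that("Z is linear in the data for a fixed gene set", {
  d1 <- two_strata_data(seed = 5)
  set.seed(8)
  shift <- matrix(rnorm(length(d1$x)), nrow(d1$x), ncol(d1$x),
                  dimnames = dimnames(d1$x))
  genes <- rownames(d1$x)[1:25]
  z1 <- colMeans(d1$x[genes, ])
  z2 <- colMeans(shift[genes, ])
  z12 <- colMeans((d1$x + shift)[genes, ])
  expect_equal(z12, z1 + z2)
})

test_that("the Z strata test recovers its observed statistic and direction", {
  d <- two_strata_data(seed = 7, n_signal = 30, delta = 1, noise_sd = 0.5)
  res <- z_strata_test(d$x, d$annotation, "123", "A", c("A", "B"),
                       n_perm = 49, seed = 3)
  v <- build_curve_group_variable(d$x, d$annotation, "123", "A", m = 100)
  za <- v$z[d$annotation$pair_id[d$annotation$stratum == "A"]]
  zb <- v$z[d$annotation$pair_id[d$annotation$stratum == "B"]]
  expect_equal(res$observed, oracle_tstat(za, zb), tolerance = 1e-12)
  expect_equal(res$p_value, (res$K + 1) / (res$N + 1))
})

test_that("a planted stratum shift is detected at the attainable minimum p", {
  cfg <- simulation_config(150, uniform_design(c("A", "B"), 3, 12),
                           n_signal = 30, signal_labels = "123", delta = 2,
                           noise_sd = 0.5, signal_strata = "A",
                           stratum_shift = 2, seed = 10)
  d <- generate_dataset(cfg)
  res <- z_strata_test(d$x, d$annotation, "123", "A", c("A", "B"),
                       n_perm = 99, seed = 4)
  expect_equal(res$p_value, 1 / 100)
  lk <- lk_test(d$x, d$annotation, c("A", "B"), k_grid = 30,
                n_perm = 99, seed = 4)
  expect_equal(lk$table$p_value, 1 / 100)
})

test_that("per-gene per-period t-statistics match the scalar oracle and negate on swap", {
  d <- two_strata_data(seed = 9, n_genes = 40)
  t1 <- gene_period_tstat(d$x, d$annotation, c("A", "B"), 1)
  t1_swap <- gene_period_tstat(d$x, d$annotation, c("B", "A"), 1)
  expect_equal(unname(t1_swap), unname(-t1))
  ann <- d$annotation
  ga <- ann$pair_id[ann$stratum == "A" & ann$time_period == 1]
  gb <- ann$pair_id[ann$stratum == "B" & ann$time_period == 1]
  for (g in rownames(d$x)[1:10])
    expect_equal(unname(t1[g]), oracle_tstat(d$x[g, ga], d$x[g, gb]),
                 tolerance = 1e-12)
  # identical samples give t = 0; the hand-computed two-pair case
  x2 <- rbind(gX = c(-1, 1, 0, 2))
  colnames(x2) <- paste0("p", 1:4)
  ann2 <- data.frame(pair_id = paste0("p", 1:4),
                     stratum = c("A", "A", "B", "B"), time_period = 1L)
  expect_equal(as.numeric(gene_period_tstat(x2, ann2, c("A", "B"), 1)),
               -1 / sqrt(2))
  # identical samples in both strata give t = 0
  x3 <- rbind(gY = c(1, 2, 1, 2))
  colnames(x3) <- paste0("p", 1:4)
  expect_equal(as.numeric(gene_period_tstat(x3, ann2, c("A", "B"), 1)), 0)
})

test_that("the L_k statistic sums the k largest scores and is monotone", {
  f <- c(3, 2, 1)
  expect_equal(l_k_statistic(f, 2), 5)
  expect_equal(l_k_statistic(f, 1), 3)
  expect_equal(l_k_statistic(f, 3), 6)
  expect_error(l_k_statistic(f, 0), "k must be")
  expect_error(l_k_statistic(f, 4), "k must be")

  set.seed(12)
  g <- abs(rnorm(50))
  lk <- vapply(1:50, function(k) l_k_statistic(g, k), numeric(1))
  expect_true(all(diff(lk) >= 0))           # L_k non-decreasing in k
  expect_true(all(diff(lk / (1:50)) <= 1e-12))  # L_k / k non-increasing
  expect_equal(lk[50], sum(g))
})

test_that("lk_test scores equal the weighted sum of absolute t-statistics", {
  d <- two_strata_data(seed = 15, n_genes = 60)
  res <- lk_test(d$x, d$annotation, c("A", "B"), k_grid = c(5, 20, 60),
                 n_perm = 19, seed = 2)
  f_manual <- rep(0, nrow(d$x))
  for (t in 1:3)
    f_manual <- f_manual +
      (1 / 3) * abs(gene_period_tstat(d$x, d$annotation, c("A", "B"), t))
  expect_equal(unname(res$f_observed), unname(f_manual))
  expect_equal(res$table$l_k[res$table$k == 60], sum(f_manual))
  expect_true(all(diff(res$table$l_k) >= 0))
})

test_that("proportional weights equal period pair counts over their total", {
  cfg <- simulation_config(30, data.frame(
    stratum = rep(c("A", "B"), each = 3),
    time_period = rep(1:3, 2),
    n_pairs = c(4L, 6L, 10L, 4L, 6L, 10L)), seed = 3)
  d <- generate_dataset(cfg)
  res <- lk_test(d$x, d$annotation, c("A", "B"), weights = "proportional",
                 k_grid = 10, n_perm = 9, seed = 1)
  expect_equal(res$weights, c(8, 12, 20) / 40)
})

test_that("exchanging the two strata leaves the p-values unchanged", {
  d <- two_strata_data(seed = 18, n_signal = 15, delta = 0.8, noise_sd = 0.6)
  z_ab <- z_strata_test(d$x, d$annotation, "123", "A", c("A", "B"),
                        n_perm = 49, seed = 6)
  z_ba <- z_strata_test(d$x, d$annotation, "123", "A", c("B", "A"),
                        n_perm = 49, seed = 6)
  expect_equal(z_ab$p_value, z_ba$p_value)
  lk_ab <- lk_test(d$x, d$annotation, c("A", "B"), k_grid = 20,
                   n_perm = 49, seed = 6)
  lk_ba <- lk_test(d$x, d$annotation, c("B", "A"), k_grid = 20,
                   n_perm = 49, seed = 6)
  expect_equal(lk_ab$table$p_value, lk_ba$table$p_value)
})

test_that("with diffuse signal the L_k p-value improves as k grows into the signal", {
  cfg <- simulation_config(300, uniform_design(c("A", "B"), 3, 15),
                           n_signal = 30, signal_labels = "123", delta = 0.6,
                           noise_sd = 1, signal_strata = "A", seed = 22)
  d <- generate_dataset(cfg)
  res <- lk_test(d$x, d$annotation, c("A", "B"), k_grid = c(5, 30, 100),
                 n_perm = 99, seed = 8)
  p <- res$table$p_value
  expect_lte(min(p[-1]), p[1])
})

test_that("single-period scope restricts the comparison to that period", {
  d <- two_strata_data(seed = 25)
  res <- lk_test(d$x, d$annotation, c("A", "B"), k_grid = 10, scope = 2,
                 n_perm = 19, seed = 3)
  expect_identical(res$periods, 2L)
  expect_equal(res$weights, 1)
  t2 <- gene_period_tstat(d$x, d$annotation, c("A", "B"), 2)
  expect_equal(unname(res$f_observed), unname(abs(t2)))
})
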