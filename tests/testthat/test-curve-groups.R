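test_that("curve-group enumeration yields all T! strict orderings", {
  expect_identical(enumerate_curve_groups(3),
                   c("123", "132", "213", "231", "312", "321"))
  expect_length(enumerate_curve_groups(4), 24)
  expect_identical(enumerate_curve_groups(2), c("12", "21"))
  for (tt in 2:6) {
    labs <- enumerate_curve_groups(tt)
    expect_length(labs, factorial(tt))
    expect_false(anyDuplicated(labs) > 0)
  }
  expect_error(enumerate_curve_groups(1), ">= 2")
})

test_that("ordering labels rank period means from farthest to nearest", {
  expect_identical(unname(ordering_label(c(-0.2, 0.0, 0.4))), "123")
  expect_identical(unname(ordering_label(c(0.1, 0.5, 0.3))), "132")
  expect_identical(unname(ordering_label(c(0.1, 0.1, 0.3))), NA_character_)
  m <- rbind(g1 = c(3, 2, 1), g2 = c(1, 3, 2))
  expect_identical(ordering_label(m), c(g1 = "321", g2 = "132"))
})

test_that("negating the data maps each label to its rank complement", {
  set.seed(21)
  for (tt in 2:4) {
    means <- matrix(rnorm(40 * tt), 40, tt)
    lab <- ordering_label(means)
    neg <- ordering_label(-means)
    complement <- vapply(strsplit(lab, ""), function(d)
      paste(tt + 1 - as.integer(d), collapse = ""), character(1))
    expect_identical(neg, complement)
  }
  # the spec of the symmetry on familiar labels
  expect_identical(unname(ordering_label(-c(-0.2, 0.0, 0.4))), "321")
  expect_identical(unname(ordering_label(-c(0.1, 0.5, 0.3))), "312")
})

test_that("welch_p_value matches the hand formula and t.test", {
  # a = (-1, 1), b = (0, 2): t = 1/sqrt(2), Welch-Satterthwaite df = 2
  p_hand <- 2 * pt(1 / sqrt(2), df = 2, lower.tail = FALSE)
  expect_equal(welch_p_value(c(-1, 1), c(0, 2)), p_hand)
  expect_equal(p_hand, 0.5528, tolerance = 1e-3)
  expect_equal(welch_p_value(c(-1, 1), c(0, 2)),
               t.test(c(-1, 1), c(0, 2))$p.value)

  expect_equal(welch_p_value(c(1, 2, 3), c(1, 2, 3)), 1)

  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(sample(2:10, 1))
    b <- rnorm(sample(2:10, 1), mean = runif(1, -2, 2))
    expect_equal(welch_p_value(a, b), t.test(a, b)$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance samples are handled deterministically", {
  expect_equal(welch_p_value(c(0, 0, 0), c(5, 5, 5)), 0)
  expect_equal(welch_p_value(c(2, 2), c(2, 2)), 1)
  expect_error(welch_p_value(1, c(1, 2)), "at least two")
})

test_that("assignment flags membership under inclusion criterion 1", {
  d <- make_dataset(n_genes = 120, pairs_per_period = 12, seed = 4,
                    n_signal = 10, delta = 1.5, noise_sd = 0.5)
  asg <- assign_curve_groups(d$x, d$annotation, "S1",
                             inclusion_criteria("alpha", alpha = 0.01))
  expect_identical(names(asg), c("gene_id", "stratum", "label", "p_value", "member"))
  expect_true(all(asg$member == (asg$p_value < 0.01), na.rm = TRUE))
  expect_false(any(asg$member & is.na(asg$label)))
  # planted monotone-increase genes are recovered with their label
  expect_true(all(asg$label[1:10] == "123"))
  expect_true(all(asg$member[1:10]))
  # a gene can belong to at most one group: labels are single-valued
  expect_true(all(table(asg$gene_id) == 1))
})

test_that("criterion 2 takes the m smallest p-values within each ordering", {
  d <- make_dataset(n_genes = 200, pairs_per_period = 15, seed = 8)
  asg <- assign_curve_groups(d$x, d$annotation, "S1",
                             inclusion_criteria("top_m", m = 5))
  for (lab in unique(na.omit(asg$label))) {
    idx <- which(asg$label == lab)
    members <- asg$gene_id[idx][asg$member[idx]]
    expect_lte(length(members), 5)
    best <- asg$gene_id[idx][order(asg$p_value[idx], asg$gene_id[idx])]
    expect_setequal(members, head(best, min(5, length(idx))))
  }
  # m larger than any ordering count: every labelled gene is a member
  asg_all <- assign_curve_groups(d$x, d$annotation, "S1",
                                 inclusion_criteria("top_m", m = 10000))
  expect_identical(asg_all$member, !is.na(asg_all$label))
})

test_that("membership under alpha is monotone in alpha", {
  d <- make_dataset(n_genes = 150, pairs_per_period = 10, seed = 13)
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  sets <- lapply(alphas, function(a) {
    asg <- assign_curve_groups(d$x, d$annotation, "S1",
                               inclusion_criteria("alpha", alpha = a))
    asg$gene_id[asg$member]
  })
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("vectorized assignment equals the scalar per-gene oracle", {
  for (seed in 1:5) {
    d <- make_dataset(n_genes = 50, pairs_per_period = 10, seed = seed)
    asg <- assign_curve_groups(d$x, d$annotation, "S1",
                               inclusion_criteria("alpha", alpha = 0.01))
    orc <- oracle_assign(d$x, d$annotation, "S1", alpha = 0.01)
    expect_identical(asg$label, orc$label)
    expect_equal(asg$p_value, orc$p_value, tolerance = 1e-12)
    expect_identical(asg$member, orc$member)
  }
})

test_that("period means average the stratum's pairs within each period", {
  x <- rbind(g1 = c(1, 3, 2, 4, 0, 6), g2 = rep(0, 6))
  colnames(x) <- paste0("p", 1:6)
  ann <- data.frame(pair_id = paste0("p", 1:6), stratum = "S1",
                    time_period = c(1L, 1L, 2L, 2L, 3L, 3L))
  pm <- period_means(x, ann, "S1")
  expect_identical(colnames(pm), c("t3", "t2", "t1"))
  expect_equal(unname(pm["g1", ]), c(3, 3, 2))  # farthest -> nearest
  expect_equal(unname(pm["g2", ]), c(0, 0, 0))
  # a single pair per period reproduces the raw values
  ann1 <- ann[c(1, 3, 5), ]
  pm1 <- period_means(x[, ann1$pair_id], ann1, "S1")
  expect_equal(unname(pm1["g1", ]), c(0, 2, 1))
  # a period with no pairs in the stratum is an error naming the period
  ann_bad <- ann
  ann_bad$stratum[ann_bad$time_period == 2] <- "S2"
  expect_error(period_means(x, ann_bad, "S1"), "period 2")
})
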