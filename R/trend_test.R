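#' Curve-group membership counts
#'
#' Counts the member genes of each curve group and their total, the test
#' statistics of the within-stratum trend tests.
#'
#' @param assignments Output of [assign_curve_groups()] for one stratum.
#' @return List with `counts` (named integer vector over all T! labels) and
#'   `total` (their sum).
#' @export
curve_group_counts <- function(assignments) {
  pm <- attr(assignments, "period_means")
  n_periods <- if (!is.null(pm)) ncol(pm) else
    max(nchar(assignments$label), na.rm = TRUE)
  labels_all <- enumerate_curve_groups(n_periods)
  member <- assignments$member & !is.na(assignments$label)
  counts <- tabulate(match(assignments$label[member], labels_all),
                     nbins = length(labels_all))
  counts <- stats::setNames(as.integer(counts), labels_all)
  list(counts = counts, total = sum(counts))
}

#' Permutation test for development over time within one stratum
#'
#' Runs the seven within-stratum hypothesis tests: one global test whose
#' statistic is the total number of genes belonging to any curve group under
#' inclusion criterion 1, and one test per curve group whose statistic is that
#' group's member count. The null distribution comes from randomizing the
#' stratum's pairs between time periods; the curve groups are redefined from
#' scratch for every randomization, and all seven tests share the same null
#' ensemble so their p-values are mutually consistent. P-values are
#' upper-tail (`(K+1)/(N+1)`, more genes than expected by chance) and the
#' expected counts reported are the means of the null counts.
#'
#' @param x Genes x pairs numeric matrix of log2 differences.
#' @param ann Pair annotation.
#' @param stratum Stratum to test.
#' @param alpha Inclusion criterion 1 limit; default 0.01.
#' @param n_perm Number of randomizations N; default 1000.
#' @param seed Master seed; randomization i uses a stream derived from it.
#' @return An object of class `"trend_test_report"`: list with `stratum`,
#'   `alpha`, `n_perm`, `seed` and `report`, a data.frame with one row per
#'   curve group plus a `global` row and columns `label`, `observed`,
#'   `expected`, `p_value`.
#' @export
trend_test_stratum <- function(x, ann, stratum, alpha = 0.01, n_perm = 1000L,
                               seed = 1L) {
  .check_expr_matrix(x)
  .check_annotation(ann, x)
  .check_stratum(ann, stratum)
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  sub <- .stratum_subset(x, ann, stratum)
  labels_all <- enumerate_curve_groups(length(sub$periods))
  obs <- .assign_counts(sub$x, sub$period, sub$periods, alpha, labels_all)
  null_counts <- matrix(0L, nrow = n_perm, ncol = length(labels_all),
                        dimnames = list(NULL, labels_all))
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, i))
    perm <- sample(sub$period)
    null_counts[i, ] <- .assign_counts(sub$x, perm, sub$periods, alpha, labels_all)
  }
  null_total <- rowSums(null_counts)
  obs_total <- sum(obs)
  p_label <- (colSums(sweep(null_counts, 2L, obs, ">=")) + 1) / (n_perm + 1)
  p_global <- (sum(null_total >= obs_total) + 1) / (n_perm + 1)
  report <- data.frame(
    label = c("global", labels_all),
    observed = c(obs_total, as.integer(obs)),
    expected = c(mean(null_total), colMeans(null_counts)),
    p_value = c(p_global, p_label),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(stratum = stratum, alpha = alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), report = report),
            class = "trend_test_report")
}

#' @export
print.trend_test_report <- function(x, ...) {
  cat("Within-stratum trend test, stratum '", x$stratum, "'\n", sep = "")
  cat("  inclusion criterion 1, alpha =", x$alpha,
      "; N =", x$n_perm, "randomizations, seed =", x$seed, "\n")
  df <- x$report
  df$expected <- round(df$expected, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a trend-test report to TSV
#'
#' One row per curve group plus the `global` row, mirroring the report fields.
#'
#' @param result Output of [trend_test_stratum()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trend_report <- function(result, path) {
  df <- result$report
  df$stratum <- result$stratum
  df$alpha <- result$alpha
  df$n_perm <- result$n_perm
  df$seed <- result$seed
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
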