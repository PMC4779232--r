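#' Curve-group variable: per-pair average over a selected gene set
#'
#' Selects the genes of curve group `label` in the selection stratum under
#' inclusion criterion 2 (the `m` genes with smallest Welch p-values among
#' those whose ordering matches the label; all of them when fewer than `m`),
#' then averages the log2 differences over that gene set for every pair in the
#' dataset. The genes are selected from the selection stratum's data only, but
#' the variable is computed for pairs of any stratum, which is what allows
#' strata to be compared on it.
#'
#' @param x Genes x pairs numeric matrix of log2 differences.
#' @param ann Pair annotation.
#' @param label Curve-group label, e.g. `"132"`.
#' @param selection_stratum Stratum whose data select the gene set.
#' @param m Criterion 2 size; default 100.
#' @return An object of class `"curve_group_variable"`: list with `label`,
#'   `selection_stratum`, `genes` (the selected ids) and `z`, a named numeric
#'   vector with one value per pair (the mean of the gene set's values,
#'   divided by the actual gene-set size).
#' @export
build_curve_group_variable <- function(x, ann, label, selection_stratum, m = 100L) {
  .check_expr_matrix(x)
  .check_annotation(ann, x)
  .check_stratum(ann, selection_stratum)
  sub <- .stratum_subset(x, ann, selection_stratum)
  if (!label %in% enumerate_curve_groups(length(sub$periods)))
    stop("'", label, "' is not a valid curve-group label for ",
         length(sub$periods), " time periods", call. = FALSE)
  take <- .select_top_m(sub$x, sub$period, sub$periods, label, m, rownames(x))
  if (!length(take))
    stop("no gene carries ordering ", label, " in stratum '",
         selection_stratum, "'", call. = FALSE)
  genes <- rownames(x)[take]
  z <- colMeans(x[genes, , drop = FALSE])
  structure(list(label = label, selection_stratum = selection_stratum,
                 genes = genes, z = z),
            class = "curve_group_variable")
}

# Welch t-statistic of a per-pair variable between two strata within a scope.
.z_statistic <- function(z, ann, strata, scope) {
  in_scope <- if (identical(scope, "all")) rep(TRUE, nrow(ann)) else
    ann$time_period == scope
  g1 <- ann$pair_id[in_scope & ann$stratum == strata[1L]]
  g2 <- ann$pair_id[in_scope & ann$stratum == strata[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each of the two strata needs at least two pairs in scope ",
         if (identical(scope, "all")) "(all periods)" else
           paste0("(period ", scope, ")"), call. = FALSE)
  a <- z[g1]
  b <- z[g2]
  .welch_vec(mean(a), stats::var(a), length(a),
             mean(b), stats::var(b), length(b))$t
}

#' Permutation test comparing two strata on a curve-group variable
#'
#' Tests whether the curve-group variable differs between two strata, either
#' over all time periods combined or within one period. The observed statistic
#' is the two-sample Welch t-statistic of the variable between the strata's
#' pairs. The null model randomizes pairs between the two strata within each
#' time period; the curve-group gene set is re-selected from the randomized
#' data before every null statistic, so the selection step is part of the
#' test. The p-value is two-sided, `(K+1)/(N+1)` on the absolute statistic.
#'
#' In the rare event that no gene carries the target ordering in a randomized
#' dataset the null statistic is recorded as `NA` and counted as extreme
#' (conservative).
#'
#' @param x Genes x pairs numeric matrix of log2 differences.
#' @param ann Pair annotation.
#' @param label Curve-group label defining the variable.
#' @param selection_stratum Stratum whose data select the gene set.
#' @param strata Character vector of the two strata to compare.
#' @param scope `"all"` for all periods combined, or an integer time period.
#' @param m Criterion 2 size; default 100.
#' @param n_perm Number of randomizations; default 1000.
#' @param seed Master seed.
#' @return A `"permutation_test"` object (see [permutation_p_value()]) with
#'   extra fields `label`, `selection_stratum`, `strata`, `scope`, `genes`
#'   and `seed`.
#' @export
z_strata_test <- function(x, ann, label, selection_stratum, strata,
                          scope = "all", m = 100L, n_perm = 1000L, seed = 1L) {
  .check_expr_matrix(x)
  .check_annotation(ann, x)
  if (length(strata) != 2L) stop("exactly two strata must be given", call. = FALSE)
  for (s in strata) .check_stratum(ann, s)
  v <- build_curve_group_variable(x, ann, label, selection_stratum, m)
  observed <- .z_statistic(v$z, ann, strata, scope)
  gene_ids <- rownames(x)
  nulls <- rep(NA_real_, n_perm)
  for (i in seq_len(n_perm)) {
    ann_i <- permute_stratum_labels(ann, strata, seed = derive_seed(seed, i))
    sub_i <- .stratum_subset(x, ann_i, selection_stratum)
    take <- .select_top_m(sub_i$x, sub_i$period, sub_i$periods, label, m, gene_ids)
    if (!length(take)) next
    z_i <- colMeans(x[take, , drop = FALSE])
    nulls[i] <- .z_statistic(z_i, ann_i, strata, scope)
  }
  res <- permutation_p_value(observed, nulls, direction = "two_sided")
  res$label <- label
  res$selection_stratum <- selection_stratum
  res$strata <- strata
  res$scope <- scope
  res$genes <- v$genes
  res$seed <- as.integer(seed)
  res
}

#' Per-gene Welch t-statistics between two strata within one time period
#'
#' For each gene, the two-sample Welch t-statistic (first stratum minus
#' second) comparing the log2 differences of the two strata's pairs in the
#' given period. Genes with zero variance in both strata get statistic 0 when
#' the means are equal and `Inf` (with matching sign) when they are not; such
#' degenerate genes are flagged in the `"degenerate"` attribute and excluded
#' from downstream top-k sums.
#'
#' @param x Genes x pairs numeric matrix of log2 differences.
#' @param ann Pair annotation.
#' @param strata Character vector of the two strata.
#' @param period Integer time period.
#' @return Named numeric vector of t-statistics, one per gene, with a logical
#'   attribute `"degenerate"`.
#' @export
gene_period_tstat <- function(x, ann, strata, period) {
  .check_expr_matrix(x)
  .check_annotation(ann, x)
  if (length(strata) != 2L) stop("exactly two strata must be given", call. = FALSE)
  for (s in strata) .check_stratum(ann, s)
  g1 <- ann$pair_id[ann$stratum == strata[1L] & ann$time_period == period]
  g2 <- ann$pair_id[ann$stratum == strata[2L] & ann$time_period == period]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each stratum needs at least two pairs in period ", period,
         call. = FALSE)
  .tstat_groups(x[, g1, drop = FALSE], x[, g2, drop = FALSE])
}

# Row-wise Welch t between two column groups.
.tstat_groups <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  w <- .welch_vec(m1, v1, n1, m2, v2, n2)
  t <- w$t
  attr(t, "degenerate") <- !is.finite(t) | (v1 == 0 & v2 == 0)
  t
}

#' Sum of the k largest values
#'
#' The L_k statistic: the sum of the `k` largest entries of the per-gene
#' weighted absolute t-statistic scores.
#'
#' @param f Numeric vector of non-negative per-gene scores.
#' @param k Integer in 1..length(f).
#' @return The sum of the k largest entries.
#' @export
l_k_statistic <- function(f, k) {
  if (length(k) != 1L || !is.numeric(k) || k != round(k) ||
      k < 1L || k > length(f))
    stop("k must be an integer in 1..", length(f), call. = FALSE)
  sum(sort(f, decreasing = TRUE)[seq_len(k)])
}

# Per-gene score F_g = sum_t w_t |T_{g,t}| over the in-scope periods.
# Degenerate genes (infinite t) get NA and are excluded from top-k sums.
.f_scores <- function(x, ann, strata, periods, weights) {
  f <- numeric(nrow(x))
  degenerate <- rep(FALSE, nrow(x))
  for (j in seq_along(periods)) {
    t_gt <- gene_period_tstat(x, ann, strata, periods[j])
    degenerate <- degenerate | attr(t_gt, "degenerate")
    f <- f + weights[j] * abs(t_gt)
  }
  f[degenerate] <- NA_real_
  names(f) <- rownames(x)
  attr(f, "degenerate") <- degenerate
  f
}

# Resolve the weight vector for the in-scope periods.
.resolve_weights <- function(weights, periods, ann, strata) {
  if (is.character(weights)) {
    weights <- match.arg(weights, c("equal", "proportional"))
    if (weights == "equal") {
      w <- rep(1 / length(periods), length(periods))
    } else {
      n_t <- vapply(periods, function(t)
        sum(ann$stratum %in% strata & ann$time_period == t), numeric(1L))
      w <- n_t / sum(n_t)
    }
  } else {
    if (length(weights) != length(periods) || any(weights < 0) ||
        sum(weights) <= 0)
      stop("custom weights must be non-negative, one per in-scope period",
           call. = FALSE)
    w <- weights / sum(weights)
  }
  w
}

#' Permutation test comparing two strata with the L_k statistic
#'
#' A curve-group-free comparison of two strata. Per gene and in-scope time
#' period the Welch t-statistic between the strata is computed; the per-gene
#' score is the weighted sum of absolute t-statistics over periods, and the
#' test statistic L_k is the sum of the k largest scores. The null model
#' randomizes pairs between the two strata within each period and recomputes
#' the t-statistics, scores and top-k selection for every randomization.
#' Upper-tail p-values `(K+1)/(N+1)` are reported for each k of a grid.
#'
#' @param x Genes x pairs numeric matrix of log2 differences.
#' @param ann Pair annotation.
#' @param strata Character vector of the two strata.
#' @param weights `"equal"` (1/T per period), `"proportional"` (period pair
#'   counts over the two strata), or a numeric vector over the in-scope
#'   periods (normalized to sum to 1). With a single-period scope the weight
#'   is 1.
#' @param k_grid Integer vector of k values; clipped to the number of genes
#'   with a finite score.
#' @param scope `"all"` or an integer time period.
#' @param n_perm Number of randomizations; default 1000.
#' @param seed Master seed.
#' @return An object of class `"lk_test_result"`: list with `table` (a
#'   data.frame with columns `k`, `l_k`, `p_value`), `f_observed` (the
#'   per-gene scores on the real labels, `NA` for degenerate genes),
#'   `weights`, `periods`, `degenerate_genes`, `strata`, `scope`, `n_perm`,
#'   `seed`.
#' @export
lk_test <- function(x, ann, strata, weights = "equal",
                    k_grid = c(10L, 50L, 100L, 200L, 500L, 1000L),
                    scope = "all", n_perm = 1000L, seed = 1L) {
  .check_expr_matrix(x)
  .check_annotation(ann, x)
  if (length(strata) != 2L) stop("exactly two strata must be given", call. = FALSE)
  for (s in strata) .check_stratum(ann, s)
  periods <- if (identical(scope, "all"))
    sort(unique(ann$time_period[ann$stratum %in% strata])) else as.integer(scope)
  w <- .resolve_weights(weights, periods, ann, strata)
  f_obs <- .f_scores(x, ann, strata, periods, w)
  pool <- sum(!is.na(f_obs))
  k_grid <- sort(unique(pmin(as.integer(k_grid), pool)))
  k_grid <- k_grid[k_grid >= 1L]
  if (!length(k_grid)) stop("k_grid is empty after clipping", call. = FALSE)
  obs <- vapply(k_grid, function(k) l_k_statistic(f_obs[!is.na(f_obs)], k),
                numeric(1L))
  exceed <- integer(length(k_grid))
  for (i in seq_len(n_perm)) {
    ann_i <- permute_stratum_labels(ann, strata, seed = derive_seed(seed, i))
    f_i <- .f_scores(x, ann_i, strata, periods, w)
    f_i <- f_i[!is.na(f_i)]
    sorted <- sort(f_i, decreasing = TRUE)
    cum <- cumsum(sorted)
    k_eff <- pmin(k_grid, length(sorted))
    exceed <- exceed + (cum[k_eff] >= obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  structure(list(table = data.frame(k = k_grid, l_k = obs, p_value = p,
                                    row.names = NULL),
                 f_observed = f_obs, weights = w, periods = periods,
                 degenerate_genes = names(f_obs)[is.na(f_obs)],
                 strata = strata, scope = scope,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "lk_test_result")
}

#' @export
print.lk_test_result <- function(x, ...) {
  cat("L_k strata comparison: '", x$strata[1L], "' vs '", x$strata[2L],
      "', scope ", if (identical(x$scope, "all")) "all periods" else
        paste("period", x$scope), "\n", sep = "")
  cat("  weights:", paste(format(x$weights, digits = 3), collapse = " "),
      "over periods", paste(x$periods, collapse = " "), "\n")
  if (length(x$degenerate_genes))
    cat("  degenerate genes excluded:", length(x$degenerate_genes), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
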