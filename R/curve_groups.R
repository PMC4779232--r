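#' Per-period mean log2 differences within a stratum
#'
#' For one stratum, averages the log2 case-minus-control differences over the
#' stratum's case-control pairs within each time period. Columns are ordered
#' from the period farthest from diagnosis to the period nearest diagnosis
#' (period 1), which is the order in which curve-group labels are read.
#'
#' @param x Genes x pairs numeric matrix of log2 differences.
#' @param ann Pair annotation (columns `pair_id`, `stratum`, `time_period`).
#' @param stratum Stratum label.
#' @return Genes x T matrix of means, columns named `t<T>`, ..., `t1`.
#' @export
period_means <- function(x, ann, stratum) {
  .check_expr_matrix(x)
  .check_annotation(ann, x)
  .check_stratum(ann, stratum)
  sub <- .stratum_subset(x, ann, stratum)
  st <- .period_stats(sub$x, sub$period, sub$periods, min_pairs = 1L,
                      stratum = stratum)
  st$mean
}

# Subset the matrix to one stratum's pairs; returns values + period vector.
.stratum_subset <- function(x, ann, stratum) {
  ann_s <- ann[ann$stratum == stratum, , drop = FALSE]
  keep <- intersect(colnames(x), ann_s$pair_id)
  period <- ann_s$time_period[match(keep, ann_s$pair_id)]
  periods <- sort(unique(ann$time_period))
  list(x = x[, keep, drop = FALSE], period = period, periods = periods)
}

# Per-gene per-period means, variances and counts via one matrix product.
# Columns ordered farthest -> nearest period (decreasing period number).
.period_stats <- function(xs, period, periods, min_pairs = 2L, stratum = NULL) {
  per_desc <- sort(periods, decreasing = TRUE)
  D <- outer(period, per_desc, "==") * 1
  n <- colSums(D)
  if (any(n < min_pairs)) {
    bad <- per_desc[which(n < min_pairs)[1L]]
    stop("time period ", bad,
         if (!is.null(stratum)) paste0(" in stratum '", stratum, "'"),
         " has fewer than ", min_pairs, " pair(s)", call. = FALSE)
  }
  S <- xs %*% D
  Q <- (xs * xs) %*% D
  M <- sweep(S, 2L, n, "/")
  V <- sweep(Q - sweep(M * M, 2L, n, "*"), 2L, pmax(n - 1, 1), "/")
  V <- pmax(V, 0) # guard tiny negative values from cancellation
  dimnames(M) <- dimnames(V) <- list(rownames(xs), paste0("t", per_desc))
  list(mean = M, var = V, n = n, periods_desc = per_desc)
}

#' Curve-group label from the ordering of period means
#'
#' The label is a string of T digits read from the farthest period (left) to
#' the period nearest diagnosis (right); the digit is the rank of that
#' period's mean among the T means (1 = smallest). `"123"` therefore denotes a
#' monotone increase in differential expression toward diagnosis. No label is
#' assigned when any two means are exactly equal, since curve groups are
#' defined only for strict orderings.
#'
#' @param means Numeric vector of T period means ordered farthest to nearest,
#'   or a genes x T matrix of such rows.
#' @return Character vector of labels, `NA` where means are tied.
#' @export
ordering_label <- function(means) {
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  if (ncol(means) < 2L) stop("at least two time periods required", call. = FALSE)
  r <- .rank_rows_strict(means)
  out <- rep(NA_character_, nrow(means))
  ok <- !r$tie
  if (any(ok))
    out[ok] <- do.call(paste0, as.data.frame(r$rank[ok, , drop = FALSE]))
  names(out) <- rownames(means)
  out
}

# Vectorized strict ranking of matrix rows; flags rows with exact ties.
.rank_rows_strict <- function(M) {
  Tn <- ncol(M)
  G <- nrow(M)
  R <- matrix(1L, G, Tn)
  tie <- rep(FALSE, G)
  for (a in seq_len(Tn - 1L)) {
    for (b in seq.int(a + 1L, Tn)) {
      gt <- M[, a] > M[, b]
      eq <- M[, a] == M[, b]
      R[, a] <- R[, a] + gt
      R[, b] <- R[, b] + (!gt & !eq)
      tie <- tie | eq
    }
  }
  list(rank = R, tie = tie)
}

#' Enumerate all possible curve-group labels for T time periods
#'
#' There are T! strict orderings: 6 labels for three periods
#' (123, 132, 213, 231, 312, 321) and 24 for four.
#'
#' @param n_periods Integer number of time periods, at least 2 (at most 9, so
#'   that single-digit labels are unambiguous).
#' @return Character vector of T! labels in lexicographic order.
#' @export
enumerate_curve_groups <- function(n_periods) {
  if (!is.numeric(n_periods) || length(n_periods) != 1L ||
      n_periods != round(n_periods) || n_periods < 2)
    stop("n_periods must be an integer >= 2", call. = FALSE)
  if (n_periods > 9)
    stop("single-digit labels support at most 9 time periods", call. = FALSE)
  perms <- .permutations(as.integer(n_periods))
  sort(do.call(paste0, as.data.frame(perms)))
}

#' Two-sided Welch two-sample t-test p-value
#'
#' Welch's unequal-variance t-statistic with Welch-Satterthwaite degrees of
#' freedom. The degenerate zero-variance limit is handled deterministically:
#' both samples constant with equal means gives p = 1, with unequal means
#' p = 0.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
welch_p_value <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must contain at least two values", call. = FALSE)
  w <- .welch_vec(mean(a), stats::var(a), length(a),
                  mean(b), stats::var(b), length(b))
  w$p
}

# Vectorized Welch machinery from sufficient statistics.
.welch_vec <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  deg <- se2 == 0
  if (any(deg)) {
    d_eq <- deg & (m1 == m2)
    d_ne <- deg & (m1 != m2)
    t[d_eq] <- 0
    p[d_eq] <- 1
    t[d_ne] <- sign((m1 - m2)[d_ne]) * Inf
    p[d_ne] <- 0
    df[deg] <- NA_real_
  }
  list(t = t, df = df, p = p)
}

#' Inclusion criteria for curve-group membership
#'
#' Criterion 1 (`mode = "alpha"`) admits a gene to its curve group when the
#' Welch p-value comparing the smallest-mean and largest-mean periods is below
#' `alpha`. Criterion 2 (`mode = "top_m"`) admits, within each curve group,
#' the `m` genes with the smallest p-values among the genes whose ordering
#' matches that group (all of them when fewer than `m` carry the ordering).
#'
#' @param mode `"alpha"` or `"top_m"`.
#' @param alpha Significance limit in (0, 1); default 0.01.
#' @param m Number of genes per group under criterion 2; default 100.
#' @return An object of class `"inclusion_criteria"`.
#' @export
inclusion_criteria <- function(mode = c("alpha", "top_m"), alpha = 0.01, m = 100L) {
  mode <- match.arg(mode)
  if (mode == "alpha" && (!is.numeric(alpha) || alpha <= 0 || alpha >= 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (mode == "top_m" && (!is.numeric(m) || m < 1 || m != round(m)))
    stop("m must be a positive integer", call. = FALSE)
  structure(list(mode = mode, alpha = alpha, m = as.integer(m)),
            class = "inclusion_criteria")
}

#' Assign genes to curve groups within a stratum
#'
#' For every gene: computes the per-period means over the stratum's pairs,
#' derives the curve-group label from their strict ordering, and tests whether
#' the smallest and largest period means differ with a two-sided Welch t-test
#' on the corresponding pair values. Membership is then flagged according to
#' the inclusion criteria. A gene with exactly tied period means receives no
#' label, no p-value and no membership.
#'
#' @param x Genes x pairs numeric matrix of log2 differences.
#' @param ann Pair annotation.
#' @param stratum Stratum whose pairs define the assignment.
#' @param criteria An [inclusion_criteria()] object.
#' @return Data.frame with columns `gene_id`, `stratum`, `label`, `p_value`,
#'   `member`, plus the per-period means as attribute `"period_means"`.
#' @export
assign_curve_groups <- function(x, ann, stratum, criteria = inclusion_criteria()) {
  .check_expr_matrix(x)
  .check_annotation(ann, x)
  .check_stratum(ann, stratum)
  if (!inherits(criteria, "inclusion_criteria"))
    stop("criteria must be built with inclusion_criteria()", call. = FALSE)
  sub <- .stratum_subset(x, ann, stratum)
  core <- .assign_core(sub$x, sub$period, sub$periods, stratum = stratum)
  member <- .membership(core$label, core$p, criteria, rownames(x))
  out <- data.frame(gene_id = rownames(x), stratum = stratum,
                    label = core$label, p_value = core$p, member = member,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "period_means") <- core$means
  attr(out, "criteria") <- criteria
  out
}

# Label + Welch p-value per gene from a stratum's submatrix. The min- and
# max-mean periods are chosen per gene; their pair values feed the Welch test.
.assign_core <- function(xs, period, periods, stratum = NULL) {
  st <- .period_stats(xs, period, periods, min_pairs = 2L, stratum = stratum)
  r <- .rank_rows_strict(st$mean)
  G <- nrow(xs)
  label <- rep(NA_character_, G)
  if (any(!r$tie))
    label[!r$tie] <- do.call(paste0, as.data.frame(r$rank[!r$tie, , drop = FALSE]))
  jmin <- max.col(-st$mean, ties.method = "first")
  jmax <- max.col(st$mean, ties.method = "first")
  idx <- seq_len(G)
  w <- .welch_vec(st$mean[cbind(idx, jmin)], st$var[cbind(idx, jmin)], st$n[jmin],
                  st$mean[cbind(idx, jmax)], st$var[cbind(idx, jmax)], st$n[jmax])
  p <- w$p
  p[r$tie] <- NA_real_
  list(label = label, p = p, means = st$mean)
}

# Membership flags under either inclusion criterion.
.membership <- function(label, p, criteria, gene_ids) {
  member <- rep(FALSE, length(label))
  ok <- !is.na(label) & !is.na(p)
  if (criteria$mode == "alpha") {
    member[ok] <- p[ok] < criteria$alpha
  } else {
    for (lab in unique(label[ok])) {
      idx <- which(ok & label == lab)
      take <- idx[order(p[idx], gene_ids[idx])]
      member[utils::head(take, criteria$m)] <- TRUE
    }
  }
  member
}

# Member counts per label in one pass; used inside permutation loops.
.assign_counts <- function(xs, period, periods, alpha, labels_all) {
  core <- .assign_core(xs, period, periods)
  member <- !is.na(core$label) & !is.na(core$p) & core$p < alpha
  counts <- tabulate(match(core$label[member], labels_all),
                     nbins = length(labels_all))
  names(counts) <- labels_all
  counts
}

# Indices (into rownames of xs) of the top-m genes of one curve group under
# inclusion criterion 2; used inside permutation loops of the Z test.
.select_top_m <- function(xs, period, periods, label, m, gene_ids) {
  core <- .assign_core(xs, period, periods)
  idx <- which(!is.na(core$label) & core$label == label & !is.na(core$p))
  if (!length(idx)) return(integer(0L))
  take <- idx[order(core$p[idx], gene_ids[idx])]
  utils::head(take, m)
}

#' Write a curve-group assignment table to TSV
#'
#' @param assignments Output of [assign_curve_groups()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(assignments, path) {
  out <- assignments
  out$member <- as.integer(out$member)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
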