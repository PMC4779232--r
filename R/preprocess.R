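#' Paired log2 expression differences
#'
#' Computes, per gene and matched case-control pair, the difference
#' `log2(case) - log2(control)` between the intensity of the case sample and
#' its matched control. The pairing keeps each case with its own control, so
#' technical batch effects shared within a pair cancel by construction.
#'
#' @param cases,controls Numeric matrices of strictly positive intensities on
#'   the original scale, features in rows (identical `rownames` in both),
#'   samples in columns.
#' @param pairing Data.frame with columns `case_sample`, `control_sample`,
#'   `pair_id`: one row per matched pair, referencing column names of `cases`
#'   and `controls` respectively.
#' @return Numeric matrix of log2 differences, rows = features, columns =
#'   `pair_id`s in pairing order.
#' @export
compute_log2_differences <- function(cases, controls, pairing) {
  if (!identical(rownames(cases), rownames(controls)))
    stop("cases and controls must share identical feature ids in the same order",
         call. = FALSE)
  need <- c("case_sample", "control_sample", "pair_id")
  if (!is.data.frame(pairing) || !all(need %in% names(pairing)))
    stop("pairing must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad_case <- setdiff(pairing$case_sample, colnames(cases))
  if (length(bad_case))
    stop("unknown case sample in pairing: ", bad_case[1L], call. = FALSE)
  bad_ctrl <- setdiff(pairing$control_sample, colnames(controls))
  if (length(bad_ctrl))
    stop("unknown control sample in pairing: ", bad_ctrl[1L], call. = FALSE)
  if (anyDuplicated(pairing$pair_id))
    stop("duplicate pair_id in pairing: ",
         pairing$pair_id[duplicated(pairing$pair_id)][1L], call. = FALSE)
  if (any(cases <= 0) || any(controls <= 0))
    stop("intensities must be strictly positive (log2 undefined otherwise)",
         call. = FALSE)
  x <- log2(cases[, pairing$case_sample, drop = FALSE]) -
    log2(controls[, pairing$control_sample, drop = FALSE])
  colnames(x) <- as.character(pairing$pair_id)
  x
}

#' Quantile normalization on the original scale
#'
#' Forces every column (sample) to the same empirical distribution: the
#' reference vector of row-wise means of the column-sorted matrix. Within each
#' column the rank order is preserved. Tied values within a column all receive
#' the mean of the reference values over their rank span, so the result is
#' deterministic and idempotent for tie-free input.
#'
#' @param m Numeric matrix with no missing values, features x samples.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) == 0L || ncol(m) == 0L)
    stop("quantile_normalize requires a non-empty numeric matrix", call. = FALSE)
  if (anyNA(m))
    stop("quantile_normalize does not accept missing values", call. = FALSE)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    assigned <- numeric(length(v))
    assigned[order(v)] <- ref
    # ties within the column share the mean reference value over their ranks
    out[, j] <- stats::ave(assigned, match(v, v), FUN = mean)
  }
  out
}

#' Filter features by detection presence
#'
#' Retains a feature when it is detected in at least
#' `ceiling(min_fraction * n_samples)` samples. With 882 samples and
#' `min_fraction = 0.01` the required count is 9.
#'
#' @param detected Logical (or 0/1) matrix, features x samples.
#' @param min_fraction Required detection fraction in (0, 1].
#' @return Character vector of retained feature ids, in input order.
#' @export
filter_by_presence <- function(detected, min_fraction) {
  if (!is.matrix(detected))
    stop("detected must be a features x samples matrix", call. = FALSE)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  threshold <- presence_threshold(ncol(detected), min_fraction)
  keep <- rowSums(detected != 0) >= threshold
  rownames(detected)[keep]
}

#' Required detection count for a presence fraction
#'
#' @param n_samples Number of samples.
#' @param min_fraction Required detection fraction in (0, 1].
#' @return Integer minimum number of samples a feature must be detected in.
#' @export
presence_threshold <- function(n_samples, min_fraction) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  as.integer(ceiling(min_fraction * n_samples))
}

#' Collapse probe-level rows to one row per gene
#'
#' When a gene is represented by several probes, the probe with the highest
#' mean intensity across all samples is kept (ties broken by lexicographically
#' smallest probe id). Probes without a gene mapping are dropped.
#'
#' @param m Numeric matrix, probes x samples.
#' @param probe_to_gene Data.frame with columns `probe_id`, `gene_id`, each
#'   probe mapping to at most one gene.
#' @return Matrix with one row per mapped gene, rownames = gene ids, rows
#'   ordered by the retained probe's position in `m`.
#' @export
collapse_probes_to_genes <- function(m, probe_to_gene) {
  if (!is.data.frame(probe_to_gene) ||
      !all(c("probe_id", "gene_id") %in% names(probe_to_gene)) ||
      nrow(probe_to_gene) == 0L)
    stop("probe_to_gene must be a non-empty data.frame with columns probe_id, gene_id",
         call. = FALSE)
  if (anyDuplicated(probe_to_gene$probe_id))
    stop("a probe maps to more than one gene: ",
         probe_to_gene$probe_id[duplicated(probe_to_gene$probe_id)][1L],
         call. = FALSE)
  map <- probe_to_gene[probe_to_gene$probe_id %in% rownames(m), , drop = FALSE]
  if (nrow(map) == 0L)
    stop("no probe in the mapping matches a row of the matrix", call. = FALSE)
  probe_mean <- rowMeans(m)[map$probe_id]
  ord <- order(map$gene_id, -probe_mean, map$probe_id)
  map <- map[ord, , drop = FALSE]
  keep <- map[!duplicated(map$gene_id), , drop = FALSE]
  row_pos <- match(keep$probe_id, rownames(m))
  keep <- keep[order(row_pos), , drop = FALSE]
  out <- m[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  out
}
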