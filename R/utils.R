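#' Derive a reproducible sub-seed from a master seed
#'
#' Permutation loops and simulation replicates each use their own seed derived
#' deterministically from one master seed, so that results are independent of
#' execution order and extending the number of randomizations extends rather
#' than reshuffles the null ensemble.
#'
#' @param seed Integer master seed.
#' @param i Positive integer stream index.
#' @return An integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @export
derive_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i), length(i) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(as.double(seed)) %% m)
  as.integer((s * 48271 + as.double(i) * 104729 + 1) %% m)
}

# All strict-order permutations of 1..n, one per row, rows in lexicographic order.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Validate a genes x pairs numeric matrix of log2 differences.
.check_expr_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene ids as rownames and pair ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene id: ", rownames(x)[duplicated(rownames(x))][1L], call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate pair id: ", colnames(x)[duplicated(colnames(x))][1L], call. = FALSE)
  if (!all(is.finite(x)))
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  invisible(x)
}

# Validate a pair annotation data.frame against an expression matrix.
.check_annotation <- function(ann, x = NULL) {
  need <- c("pair_id", "stratum", "time_period")
  if (!is.data.frame(ann) || !all(need %in% names(ann)))
    stop("pair annotation must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$pair_id))
    stop("duplicate pair_id in annotation: ",
         ann$pair_id[duplicated(ann$pair_id)][1L], call. = FALSE)
  tp <- ann$time_period
  if (!is.numeric(tp) || any(tp < 1) || any(tp != round(tp)))
    stop("time_period must contain integers >= 1 (1 = period nearest diagnosis)",
         call. = FALSE)
  if (any(!nzchar(as.character(ann$stratum))))
    stop("stratum labels must be non-empty", call. = FALSE)
  if (!is.null(x)) {
    missing <- setdiff(colnames(x), ann$pair_id)
    if (length(missing))
      stop("pair id(s) in matrix absent from annotation: ",
           paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  }
  invisible(ann)
}

.check_stratum <- function(ann, stratum) {
  if (!stratum %in% ann$stratum)
    stop("unknown stratum: '", stratum, "'", call. = FALSE)
  invisible(stratum)
}
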