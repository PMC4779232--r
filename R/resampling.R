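#' Randomize time-period labels within one stratum
#'
#' Uniformly permutes the time-period labels among the case-control pairs of
#' the given stratum, leaving every other stratum untouched. Each pair's gene
#' expression vector is untouched, so the inter-gene correlation structure is
#' preserved; only the pairing of expression vectors with time periods is
#' broken. Per-period pair counts are preserved exactly (sampling without
#' replacement), matching a design with fixed numbers of pairs per period.
#'
#' @param ann Pair annotation.
#' @param stratum Stratum whose labels are permuted.
#' @param seed Optional integer; when given, the permutation is drawn from a
#'   fresh RNG stream seeded with it (reproducible), otherwise from the
#'   current RNG state.
#' @return A pair annotation with permuted `time_period` in the stratum.
#' @export
permute_time_labels <- function(ann, stratum, seed = NULL) {
  .check_annotation(ann)
  .check_stratum(ann, stratum)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(ann$stratum == stratum)
  out <- ann
  # index-based shuffle: sample(x) on a length-1 vector would draw from 1:x
  out$time_period[idx] <- ann$time_period[idx][sample.int(length(idx))]
  out
}

#' Randomize stratum labels between two strata within each time period
#'
#' Within every time period separately, uniformly permutes the stratum labels
#' among the pairs belonging to either of the two strata. Per-period
#' per-stratum counts are preserved; time periods never change; pairs in other
#' strata are untouched.
#'
#' @param ann Pair annotation.
#' @param strata Character vector of the two stratum labels.
#' @param seed Optional integer seed, as in [permute_time_labels()].
#' @return A pair annotation with permuted `stratum` labels.
#' @export
permute_stratum_labels <- function(ann, strata, seed = NULL) {
  .check_annotation(ann)
  if (length(strata) != 2L)
    stop("exactly two strata must be given", call. = FALSE)
  for (s in strata) .check_stratum(ann, s)
  if (!is.null(seed)) set.seed(seed)
  out <- ann
  in_pair <- ann$stratum %in% strata
  for (t in sort(unique(ann$time_period[in_pair]))) {
    idx <- which(in_pair & ann$time_period == t)
    if (length(idx) > 1L)
      out$stratum[idx] <- ann$stratum[idx][sample.int(length(idx))]
  }
  out
}

#' Permutation p-value from an observed statistic and its null sample
#'
#' The p-value is `(K + 1) / (N + 1)`, where `K` counts the null statistics at
#' least as extreme as the observed one out of `N` randomizations. Ties with
#' the observed statistic count as extreme, making the test conservative; the
#' smallest attainable p-value is `1 / (N + 1)`.
#'
#' @param observed Observed test statistic.
#' @param nulls Numeric vector of N null statistics. `NA` entries (degenerate
#'   randomizations) are counted as extreme, again conservatively.
#' @param direction `"upper"` counts `null >= observed`; `"two_sided"` counts
#'   `|null| >= |observed|`.
#' @return An object of class `"permutation_test"`: a list with elements
#'   `observed`, `null_statistics`, `K`, `N`, `p_value`, `direction`.
#' @export
permutation_p_value <- function(observed, nulls, direction = c("upper", "two_sided")) {
  direction <- match.arg(direction)
  if (length(nulls) < 1L) stop("nulls must contain at least one value", call. = FALSE)
  if (!is.finite(observed)) stop("observed statistic must be finite", call. = FALSE)
  extreme <- switch(direction,
                    upper = nulls >= observed,
                    two_sided = abs(nulls) >= abs(observed))
  K <- sum(extreme, na.rm = TRUE) + sum(is.na(extreme))
  N <- length(nulls)
  structure(list(observed = observed, null_statistics = nulls,
                 K = as.integer(K), N = as.integer(N),
                 p_value = (K + 1) / (N + 1), direction = direction),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Permutation test (", x$direction, ")\n", sep = "")
  cat("  observed statistic:", format(x$observed), "\n")
  cat("  randomizations N =", x$N, ", extreme K =", x$K, "\n")
  cat("  p-value (K+1)/(N+1) =", format(x$p_value), "\n")
  invisible(x)
}
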