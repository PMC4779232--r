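#' Read a genes x pairs expression difference matrix from TSV
#'
#' The expected layout is one header row (`gene_id` followed by the pair ids),
#' then one row per gene: the gene id followed by the log2 case-minus-control
#' difference for each pair. Every cell must be numeric; missing values are
#' rejected at load time because all downstream statistics assume a complete
#' matrix.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene ids as rownames and pair ids as colnames,
#'   in file order.
#' @seealso [write_expression_matrix()] for the inverse operation.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expected a gene id column plus at least one pair column in ", path,
         call. = FALSE)
  gene_ids <- raw[[1L]]
  pair_ids <- colnames(raw)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in ", path, ": ",
         gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  if (anyDuplicated(pair_ids))
    stop("duplicate pair id in ", path, ": ",
         pair_ids[duplicated(pair_ids)][1L], call. = FALSE)
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(pair_ids),
                 dimnames = list(gene_ids, pair_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or missing cell in ", path, " at gene '",
         gene_ids[bad[1L, 1L]], "' (row ", bad[1L, 1L], "), pair '",
         pair_ids[bad[1L, 2L]], "' (column ", bad[1L, 2L] + 1L, ")",
         call. = FALSE)
  }
  vals
}

#' Write an expression matrix to TSV at full double precision
#'
#' Values are written with `%.17g` so that a read/write cycle reproduces the
#' doubles exactly and repeated write/read cycles are byte-identical.
#'
#' @param x Numeric matrix with gene rownames and pair colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  .check_expr_matrix(x)
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a pair annotation table from TSV
#'
#' Expects columns `pair_id`, `stratum` and `time_period`. Time periods are
#' coded as integers with 1 the period nearest diagnosis and larger values
#' further back in time.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with character `pair_id` and `stratum` and integer
#'   `time_period`.
#' @export
read_pair_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("pair_id", "stratum", "time_period")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop("annotation ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ann <- ann[need]
  ann$pair_id <- as.character(ann$pair_id)
  ann$stratum <- as.character(ann$stratum)
  tp <- suppressWarnings(as.numeric(ann$time_period))
  if (any(!is.finite(tp)))
    stop("non-numeric time_period at row ", which(!is.finite(tp))[1L],
         " of ", path, call. = FALSE)
  ann$time_period <- as.integer(tp)
  .check_annotation(ann)
  ann
}

#' Write a pair annotation table to TSV
#'
#' @param ann Data.frame with columns `pair_id`, `stratum`, `time_period`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pair_annotation <- function(ann, path) {
  .check_annotation(ann)
  utils::write.table(ann[c("pair_id", "stratum", "time_period")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features x samples detection (presence) matrix from TSV
#'
#' Same layout as the expression matrix; cells must be 0 or 1 (1 = detected).
#'
#' @param path Path to a tab-separated file.
#' @return A logical matrix.
#' @export
read_detection_matrix <- function(path) {
  m <- read_expression_matrix(path)
  if (!all(m %in% c(0, 1)))
    stop("detection matrix must contain only 0/1 values: ", path, call. = FALSE)
  m > 0
}
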