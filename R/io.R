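#' Construct an expression dataset
#'
#' A set of N time-course profiles sharing the same m time points and
#' sampling interval. Rows are genes, columns time points.
#'
#' @param matrix Numeric N x m matrix, no missing values.
#' @param gene_ids Character vector of N unique identifiers; defaults to
#'   rownames or `gene_1..gene_N`.
#' @param delta Sampling interval (> 0).
#' @param excluded data.frame of rows dropped at load time (columns
#'   `gene_id`, `reason`); empty by default.
#' @return An object of class `tc_dataset`.
#' @export
tc_dataset <- function(matrix, gene_ids = NULL, delta = 1,
                       excluded = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(gene_ids)) {
    gene_ids <- rownames(matrix)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(matrix)))
  }
  stopifnot(length(gene_ids) == nrow(matrix), delta > 0)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    stop("expression matrix contains non-finite values; exclude such rows",
         call. = FALSE)
  }
  if (is.null(excluded)) {
    excluded <- data.frame(gene_id = character(), reason = character())
  }
  rownames(matrix) <- gene_ids
  structure(list(gene_ids = gene_ids, matrix = matrix, delta = delta,
                 excluded = excluded),
            class = "tc_dataset")
}

#' @export
print.tc_dataset <- function(x, ...) {
  cat(sprintf("<tc_dataset> %d genes x %d time points, delta = %g",
              nrow(x$matrix), ncol(x$matrix), x$delta))
  if (nrow(x$excluded) > 0) {
    cat(sprintf(" (%d rows excluded at load)", nrow(x$excluded)))
  }
  cat("\n")
  invisible(x)
}

# Coerce matrices, lists of profiles, or tc_datasets to tc_dataset.
as_tc_dataset <- function(x, delta = 1) {
  if (inherits(x, "tc_dataset")) return(x)
  if (is.matrix(x) || is.data.frame(x)) {
    return(tc_dataset(as.matrix(x), delta = delta))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "tc_profile"))) {
    mat <- do.call(rbind, lapply(x, `[[`, "values"))
    return(tc_dataset(mat, gene_ids = vapply(x, `[[`, character(1), "gene_id"),
                      delta = x[[1]]$delta))
  }
  if (is.numeric(x)) return(tc_dataset(matrix(x, nrow = 1), delta = delta))
  stop("cannot interpret input as an expression dataset", call. = FALSE)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects one header line of time labels, a first column of gene
#' identifiers and numeric time-point columns. Any row containing an
#' empty or unparseable cell is excluded wholesale and recorded with a
#' reason (the standard preprocessing rule for public cell-cycle
#' matrices, where imputation is deliberately avoided); ragged rows are a
#' hard error. Duplicate gene identifiers are rejected.
#'
#' @param path Path to the TSV file.
#' @param delta Sampling interval to attach (the header's time labels are
#'   not parsed; public matrices carry them inconsistently).
#' @return A [tc_dataset()]; dropped rows are listed in `$excluded`.
#' @export
read_expression_tsv <- function(path, delta = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty dataset: ", path, call. = FALSE)
  # sentinel keeps trailing empty cells (a trailing missing value must
  # count as a field, not shorten the row)
  split <- lapply(strsplit(paste0(lines, "\tEOL"), "\t", fixed = TRUE),
                  function(f) f[-length(f)])
  ncols <- length(split[[1]])
  body <- split[-1]
  widths <- lengths(body)
  if (any(widths != ncols)) {
    stop("malformed file: row(s) ", paste(which(widths != ncols), collapse = ", "),
         " have ", paste(unique(widths[widths != ncols]), collapse = "/"),
         " fields, header has ", ncols, call. = FALSE)
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- lapply(body, function(f) suppressWarnings(as.numeric(f[-1])))
  ok <- vapply(vals, function(v) all(is.finite(v)), logical(1))
  excluded <- data.frame(gene_id = ids[!ok],
                         reason = rep("missing or non-numeric value",
                                      sum(!ok)))
  if (!any(ok)) stop("empty dataset after exclusions: ", path, call. = FALSE)
  mat <- do.call(rbind, vals[ok])
  tc_dataset(mat, gene_ids = ids[ok], delta = delta, excluded = excluded)
}

#' Write an expression dataset as tab-separated text
#'
#' Inverse of [read_expression_tsv()]: a `gene_id` header column followed
#' by time labels `t1..tm`. Round-trips exactly (values written with full
#' precision).
#'
#' @param dataset A [tc_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "tc_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids,
                   format(dataset$matrix, digits = 17, trim = TRUE,
                          scientific = FALSE))
  names(df) <- c("gene_id", paste0("t", seq_len(ncol(dataset$matrix))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
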