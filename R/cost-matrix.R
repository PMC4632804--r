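#' Validate an unbalanced-assignment cost matrix
#'
#' An instance is an m x n matrix of nonnegative costs with strictly fewer
#' individuals (rows) than jobs (columns). The strand pipeline additionally
#' requires integer costs, because costs are encoded as strand *lengths*;
#' the brute-force oracle accepts real-valued costs.
#'
#' @param x a numeric matrix or data frame
#' @param integer_costs require integer entries (the strand-encoding mode)
#' @return a validated numeric matrix with dimnames `i1..im` / `j1..jn`
#' @examples
#' as_cost_matrix(rbind(c(2, 4, 1), c(1, 2, 3)))
#' @export
as_cost_matrix <- function(x, integer_costs = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("cost matrix must be numeric")
  if (anyNA(x)) stop("cost matrix contains missing values")
  if (any(x < 0)) stop("costs must be nonnegative")
  m <- nrow(x); n <- ncol(x)
  if (m < 1L) stop("need at least one individual")
  if (m >= n)
    stop("not an unbalanced instance: need fewer individuals (rows = ", m,
         ") than jobs (columns = ", n, ")")
  if (integer_costs && any(x != round(x)))
    stop("strand mode requires integer costs (lengths are integral)")
  dimnames(x) <- list(paste0("i", seq_len(m)), paste0("j", seq_len(n)))
  x
}

#' Read a cost matrix from a CSV or TSV file
#'
#' The file holds one row per individual and one column per job. A header
#' row and/or a leading label column (e.g. `i1..im`) are detected and
#' dropped automatically. The separator is taken from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path path to the file
#' @param integer_costs passed to [as_cost_matrix()]
#' @return a validated cost matrix
#' @export
read_cost_matrix <- function(path, integer_costs = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  header <- all(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) > 1L &&
      anyNA(suppressWarnings(as.numeric(as.character(df[[1L]]))))) {
    df <- df[, -1L, drop = FALSE]  # row-label column
  }
  num <- suppressWarnings(vapply(df, function(col) as.numeric(as.character(col)),
                                 numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df))
  if (anyNA(num)) stop("non-numeric cost entries in ", path)
  as_cost_matrix(num, integer_costs = integer_costs)
}

#' Generate a random cost matrix
#'
#' Uniform independent integer costs in `[cost_lo, cost_hi]`; the same seed
#' always yields the same instance.
#'
#' @param m individuals (rows); must satisfy `m < n`
#' @param n jobs (columns)
#' @param cost_lo,cost_hi inclusive integer cost bounds, `0 <= lo <= hi`
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a validated cost matrix
#' @examples
#' random_instance(2, 3, seed = 7)
#' @export
random_instance <- function(m, n, cost_lo = 0, cost_hi = 9, seed = NULL) {
  if (cost_lo != round(cost_lo) || cost_hi != round(cost_hi))
    stop("cost bounds must be integers")
  if (cost_lo < 0 || cost_lo > cost_hi)
    stop("need 0 <= cost_lo <= cost_hi")
  if (!is.null(seed)) set.seed(seed)
  vals <- sample.int(cost_hi - cost_lo + 1L, m * n, replace = TRUE) - 1L +
    cost_lo
  as_cost_matrix(matrix(vals, nrow = m, ncol = n))
}
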