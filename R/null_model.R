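#' Margin-constrained null ensemble for a count matrix
#'
#' Draws random non-negative integer matrices sharing exactly the row and
#' column totals of the source matrix, using Patefield's algorithm for
#' uniform sampling of two-way tables conditioned on their margins (via
#' [stats::r2dtable()]).  These ensembles are the reference distribution
#' for all nestedness and modularity significance statements.
#'
#' @param M Non-negative integer matrix with positive grand total.
#' @param n_draws Number of matrices to draw (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `null_ensemble`: list with `matrices` (list
#'   of integer matrices with `M`'s dimnames), `row_sums`, `col_sums`,
#'   `n_draws` and `seed`.
#' @examples
#' M <- matrix(c(3, 1, 0, 2), 2)
#' ens <- patefield_null(M, n_draws = 5, seed = 1)
#' all(sapply(ens$matrices, function(x) all(rowSums(x) == rowSums(M))))
#' @export
patefield_null <- function(M, n_draws = 1000, seed = NULL) {
  M <- unclass(as.matrix(M))
  if (any(M < 0) || any(M != round(M)))
    stop("validation error: M must be a non-negative integer matrix", call. = FALSE)
  if (sum(M) == 0)
    stop("degenerate matrix: zero grand total", call. = FALSE)
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- as.integer(round(rowSums(M)))
  cs <- as.integer(round(colSums(M)))
  draws <- stats::r2dtable(n_draws, r, cs)
  draws <- lapply(draws, function(x) {
    dimnames(x) <- dimnames(M)
    storage.mode(x) <- "integer"
    x
  })
  structure(list(matrices = draws, row_sums = r, col_sums = cs,
                 n_draws = as.integer(n_draws), seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %d draws of a %d x %d matrix (fixed margins, grand total %d)\n",
              x$n_draws, length(x$row_sums), length(x$col_sums), sum(x$row_sums)))
  invisible(x)
}
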