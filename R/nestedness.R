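#' Weighted-interaction nestedness (WIN)
#'
#' Packs the matrix (rows and columns sorted by decreasing marginal
#' totals, ties broken by original index) and scores how strongly the
#' interaction weight concentrates in the generalist corner.  Each
#' non-zero cell at packed position (i, j) gets a closeness score
#' `1 - sqrt((i-1)^2 + (j-1)^2) / sqrt((nr-1)^2 + (nc-1)^2)` — 1 at the
#' generalist corner, 0 at the opposite corner — and WIN is the mean
#' closeness weighted by cell values.  A perfectly packed (nested) matrix
#' approaches the maximum attainable WIN; checkerboard-like (anti-nested)
#' matrices score *below* margin-conditioned random matrices because the
#' Euclidean distance is convex, so weight parked along the anti-diagonal
#' is farther from the corner than the same weight spread at random.
#'
#' @param M Non-negative matrix with at least one positive cell.
#' @return A single number in \[0, 1\]; larger = more nested.  A 1 x 1
#'   matrix scores 1 (its only cell is the corner).
#' @examples
#' win(rbind(c(8, 4, 2), c(4, 2, 0), c(2, 0, 0)))  # strongly packed
#' @export
win <- function(M) {
  M <- unclass(as.matrix(M))
  if (any(M < 0)) stop("validation error: negative cells", call. = FALSE)
  if (sum(M) == 0) stop("degenerate matrix: all cells zero", call. = FALSE)
  P <- pack_matrix(M)
  cl <- corner_closeness(nrow(P), ncol(P))
  nz <- P > 0
  sum(P[nz] * cl[nz]) / sum(P[nz])
}

# rows/cols sorted by decreasing margin, stable ties by original index
pack_matrix <- function(M) {
  ord_r <- order(-rowSums(M), seq_len(nrow(M)))
  ord_c <- order(-colSums(M), seq_len(ncol(M)))
  M[ord_r, ord_c, drop = FALSE]
}

# closeness of every grid cell to the packed (generalist) corner
corner_closeness <- function(nr, nc) {
  d_corner <- sqrt((nr - 1)^2 + (nc - 1)^2)
  if (d_corner == 0) return(matrix(1, nr, nc))
  d <- sqrt(outer((seq_len(nr) - 1)^2, (seq_len(nc) - 1)^2, `+`))
  1 - d / d_corner
}

# WIN of the maximally nested matrix compatible with M's margins: the
# transportation problem max sum(w * closeness) s.t. fixed row/column
# totals.  The closeness surface is supermodular (Monge), so the greedy
# allocation in decreasing-closeness order is optimal.
win_max <- function(M) {
  M <- unclass(as.matrix(M))
  r <- sort(rowSums(M), decreasing = TRUE)
  cs <- sort(colSums(M), decreasing = TRUE)
  nr <- length(r); nc <- length(cs)
  cl <- corner_closeness(nr, nc)
  X <- matrix(0, nr, nc)
  for (k in order(-as.vector(cl))) {
    i <- (k - 1) %% nr + 1
    j <- (k - 1) %/% nr + 1
    a <- min(r[i], cs[j])
    if (a > 0) { X[i, j] <- a; r[i] <- r[i] - a; cs[j] <- cs[j] - a }
  }
  win(X)
}

#' Weighted-Interaction Nestedness Estimator (WINE)
#'
#' Normalizes the observed [win()] of a matrix against a
#' margin-constrained null ensemble and the maximally packed matrix
#' sharing the observed margins:
#' \deqn{WINE = (WIN_{obs} - \overline{WIN}_{null}) / (WIN_{max} - \overline{WIN}_{null})}
#' WINE is ~0 when the observed nestedness is what the margins alone
#' produce, approaches 1 for maximal packing, and is negative for
#' anti-nested (checkerboard-like) structure.  Also reports
#' `z = (WIN_obs - mean) / sd(null)` and the one-tailed
#' `p = Pr(WIN_null >= WIN_obs)` for the alternative "more nested than
#' random".
#'
#' @param M Non-negative interaction matrix (morphospecies x distance
#'   categories).
#' @param ensemble A [patefield_null()] ensemble generated from `M`.
#' @return An object of class `nestedness_result`: list with
#'   `win_observed`, `win_null_mean`, `win_null_sd`, `win_max`, `wine`,
#'   `z`, `p`, `n_draws`.
#' @export
wine <- function(M, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  obs <- win(M)
  wmax <- win_max(M)
  null_win <- vapply(ensemble$matrices, win, numeric(1))
  mu <- mean(null_win)
  sdev <- stats::sd(null_win)
  if (sdev == 0)
    stop("undefined z-score: null WIN distribution has zero spread (",
         ensemble$n_draws, " draws, all equal to ", format(mu), ")", call. = FALSE)
  structure(
    list(win_observed = obs,
         win_null_mean = mu,
         win_null_sd = sdev,
         win_max = wmax,
         wine = (obs - mu) / (wmax - mu),
         z = (obs - mu) / sdev,
         p = mean(null_win >= obs),
         null_win = null_win,
         n_draws = ensemble$n_draws),
    class = "nestedness_result")
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf("Weighted nestedness: WIN obs %.3f / null %.3f (max %.3f)\n",
              x$win_observed, x$win_null_mean, x$win_max))
  cat(sprintf("  WINE %.3f, z = %.2f, one-tailed p = %.4f (%d null draws)\n",
              x$wine, x$z, x$p, x$n_draws))
  invisible(x)
}
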