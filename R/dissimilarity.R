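#' Modified Gower dissimilarity
#'
#' Gower-type mean absolute difference on log-transformed abundances:
#' each count x becomes log(x, base) + 1 when x > 0 and 0 when absent, and
#' the dissimilarity between two samples is the mean absolute difference
#' over species that are not absent from both.  With base 10 (the
#' default) an order-of-magnitude change in abundance of one species
#' contributes exactly as much as a presence-absence change, which is the
#' property motivating the transform.
#'
#' @param cm A `community_matrix`, or a plain non-negative samples x
#'   species matrix.
#' @param log_base Logarithm base (> 1), default 10.
#' @return A symmetric dissimilarity matrix of class `dissimilarity_matrix`
#'   with sample keys as dimnames.
#' @details A pair of entirely empty samples has no species on which to
#'   compare them (the denominator is 0); this raises an error naming the
#'   offending samples.  Exclude empty traps before calling (see
#'   [multiscale_dispersion()], which does so and reports the count).
#' @examples
#' x <- rbind(a = c(spA = 1), b = c(spA = 10))
#' modified_gower(x)[ "a", "b" ]  # 1: one order of magnitude
#' @export
modified_gower <- function(cm, log_base = 10) {
  x <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  if (!is.numeric(log_base) || length(log_base) != 1 || log_base <= 1)
    stop("`log_base` must be a single number > 1", call. = FALSE)
  if (any(x < 0)) stop("validation error: negative counts", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)

  xt <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  pos <- x > 0
  xt[pos] <- log(x[pos], base = log_base) + 1

  # Manhattan distance on the transform; absences transform to 0, so
  # double-zero species contribute nothing to the numerator and are
  # excluded from the denominator (species present in i or j)
  num <- as.matrix(stats::dist(xt, method = "manhattan"))
  P <- matrix(as.numeric(pos), nrow(x))
  n_present <- rowSums(P)
  m <- outer(n_present, n_present, `+`) - P %*% t(P)
  diag(m) <- pmax(diag(m), 1)  # diagonal is 0/0 -> 0 regardless
  if (any(m == 0)) {
    nm <- if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x)
    bad <- sort(which(m == 0, arr.ind = TRUE)[1, ])
    stop(sprintf("undefined pair: samples '%s' and '%s' share no observed species (both empty)",
                 nm[bad[1]], nm[bad[2]]), call. = FALSE)
  }
  D <- num / m
  dimnames(D) <- list(rownames(x), rownames(x))
  structure(D, class = c("dissimilarity_matrix", class(D)))
}
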