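#' Principal coordinates embedding of a dissimilarity matrix
#'
#' Eigendecomposes the Gower-centred matrix of -1/2 squared
#' dissimilarities and keeps axes of both eigenvalue signs.  Any
#' dissimilarity matrix is thereby embedded in a Euclidean space extended
#' by "imaginary" axes: for samples i, j the identity
#' \deqn{d_{ij}^2 = \|x_i - x_j\|^2_{+} - \|x_i - x_j\|^2_{-}}
#' holds, where the two norms are taken on the positive- and
#' negative-eigenvalue axes respectively.  Retaining the negative axes
#' avoids the downward bias in centroid distances that silently dropping
#' them would introduce for semi-metric dissimilarities such as the
#' modified Gower.
#'
#' @param D A symmetric dissimilarity matrix (class `dissimilarity_matrix`
#'   or plain matrix) with zero diagonal.
#' @return An object of class `pcoa_embedding`: list with `pos` (samples x
#'   real axes), `neg` (samples x imaginary axes, possibly 0 columns) and
#'   `eigenvalues` (all eigenvalues, decreasing).
#' @export
pcoa <- function(D) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-10) || any(diag(D) != 0) || any(D < 0))
    stop("validation error: D must be a symmetric non-negative matrix with zero diagonal",
         call. = FALSE)
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("sample", seq_len(n))
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  ipos <- which(e$values > tol)
  ineg <- which(e$values < -tol)
  pos <- e$vectors[, ipos, drop = FALSE] %*% diag(sqrt(e$values[ipos]), length(ipos))
  neg <- e$vectors[, ineg, drop = FALSE] %*% diag(sqrt(-e$values[ineg]), length(ineg))
  rownames(pos) <- rownames(neg) <- rownames(D)
  structure(list(pos = pos, neg = neg, eigenvalues = e$values),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat(sprintf("PCoA embedding: %d samples, %d real + %d imaginary axes\n",
              nrow(x$pos), ncol(x$pos), ncol(x$neg)))
  invisible(x)
}

#' Distance-to-centroid dispersion within groups
#'
#' For every sample, the Euclidean distance to the centroid of its group
#' in a [pcoa()] embedding, combining real and imaginary axes as
#' sqrt(max(d+^2 - d-^2, 0)).  Cases where the imaginary component
#' exceeds the real one are clamped to zero and counted in the
#' `n_clamped` attribute.  Singleton groups yield distance 0.
#'
#' @param embedding A `pcoa_embedding`.
#' @param grouping A vector mapping each sample to a group: either named
#'   by sample key or in embedding row order.
#' @return A data frame with columns `sample`, `group`, `distance`, with
#'   attribute `n_clamped`.
#' @export
dispersion <- function(embedding, grouping) {
  stopifnot(inherits(embedding, "pcoa_embedding"))
  samples <- rownames(embedding$pos)
  if (!is.null(names(grouping))) {
    miss <- setdiff(samples, names(grouping))
    if (length(miss) > 0)
      stop("validation error: samples missing from grouping: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    grouping <- grouping[samples]
  } else if (length(grouping) != length(samples)) {
    stop("validation error: grouping length does not match number of samples",
         call. = FALSE)
  }
  grouping <- as.character(grouping)
  if (anyNA(grouping))
    stop("validation error: NA group assignment", call. = FALSE)

  dist2_to_centroid <- function(coords) {
    out <- numeric(length(samples))
    if (ncol(coords) == 0) return(out)
    for (g in unique(grouping)) {
      idx <- which(grouping == g)
      centroid <- colMeans(coords[idx, , drop = FALSE])
      out[idx] <- colSums((t(coords[idx, , drop = FALSE]) - centroid)^2)
    }
    out
  }
  dp2 <- dist2_to_centroid(embedding$pos)
  dn2 <- dist2_to_centroid(embedding$neg)
  delta <- dp2 - dn2
  n_clamped <- sum(delta < -1e-12)
  res <- data.frame(sample = samples, group = grouping,
                    distance = sqrt(pmax(delta, 0)))
  attr(res, "n_clamped") <- n_clamped
  res
}

#' Four-scale beta-diversity dispersion for one season
#'
#' The per-season workflow for beta diversity: build the trap-level
#' community matrix for the requested season, exclude empty traps (their
#' modified Gower dissimilarity is undefined), embed all traps once with
#' [pcoa()] on [modified_gower()] dissimilarities, then compute
#' distance-to-centroid at four nested spatial scales within that single
#' embedding:
#' \describe{
#'   \item{transect}{centroid of each transect — heterogeneity along each
#'     gradient}
#'   \item{distance_category}{centroid of each distance category pooled
#'     across transects}
#'   \item{distance_by_transect}{centroid of each distance category within
#'     each transect}
#'   \item{sample_point}{centroid of each sample point — sampling
#'     variation}
#' }
#'
#' @param table A `trap_table`.
#' @param season Season label present in the table.
#' @param log_base Base for the modified Gower transform (default 10).
#' @return A data frame with columns `sample`, `scale`, `group`, `season`,
#'   `distance` plus per-trap metadata; attributes `n_excluded_empty` and
#'   `n_clamped`.
#' @export
multiscale_dispersion <- function(table, season, log_base = 10) {
  cm <- build_community_matrix(table, level = "trap", season_filter = season)
  empty <- rowSums(cm$counts) == 0
  n_excluded <- sum(empty)
  if (sum(!empty) < 2)
    stop("fewer than 2 non-empty traps in season ", season, call. = FALSE)
  cm$counts <- cm$counts[!empty, , drop = FALSE]
  cm$metadata <- cm$metadata[!empty, , drop = FALSE]

  emb <- pcoa(modified_gower(cm, log_base = log_base))
  md <- cm$metadata
  groupings <- list(
    transect = sprintf("T%d", md$transect),
    distance_category = sprintf("%dm", md$distance_m),
    distance_by_transect = sprintf("T%d/%dm", md$transect, md$distance_m),
    sample_point = sprintf("T%d/%dm/P%d", md$transect, md$distance_m, md$sample_point))

  n_clamped <- 0L
  out <- do.call(rbind, lapply(names(groupings), function(sc) {
    d <- dispersion(emb, setNames(groupings[[sc]], rownames(cm$counts)))
    n_clamped <<- n_clamped + attr(d, "n_clamped")
    cbind(d[, "sample", drop = FALSE], scale = sc,
          d[, c("group", "distance")], season = season, md)
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded_empty") <- n_excluded
  attr(out, "n_clamped") <- n_clamped
  out
}
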