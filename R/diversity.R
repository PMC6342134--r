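#' Per-sample alpha metrics
#'
#' Three standard within-sample metrics for a species count vector:
#' `abundance()` is the number of individuals, `richness()` the number of
#' morphospecies with at least one capture, and `effective_species()` the
#' Hill number of order 1, i.e. the exponential of Shannon entropy
#' computed with natural logarithms on relative abundances.  The Hill
#' number is base-invariant (the exponential cancels the logarithm base)
#' and satisfies 1 <= effective_species <= richness, with equality on the
#' left for a monoculture and on the right for a perfectly even community.
#'
#' @param counts Non-negative integer vector of per-species counts.
#' @return `abundance()` and `richness()` return a single integer;
#'   `effective_species()` a single double.
#' @examples
#' abundance(c(3, 0, 7))          # 10
#' richness(c(3, 0, 7))           # 2
#' effective_species(c(10, 10, 10, 10))  # 4
#' @export
abundance <- function(counts) {
  counts <- check_counts(counts)
  as.integer(sum(counts))
}

#' @rdname abundance
#' @export
richness <- function(counts) {
  counts <- check_counts(counts)
  as.integer(sum(counts > 0))
}

#' @rdname abundance
#' @export
effective_species <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0)
    stop("undefined diversity: effective number of species of an empty sample",
         call. = FALSE)
  p <- counts[counts > 0] / n
  exp(-sum(p * log(p)))
}

check_counts <- function(counts) {
  if (length(counts) == 0) return(numeric(0))
  if (anyNA(counts) || any(counts < 0))
    stop("validation error: counts must be non-negative and non-missing",
         call. = FALSE)
  counts
}

#' Alpha-metric table for a community matrix
#'
#' Applies the three alpha metrics to every sample of a
#' [build_community_matrix()] result and returns one row per sample with
#' its metadata.  Empty samples (zero captures) get `NA` effective
#' species — the exponential Shannon index of an empty community is
#' undefined, and propagating missingness avoids biasing summaries.
#'
#' @param cm A `community_matrix`.
#' @return A data frame: sample metadata plus `abundance`, `richness`,
#'   `effective_species`.
#' @export
alpha_metrics <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  ab <- as.integer(rowSums(cm$counts))
  ri <- as.integer(rowSums(cm$counts > 0))
  ef <- vapply(seq_len(nrow(cm$counts)), function(i) {
    if (ab[i] == 0) return(NA_real_)
    effective_species(cm$counts[i, ])
  }, numeric(1))
  out <- cbind(cm$metadata,
               data.frame(abundance = ab, richness = ri, effective_species = ef))
  rownames(out) <- rownames(cm$counts)
  out
}
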