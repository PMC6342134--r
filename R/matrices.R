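#' Build a community count matrix from a trap table
#'
#' Aggregates trap records into a samples x morphospecies count matrix at a
#' chosen pooling level.  Samples are always season-specific: at the
#' default `trap` level one sample is one trap in one season, matching the
#' per-trap responses used for alpha metrics and dispersion.
#'
#' @param table A `trap_table`.
#' @param level Pooling level: `"trap"` (no pooling), `"sample_point"`
#'   (traps summed within a sample point) or `"distance_by_transect"`
#'   (traps summed within a distance category of a transect).
#' @param season_filter Optional season label; only records of that season
#'   are used.
#' @param drop_zero_species Drop morphospecies with zero total across all
#'   retained samples (default `TRUE`); the choice is recorded in the
#'   result.
#' @return A list of class `community_matrix` with elements `counts`
#'   (integer matrix, samples x species), `metadata` (one row per sample:
#'   transect, distance_m, sample_point, trap, season, as applicable to the
#'   level) and `zero_species_dropped`.
#' @examples
#' d <- survey_design(n_transects = 1, n_sample_points = 1, n_traps = 2)
#' tab <- trap_table(data.frame(
#'   transect = 1, distance_m = 0, sample_point = 1, trap = 1:2,
#'   season = "wet", species = "spA", count = c(3, 5)), d)
#' build_community_matrix(tab)$counts
#' @export
build_community_matrix <- function(table,
                                   level = c("trap", "sample_point", "distance_by_transect"),
                                   season_filter = NULL,
                                   drop_zero_species = TRUE) {
  stopifnot(inherits(table, "trap_table"))
  level <- match.arg(level)
  df <- as.data.frame(table)
  if (!is.null(season_filter)) df <- df[df$season == season_filter, , drop = FALSE]
  if (nrow(df) == 0)
    stop("empty selection: no records remain after filtering", call. = FALSE)

  key_cols <- switch(level,
    trap = c("transect", "distance_m", "sample_point", "trap", "season"),
    sample_point = c("transect", "distance_m", "sample_point", "season"),
    distance_by_transect = c("transect", "distance_m", "season"))

  sample_key <- do.call(paste, c(df[key_cols], sep = "/"))
  species <- sort(unique(df$species))
  samples <- unique(sample_key)
  counts <- matrix(0L, nrow = length(samples), ncol = length(species),
                   dimnames = list(samples, species))
  agg <- tapply(df$count, list(sample_key, df$species), sum)
  agg[is.na(agg)] <- 0L
  counts[rownames(agg), colnames(agg)] <- as.integer(agg)

  meta <- df[!duplicated(sample_key), key_cols, drop = FALSE]
  rownames(meta) <- sample_key[!duplicated(sample_key)]
  meta <- meta[samples, , drop = FALSE]

  if (drop_zero_species) {
    keep <- colSums(counts) > 0
    counts <- counts[, keep, drop = FALSE]
  }
  structure(
    list(counts = counts, metadata = meta, level = level,
         zero_species_dropped = drop_zero_species),
    class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix (%s level): %d samples x %d morphospecies, %d individuals\n",
              x$level, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Build distance-class interaction matrices
#'
#' For every observed transect x season combination, pools counts over
#' sample points and traps into a morphospecies (rows) x distance
#' categories (columns) matrix — the unit of the nestedness and modularity
#' analyses.  Morphospecies never caught in that transect and season
#' (all-zero rows) are removed.
#'
#' @param table A `trap_table`.
#' @return A named list of `interaction_matrix` objects (integer matrices
#'   with species rownames and distance-category colnames, plus attributes
#'   `transect` and `season`), named `"T<transect>.<season>"`.
#' @examples
#' d <- survey_design(n_transects = 1, n_sample_points = 1, n_traps = 2)
#' tab <- trap_table(data.frame(
#'   transect = 1, distance_m = c(0, 0, 50), sample_point = 1,
#'   trap = c(1, 2, 1), season = "wet", species = "spA",
#'   count = c(1, 3, 2)), d)
#' build_interaction_matrices(tab)[["T1.wet"]]
#' @export
build_interaction_matrices <- function(table) {
  stopifnot(inherits(table, "trap_table"))
  design <- attr(table, "design")
  df <- as.data.frame(table)
  combos <- unique(df[c("transect", "season")])
  combos <- combos[order(combos$transect, match(combos$season, design$seasons)), ]
  out <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$transect[i]; se <- combos$season[i]
    sub <- df[df$transect == tr & df$season == se, , drop = FALSE]
    species <- sort(unique(sub$species))
    m <- matrix(0L, nrow = length(species), ncol = length(design$distance_categories_m),
                dimnames = list(species, as.character(design$distance_categories_m)))
    agg <- tapply(sub$count, list(sub$species, as.character(sub$distance_m)), sum)
    agg[is.na(agg)] <- 0L
    m[rownames(agg), colnames(agg)] <- as.integer(agg)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    attr(m, "transect") <- tr
    attr(m, "season") <- se
    class(m) <- c("interaction_matrix", class(m))
    out[[sprintf("T%d.%s", tr, se)]] <- m
  }
  out
}

#' Read / write a wide interaction matrix
#'
#' Wide CSV format: first column `species`, remaining columns the distance
#' categories in metres.
#'
#' @param m An `interaction_matrix` (or plain species x distance matrix).
#' @param path File path.
#' @return `read_interaction_matrix` returns an integer matrix with
#'   species rownames and distance colnames; `write_interaction_matrix`
#'   returns `path` invisibly.
#' @export
write_interaction_matrix <- function(m, path) {
  mm <- matrix(as.vector(m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(species = rownames(mm), as.data.frame(mm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (names(df)[1] != "species")
    stop("interaction matrix format error: first column must be `species`", call. = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$species
  m
}

#' Read / write a community matrix
#'
#' Wide CSV: the sample metadata columns followed by one column per
#' morphospecies.  The written file re-reads to an identical object.
#'
#' @param cm A `community_matrix`.
#' @param path File path.
#' @return `read_community_matrix` returns a `community_matrix`;
#'   `write_community_matrix` returns `path` invisibly.
#' @export
write_community_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "community_matrix"))
  df <- cbind(sample = rownames(cm$counts), cm$metadata,
              as.data.frame(unclass(cm$counts)[seq_len(nrow(cm$counts)), , drop = FALSE]),
              stringsAsFactors = FALSE)
  attr(df, "level") <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_community_matrix
#' @param level Pooling level recorded in the re-read object.
#' @param zero_species_dropped Flag recorded in the re-read object.
#' @export
read_community_matrix <- function(path, level = "trap", zero_species_dropped = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  meta_cols <- intersect(c("transect", "distance_m", "sample_point", "trap", "season"),
                         names(df))
  sp_cols <- setdiff(names(df), c("sample", meta_cols))
  counts <- as.matrix(df[sp_cols])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$sample
  meta <- df[meta_cols]
  rownames(meta) <- df$sample
  structure(list(counts = counts, metadata = meta, level = level,
                 zero_species_dropped = zero_species_dropped),
            class = "community_matrix")
}
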