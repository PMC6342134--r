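#' Survey design description
#'
#' Declares the sampling hierarchy of a trap survey: transects running away
#' from the water source, discrete distance categories along each transect,
#' sample points within each category, traps within each sample point, and
#' the seasons sampled.  The defaults describe a 1-km transect design with
#' five sample points at each of seven distances from water and three
#' pitfall traps per point, surveyed once per season.
#'
#' @param n_transects Number of transects (>= 1).
#' @param distance_categories_m Strictly increasing integer vector of
#'   distance categories in metres; the first element must be 0 (the water
#'   edge).
#' @param n_sample_points Sample points per distance category (>= 1).
#' @param n_traps Traps per sample point (>= 1).
#' @param seasons Character vector of season labels.
#'
#' @return An object of class `survey_design`.
#' @examples
#' survey_design()
#' survey_design(n_transects = 2, distance_categories_m = c(0, 100, 500))
#' @export
survey_design <- function(n_transects = 6,
                          distance_categories_m = c(0L, 50L, 100L, 150L, 250L, 500L, 1000L),
                          n_sample_points = 5,
                          n_traps = 3,
                          seasons = c("wet", "dry")) {
  distance_categories_m <- as.integer(distance_categories_m)
  if (length(distance_categories_m) < 1 || anyNA(distance_categories_m))
    stop("`distance_categories_m` must be a non-empty integer vector", call. = FALSE)
  if (distance_categories_m[1] != 0L)
    stop("first distance category must be 0 (the water edge)", call. = FALSE)
  if (is.unsorted(distance_categories_m, strictly = TRUE))
    stop("`distance_categories_m` must be strictly increasing", call. = FALSE)
  for (nm in c("n_transects", "n_sample_points", "n_traps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop(sprintf("`%s` must be a single integer >= 1", nm), call. = FALSE)
  }
  seasons <- as.character(seasons)
  if (length(seasons) < 1 || anyDuplicated(seasons))
    stop("`seasons` must be a non-empty vector of unique labels", call. = FALSE)
  structure(
    list(
      n_transects = as.integer(n_transects),
      distance_categories_m = distance_categories_m,
      n_sample_points = as.integer(n_sample_points),
      n_traps = as.integer(n_traps),
      seasons = seasons
    ),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Trap survey design\n")
  cat(sprintf("  transects:        %d\n", x$n_transects))
  cat(sprintf("  distances (m):    %s\n", paste(x$distance_categories_m, collapse = ", ")))
  cat(sprintf("  sample points:    %d per distance category\n", x$n_sample_points))
  cat(sprintf("  traps:            %d per sample point\n", x$n_traps))
  cat(sprintf("  seasons:          %s\n", paste(x$seasons, collapse = ", ")))
  cat(sprintf("  traps per season: %d\n",
              x$n_transects * length(x$distance_categories_m) * x$n_sample_points * x$n_traps))
  invisible(x)
}
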