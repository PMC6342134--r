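#' Configuration for the synthetic trap-survey generator
#'
#' Describes a synthetic community with the statistical structure the
#' downstream analyses assume: a long-tailed species abundance
#' distribution, per-season log-linear abundance trends along the
#' distance-to-water gradient, a multiplicative wet:dry season effect,
#' overdispersed (negative binomial) trap counts, and optionally planted
#' nested or modular organisation of species across distance categories.
#'
#' The expected count of species `sp` in one trap in season `s` at
#' distance `d` metres is
#' \deqn{\lambda = base(sp) \cdot season(s) \cdot e^{trend_s \, d / 100}
#'   \cdot w(sp, d)}
#' with `base` scaled so the expected grand total over the whole survey
#' equals `total_individuals`, and `w` the structure weight
#' (row-normalised to mean 1 so that planting structure does not change
#' expected totals).
#'
#' @param design A [survey_design()].
#' @param n_species Number of morphospecies in the pool (default 150).
#' @param total_individuals Expected grand total over the full survey
#'   (default 55000).
#' @param sad Species abundance distribution: `"log-series"` (default)
#'   or `"lognormal"`.
#' @param sad_param Shape parameter: the log-series `x` (default 0.999,
#'   long-tailed) or the lognormal `sdlog` (default 1.5).
#' @param distance_trend Named numeric, log-linear trend per 100 m for
#'   each season (negative = decline away from water).
#' @param season_effect Multiplicative wet:dry abundance ratio
#'   (default 2: wet season twice as abundant).
#' @param structure `"none"`, `"nested"` or `"modular"`.
#' @param strength Structure strength in \[0, 1\]: 0 = unstructured,
#'   1 = fully structured (strict zeros outside the planted pattern).
#' @param modules For modular structure: list of integer vectors
#'   partitioning the distance categories (metres) into modules.
#'   Default: near-water block `{0, 50, 100}` vs the rest.
#' @param nested_decay For nested structure: e-folding rate of a
#'   species' expected count across the distance categories it occupies
#'   (default 1 per category step).
#' @param dispersion Negative-binomial size parameter for trap counts
#'   (default 0.5 — strongly aggregated, as arthropod trap counts are).
#' @param seed Integer seed; identical configs and seeds give
#'   byte-identical tables.
#' @return An object of class `generator_config`.
#' @seealso [generate_survey()], [planted_truth()]
#' @export
generator_config <- function(design = survey_design(),
                             n_species = 150,
                             total_individuals = 55000,
                             sad = c("log-series", "lognormal"),
                             sad_param = NULL,
                             distance_trend = c(wet = -0.1, dry = -0.1),
                             season_effect = 2,
                             structure = c("none", "nested", "modular"),
                             strength = 1,
                             modules = NULL,
                             nested_decay = 1,
                             dispersion = 0.5,
                             seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  sad <- match.arg(sad)
  structure_type <- match.arg(structure)
  if (is.null(sad_param)) sad_param <- if (sad == "log-series") 0.999 else 1.5
  if (n_species < 1 || total_individuals <= 0 || dispersion <= 0)
    stop("configuration error: n_species, total_individuals and dispersion must be positive",
         call. = FALSE)
  if (!is.numeric(strength) || strength < 0 || strength > 1)
    stop("configuration error: strength must lie in [0, 1]", call. = FALSE)
  if (is.null(names(distance_trend)) ||
      !setequal(names(distance_trend), design$seasons))
    stop("configuration error: `distance_trend` must be named by the design's seasons",
         call. = FALSE)
  if (season_effect <= 0)
    stop("configuration error: season_effect must be positive", call. = FALSE)
  cats <- design$distance_categories_m
  if (structure_type == "modular") {
    if (is.null(modules))
      modules <- list(cats[cats <= 100], cats[cats > 100])
    flat <- unlist(modules)
    if (anyDuplicated(flat) || !setequal(flat, cats))
      stop("configuration error: `modules` must partition the distance categories disjointly",
         call. = FALSE)
  } else {
    modules <- NULL
  }
  structure(
    list(design = design, n_species = as.integer(n_species),
         total_individuals = total_individuals, sad = sad,
         sad_param = sad_param,
         distance_trend = distance_trend[design$seasons],
         season_effect = season_effect, structure = structure_type,
         strength = strength, modules = modules,
         nested_decay = nested_decay, dispersion = dispersion,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' Generate a synthetic trap survey
#'
#' Draws one record per trap x season x morphospecies (zero counts
#' included, so every trap is explicit) with negative-binomial counts
#' around the mean surface described in [generator_config()].
#'
#' @param config A [generator_config()].
#' @return A `trap_table`.
#' @examples
#' cfg <- generator_config(design = survey_design(n_transects = 1),
#'                         n_species = 10, total_individuals = 500, seed = 7)
#' tab <- generate_survey(cfg)
#' sum(tab$count)
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  des <- config$design
  surf <- survey_mean_surface(config)  # consumes the seed's first draws
  grid <- surf$grid
  lambda <- surf$lambda
  counts <- stats::rnbinom(length(lambda), size = config$dispersion,
                           mu = as.vector(lambda))
  n_sp <- config$n_species
  species <- sprintf("sp%03d", seq_len(n_sp))
  records <- grid[rep(seq_len(nrow(grid)), times = n_sp), , drop = FALSE]
  records$species <- rep(species, each = nrow(grid))
  records$count <- counts
  rownames(records) <- NULL
  trap_table(records, des)
}

# Deterministic-given-seed expected-count surface: seeds the RNG, draws
# the SAD, and returns the trap grid with the lambda matrix (grid rows x
# species), scaled so sum(lambda) == total_individuals exactly.  Exposed
# internally so tests can verify marginal control analytically
# (var(total) = sum(lambda + lambda^2 / size)).
survey_mean_surface <- function(config) {
  des <- config$design
  set.seed(config$seed)
  # sorted decreasing, so sp001 is the most abundant morphospecies and the
  # planted nested ordering is the label order
  rel <- sort(draw_relative_abundances(config), decreasing = TRUE)
  W <- structure_weights(config, rel)          # n_species x n_categories, row mean 1
  grid <- expand.grid(
    trap = seq_len(des$n_traps),
    sample_point = seq_len(des$n_sample_points),
    distance_m = des$distance_categories_m,
    transect = seq_len(des$n_transects),
    season = des$seasons,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  season_mult <- setNames(rep(1, length(des$seasons)), des$seasons)
  if (all(c("wet", "dry") %in% des$seasons)) season_mult["wet"] <- config$season_effect
  trap_mult <- season_mult[grid$season] *
    exp(config$distance_trend[grid$season] * grid$distance_m / 100)
  cat_index <- match(grid$distance_m, des$distance_categories_m)
  lambda <- outer(trap_mult, rel) * t(W)[cat_index, , drop = FALSE]
  lambda <- lambda * (config$total_individuals / sum(lambda))
  list(grid = grid, lambda = lambda, rel = rel, W = W)
}

# relative abundances of the species pool under the configured SAD
draw_relative_abundances <- function(config) {
  n <- config$n_species
  if (config$sad == "log-series") {
    x <- config$sad_param
    k <- seq_len(20000L)
    pmf <- x^k / k
    ab <- k[findInterval(stats::runif(n), cumsum(pmf) / sum(pmf)) + 1L]
  } else {
    ab <- stats::rlnorm(n, meanlog = 0, sdlog = config$sad_param)
  }
  ab / sum(ab)
}

# species x distance-category weight matrix, each row normalised to mean 1.
# `rel` = species relative abundances, sorted decreasing (needed to plant
# weighted nestedness).
structure_weights <- function(config, rel) {
  des <- config$design
  ncat <- length(des$distance_categories_m)
  n_sp <- config$n_species
  s <- config$strength
  U <- matrix(1, n_sp, ncat)
  if (config$structure == "none" || s == 0) return(U)
  if (config$structure == "nested") {
    # Weighted nestedness in the packing sense: at strength 1 the expected
    # matrix is the maximally corner-packed arrangement compatible with the
    # species abundance distribution — rank-ordered species aligned onto
    # geometrically decaying distance-category capacity by a
    # northwest-corner transport (each species occupies a contiguous band
    # of categories, dominant species mass piled against the water edge).
    q <- exp(-config$nested_decay * (seq_len(ncat) - 1))
    q <- q / sum(q)
    Fc <- cumsum(rel); Fp <- c(0, Fc[-n_sp])
    Qc <- cumsum(q);   Qp <- c(0, Qc[-ncat])
    P <- matrix(0, n_sp, ncat)
    for (i in seq_len(n_sp)) {
      overlap <- pmax(0, pmin(Fc[i], Qc) - pmax(Fp[i], Qp))
      if (sum(overlap) == 0) overlap[min(findInterval(Fp[i], Qc) + 1, ncat)] <- 1
      P[i, ] <- overlap / sum(overlap)
    }
  } else { # modular: species assigned round-robin to distance-category modules
    k <- length(config$modules)
    sp_module <- ((seq_len(n_sp) - 1) %% k) + 1
    P <- matrix(0, n_sp, ncat)
    for (i in seq_len(n_sp)) {
      in_mod <- des$distance_categories_m %in% config$modules[[sp_module[i]]]
      P[i, in_mod] <- 1
    }
  }
  W <- (1 - s) * U + s * P
  W / rowMeans(W)
}

#' Planted structural truth of a generator configuration
#'
#' Returns what the generator planted, for recovery tests: the module
#' partition (modular), the species occupancy ordering (nested), and the
#' per-season trend coefficients.
#'
#' @param config A [generator_config()].
#' @return A list of class `structure_truth` with elements `structure`,
#'   `modules` (modular only), `species_order` and `breadth` (nested
#'   only: species labels in decreasing occupancy breadth, and the
#'   number of distance categories each occupies), `distance_trend`,
#'   `season_effect`, `strength`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  out <- list(structure = config$structure,
              distance_trend = config$distance_trend,
              season_effect = config$season_effect,
              strength = config$strength)
  if (config$structure == "modular") {
    out$modules <- config$modules
    k <- length(config$modules)
    out$species_modules <- setNames(((seq_len(config$n_species) - 1) %% k) + 1,
                                    sprintf("sp%03d", seq_len(config$n_species)))
  }
  if (config$structure == "nested") {
    ncat <- length(config$design$distance_categories_m)
    n_sp <- config$n_species
    out$species_order <- sprintf("sp%03d", seq_len(n_sp))
    out$breadth <- pmax(1L, round(ncat * (n_sp - seq_len(n_sp) + 1) / n_sp))
  }
  if (config$structure == "none") {
    out <- out[c("structure")]
  }
  class(out) <- "structure_truth"
  out
}

#' Read / write a generator configuration as structured text
#'
#' Key:value YAML serialisation of a [generator_config()] including its
#' survey design, so a generation run is fully described by one small
#' text file.
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `read_generator_config()` returns a `generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$distance_trend <- as.list(x$distance_trend)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  design <- do.call(survey_design, x$design)
  generator_config(
    design = design, n_species = x$n_species,
    total_individuals = x$total_individuals, sad = x$sad,
    sad_param = x$sad_param,
    distance_trend = unlist(x$distance_trend),
    season_effect = x$season_effect, structure = x$structure,
    strength = x$strength, modules = x$modules,
    nested_decay = x$nested_decay, dispersion = x$dispersion,
    seed = x$seed)
}
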