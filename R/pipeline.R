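#' Benjamini–Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR control: adjusted p_(i) = min over j >= i of m * p_(j) / j,
#' capped at 1; hypotheses with adjusted p <= alpha are rejected.
#' Delegates the adjustment to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Target FDR level in (0, 1), default 0.05.
#' @return A data frame with columns `p`, `p_adjusted`, `reject`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("validation error: alpha must lie in (0, 1)", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' Run configuration for the full analysis pipeline
#'
#' @param input Path to a trap-table CSV, or a [generator_config()] to
#'   synthesise the survey.
#' @param design Survey design used to validate a CSV input (ignored for
#'   a generator input, which carries its own design).
#' @param log_base Modified Gower logarithm base (default 10).
#' @param n_null_draws Null matrices per interaction matrix
#'   (default 1000).
#' @param n_permutations Permutations for the seasonal comparison
#'   (default 9999).
#' @param restarts Annealing restarts for modularity (default 10).
#' @param alpha FDR level for the structure-test summary (default 0.05).
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it, so a rerun reproduces all outputs exactly.
#' @param out_dir Output directory for the result artifacts.
#' @param stages Subset of `c("alpha", "dispersion", "structure",
#'   "seasonal")` to run; `"seasonal"` requires `"structure"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, design = survey_design(), log_base = 10,
                       n_null_draws = 1000, n_permutations = 9999,
                       restarts = 10, alpha = 0.05, seed = 1,
                       out_dir = tempfile("piosphere_run_"),
                       stages = c("alpha", "dispersion", "structure", "seasonal")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("seasonal" %in% stages && !("structure" %in% stages))
    stop("configuration error: the seasonal stage needs the structure stage",
         call. = FALSE)
  for (nm in c("n_null_draws", "n_permutations", "restarts")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1)
      stop(sprintf("configuration error: `%s` must be >= 1", nm), call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1)
    stop("configuration error: alpha must lie in (0, 1)", call. = FALSE)
  structure(list(input = input, design = design, log_base = log_base,
                 n_null_draws = as.integer(n_null_draws),
                 n_permutations = as.integer(n_permutations),
                 restarts = as.integer(restarts), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir,
                 stages = stages),
            class = "run_config")
}

#' Run the full multi-scale community analysis
#'
#' Orchestrates the analysis on a trap table: per-trap alpha metrics and
#' per-category summaries, four-scale dispersion per season, WINE and
#' modularity with margin-constrained null inference per transect x
#' season, seasonal D-value comparisons per transect, BH adjustment of
#' the structure-test p-value families, a model-ready long table for
#' external mixed-model fitting, and a machine-readable JSON manifest
#' (config, seeds, package version, exclusion/clamp counts).  All
#' tabular artifacts are CSV files in `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages (default `FALSE`).
#' @return Invisibly, a list with the in-memory results (`table`,
#'   `alpha`, `alpha_summary`, `dispersion`, `dispersion_summary`,
#'   `structure`, `seasonal`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("piosphere")),
                   seed = config$seed,
                   stages = config$stages,
                   settings = config[c("log_base", "n_null_draws", "n_permutations",
                                       "restarts", "alpha")])

  # --- input ---------------------------------------------------------
  if (inherits(config$input, "generator_config")) {
    say("stage input: generating synthetic survey (seed %d)", config$input$seed)
    table <- generate_survey(config$input)
    manifest$input <- list(kind = "generator",
                           generator_seed = config$input$seed,
                           structure = config$input$structure)
  } else {
    say("stage input: reading %s", config$input)
    table <- read_trap_table(config$input, config$design)
    manifest$input <- list(kind = "file", path = as.character(config$input))
  }
  design <- attr(table, "design")
  seasons <- intersect(design$seasons, unique(table$season))
  res$table <- table
  manifest$n_records <- nrow(table)
  manifest$n_individuals <- sum(table$count)
  manifest$n_morphospecies <- length(unique(table$species[table$count > 0]))

  # --- alpha metrics -------------------------------------------------
  if ("alpha" %in% config$stages) {
    say("stage alpha: per-trap metrics")
    cm <- build_community_matrix(table, level = "trap")
    res$alpha <- alpha_metrics(cm)
    res$alpha_summary <- summarize_by(res$alpha,
                                      c("abundance", "richness", "effective_species"),
                                      c("distance_m", "season"))
    write_artifact(res$alpha, config$out_dir, "alpha_metrics.csv")
    write_artifact(res$alpha_summary, config$out_dir, "alpha_summary.csv")
    write_artifact(res$alpha, config$out_dir, "model_ready.csv")
  }

  # --- dispersion ----------------------------------------------------
  if ("dispersion" %in% config$stages) {
    disp <- list()
    for (se in seasons) {
      say("stage dispersion: season %s", se)
      disp[[se]] <- multiscale_dispersion(table, season = se,
                                          log_base = config$log_base)
    }
    res$dispersion <- do.call(rbind, c(disp, make.row.names = FALSE))
    manifest$dispersion <- list(
      n_excluded_empty = sum(vapply(disp, attr, 0L, which = "n_excluded_empty")),
      n_clamped = sum(vapply(disp, attr, 0L, which = "n_clamped")))
    res$dispersion_summary <- summarize_by(res$dispersion, "distance",
                                           c("scale", "distance_m", "season"))
    write_artifact(res$dispersion, config$out_dir, "dispersion.csv")
    write_artifact(res$dispersion_summary, config$out_dir, "dispersion_summary.csv")
  }

  # --- structure: nestedness + modularity ----------------------------
  if ("structure" %in% config$stages) {
    mats <- build_interaction_matrices(table)
    rows <- list(); store <- list()
    for (nm in names(mats)) {
      say("stage structure: %s (%d species x %d categories)", nm,
          nrow(mats[[nm]]), ncol(mats[[nm]]))
      M <- mats[[nm]]
      sub_seed <- (config$seed + match(nm, names(mats)) * 1009L) %% .Machine$integer.max
      ens <- patefield_null(M, n_draws = config$n_null_draws, seed = sub_seed)
      nest <- wine(M, ens)
      mod <- modularity_significance(M, ens, restarts = config$restarts,
                                     seed = sub_seed + 1L)
      store[[nm]] <- list(matrix = M, ensemble_seed = sub_seed,
                          nestedness = nest, modularity = mod)
      rows[[nm]] <- data.frame(
        transect = attr(M, "transect"), season = attr(M, "season"),
        statistic = c("WIN", "Q"),
        observed = c(nest$win_observed, mod$Q),
        null_mean = c(nest$win_null_mean, mod$q_null_mean),
        normalized = c(nest$wine, NA),
        n_modules = c(NA, mod$n_modules),
        z = c(nest$z, mod$z), p = c(nest$p, mod$p))
      write_artifact(
        data.frame(node = c(names(mod$row_modules), names(mod$column_modules)),
                   mode = rep(c("species", "distance_m"),
                              c(length(mod$row_modules), length(mod$column_modules))),
                   module = c(mod$row_modules, mod$column_modules)),
        config$out_dir, sprintf("modules_%s.csv", nm))
    }
    structure_table <- do.call(rbind, c(rows, make.row.names = FALSE))
    # BH within each statistic family
    structure_table$p_adjusted <- NA_real_
    structure_table$reject <- NA
    for (st in unique(structure_table$statistic)) {
      idx <- structure_table$statistic == st
      bh <- benjamini_hochberg(structure_table$p[idx], config$alpha)
      structure_table$p_adjusted[idx] <- bh$p_adjusted
      structure_table$reject[idx] <- bh$reject
    }
    res$structure <- structure_table
    res$structure_detail <- store
    write_artifact(structure_table, config$out_dir, "structure_results.csv")
  }

  # --- seasonal comparisons ------------------------------------------
  if ("seasonal" %in% config$stages && length(seasons) >= 2) {
    store <- res$structure_detail
    transects <- sort(unique(vapply(store, function(x) attr(x$matrix, "transect"), 0L)))
    rows <- list()
    for (tr in transects) {
      wet_nm <- sprintf("T%d.wet", tr); dry_nm <- sprintf("T%d.dry", tr)
      if (!(wet_nm %in% names(store)) || !(dry_nm %in% names(store))) next
      say("stage seasonal: transect %d", tr)
      for (st in c("WIN", "Q")) {
        w <- store[[wet_nm]]; d <- store[[dry_nm]]
        if (st == "WIN") {
          sc <- seasonal_comparison(w$nestedness$win_observed, w$nestedness$null_win,
                                    d$nestedness$win_observed, d$nestedness$null_win,
                                    n_permutations = config$n_permutations,
                                    seed = (config$seed + tr * 31L) %% .Machine$integer.max)
        } else {
          sc <- seasonal_comparison(w$modularity$Q, w$modularity$q_null,
                                    d$modularity$Q, d$modularity$q_null,
                                    n_permutations = config$n_permutations,
                                    seed = (config$seed + tr * 31L + 1L) %% .Machine$integer.max)
        }
        rows[[paste(tr, st)]] <- data.frame(transect = tr, statistic = st,
                                            D_difference = sc$statistic, p = sc$p,
                                            n_permutations = sc$n_permutations)
      }
    }
    if (length(rows) > 0) {
      res$seasonal <- do.call(rbind, c(rows, make.row.names = FALSE))
      bh <- benjamini_hochberg(res$seasonal$p, config$alpha)
      res$seasonal$p_adjusted <- bh$p_adjusted
      res$seasonal$reject <- bh$reject
      write_artifact(res$seasonal, config$out_dir, "seasonal_comparisons.csv")
    }
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("run complete: %s (%.1f s)", config$out_dir, manifest$elapsed_s)
  invisible(res)
}

# mean / sd / SE / n of `vars` within every combination of `by` columns
summarize_by <- function(df, vars, by) {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  groups <- split(df, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    base <- g[1, by, drop = FALSE]
    for (v in vars) {
      x <- g[[v]][!is.na(g[[v]])]
      base[[paste0(v, "_mean")]] <- mean(x)
      base[[paste0(v, "_se")]] <- stats::sd(x) / sqrt(length(x))
      base[[paste0(v, "_n")]] <- length(x)
    }
    base
  }))
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

write_artifact <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(NULL)
}
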