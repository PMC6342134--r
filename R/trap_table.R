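# canonical column order of the long input format
TRAP_TABLE_COLUMNS <- c("transect", "distance_m", "sample_point", "trap",
                        "season", "species", "count")

#' Construct a validated trap table
#'
#' A trap table holds one row per trap x season x morphospecies with the
#' full sampling hierarchy.  Rows are validated against a
#' [survey_design()]: counts must be non-negative integers, distance
#' categories must belong to the declared set, seasons to the declared
#' season list, and the key (transect, distance, sample point, trap,
#' season, species) must be unique.
#'
#' @param records A data frame with columns `transect`, `distance_m`,
#'   `sample_point`, `trap`, `season`, `species`, `count`.
#' @param design A [survey_design()].
#' @return A data frame of class `trap_table` with the design attached as
#'   attribute `design`.
#' @examples
#' d <- survey_design(n_transects = 1, n_sample_points = 1, n_traps = 2)
#' tab <- trap_table(data.frame(
#'   transect = 1, distance_m = 0, sample_point = 1, trap = 1:2,
#'   season = "wet", species = "spA", count = c(3, 5)), d)
#' nrow(tab)
#' @export
trap_table <- function(records, design = survey_design()) {
  stopifnot(inherits(design, "survey_design"))
  records <- as.data.frame(records)
  missing_cols <- setdiff(TRAP_TABLE_COLUMNS, names(records))
  if (length(missing_cols) > 0)
    stop("trap table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[TRAP_TABLE_COLUMNS]
  line <- seq_len(nrow(records))

  bad <- function(cond, what) {
    if (any(cond))
      stop(sprintf("trap table validation error: %s at row(s) %s", what,
                   paste(utils::head(line[cond], 5), collapse = ", ")),
           call. = FALSE)
  }
  cnt <- records$count
  bad(!is.finite(cnt) | cnt < 0 | cnt != round(cnt),
      "count must be a non-negative integer")
  records$count <- as.integer(round(cnt))
  records$distance_m <- as.integer(records$distance_m)
  bad(!(records$distance_m %in% design$distance_categories_m),
      sprintf("distance_m outside declared categories {%s}",
              paste(design$distance_categories_m, collapse = ", ")))
  bad(!(as.character(records$season) %in% design$seasons),
      sprintf("season outside declared set {%s}",
              paste(design$seasons, collapse = ", ")))
  records$season <- as.character(records$season)
  records$species <- as.character(records$species)
  for (nm in c("transect", "sample_point", "trap")) {
    v <- as.integer(records[[nm]])
    bad(is.na(v) | v < 1, sprintf("%s must be a positive integer identifier", nm))
    records[[nm]] <- v
  }
  bad(records$transect > design$n_transects, "transect exceeds design")
  bad(records$sample_point > design$n_sample_points, "sample_point exceeds design")
  bad(records$trap > design$n_traps, "trap exceeds design")

  key <- do.call(paste, c(records[setdiff(TRAP_TABLE_COLUMNS, "count")], sep = "\r"))
  bad(duplicated(key), "duplicate (transect, distance, point, trap, season, species) key")

  rownames(records) <- NULL
  structure(records, design = design, class = c("trap_table", "data.frame"))
}

#' Read a trap table from delimited text
#'
#' Expects comma-delimited UTF-8 with a header naming the seven required
#' fields (`transect,distance_m,sample_point,trap,season,species,count`).
#' Rows violating the survey design are rejected with row-numbered
#' diagnostics.
#'
#' @param path Path to a CSV file.
#' @param design A [survey_design()] describing the expected hierarchy.
#' @return A `trap_table`.
#' @seealso [write_trap_table()]
#' @export
read_trap_table <- function(path, design = survey_design()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trap_table(raw, design)
}

#' Write a trap table to CSV
#'
#' Inverse of [read_trap_table()]: the written file re-reads to an
#' identical table under the same design.
#'
#' @param table A `trap_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trap_table <- function(table, path) {
  stopifnot(inherits(table, "trap_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.trap_table <- function(x, n = 6, ...) {
  cat(sprintf("Trap table: %d records, %d individuals, %d morphospecies\n",
              nrow(x), sum(x$count), length(unique(x$species))))
  cat(sprintf("  transects %s | seasons %s\n",
              paste(sort(unique(x$transect)), collapse = ","),
              paste(unique(x$season), collapse = ",")))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("  ... %d more records\n", nrow(x) - n))
  invisible(x)
}
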