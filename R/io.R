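# Readers/writers for the pipeline's plain-text table formats. All CSVs are
# comma-separated, header row, UTF-8, "." decimal. Readers validate required
# columns and refuse empty tables with a named error; numeric round-trips are
# faithful to ~15 significant digits.

.read_table <- function(path, required, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop(what, ": malformed header, missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(d) == 0) stop(what, ": empty table: ", path)
  d
}

.write_table <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write pipeline tables
#'
#' Readers validate the required columns of each dialect (plot records,
#' long-format daily weather, soil, county production, BLUEs, cluster
#' assignments) and error on missing files, malformed headers, or empty
#' tables. Writers emit comma-separated UTF-8 with a header row.
#'
#' @param path file path
#' @return The validated data frame (readers) or `path` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_plots <- function(path) {
  .read_table(path, c("genotype", "location", "year", "replicate", "row",
                      "column", "yield"), "plots")
}

#' @rdname table_io
#' @param plots plot records
#' @export
write_plots <- function(plots, path) .write_table(plots, path)

#' @rdname table_io
#' @export
read_weather <- function(path) {
  .read_table(path, c("location", "day", "variable", "value"), "weather")
}

#' @rdname table_io
#' @param weather long-format daily weather
#' @export
write_weather <- function(weather, path) .write_table(weather, path)

#' @rdname table_io
#' @export
read_soil <- function(path) .read_table(path, "location", "soil")

#' @rdname table_io
#' @param soil soil covariate table
#' @export
write_soil <- function(soil, path) .write_table(soil, path)

#' @rdname table_io
#' @export
read_production <- function(path) {
  .read_table(path, c("county", "production_share"), "production")
}

#' @rdname table_io
#' @param production county production table
#' @export
write_production <- function(production, path) .write_table(production, path)

#' @rdname table_io
#' @export
read_blues <- function(path) {
  .read_table(path, c("location", "year", "genotype", "blue", "se"), "blues")
}

#' @rdname table_io
#' @param blues BLUE table
#' @export
write_blues <- function(blues, path) .write_table(blues, path)

#' Read / write a square matrix with row ids (W, kernels, centroids)
#'
#' The first column (`id`) carries row names; remaining columns are numeric.
#'
#' @param M matrix with rownames
#' @param path file path
#' @return The matrix (reader) or `path` invisibly (writer).
#' @export
write_matrix_csv <- function(M, path) {
  d <- data.frame(id = rownames(M), as.data.frame(unclass(M),
                                                  check.names = FALSE),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  d <- .read_table(path, "id", "matrix")
  M <- as.matrix(d[, setdiff(names(d), "id"), drop = FALSE])
  rownames(M) <- d$id
  M
}

#' @rdname table_io
#' @export
read_clusters <- function(path) {
  d <- .read_table(path, c("environment", "cluster"), "clusters")
  stats::setNames(as.integer(d$cluster), d$environment)
}

#' @rdname table_io
#' @param assignments named cluster assignments
#' @export
write_clusters <- function(assignments, path) {
  .write_table(data.frame(environment = names(assignments),
                          cluster = as.integer(assignments)), path)
}
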