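#' Write a beta/expression matrix as a delimited table (probes x samples)
#'
#' The on-disk orientation is features in rows, samples in columns (the
#' array-world convention); in memory this package keeps samples in rows.
#'
#' @param x samples x features matrix.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_matrix <- function(x, path, sep = "\t") {
  df <- data.frame(feature = colnames(x), t(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a delimited feature x sample matrix into samples x features form
#' @param path input path written by \code{\link{write_matrix}}.
#' @param sep field separator.
#' @return samples x features numeric matrix.
#' @export
read_matrix <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  m
}

#' Write / read a sample sheet
#' @param sheet sample sheet data.frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a gene set as one gene per line
#' @param set a \code{\link{gene_set}}.
#' @param path file path.
#' @export
write_gene_set <- function(set, path) {
  writeLines(set$genes, path)
}

#' Write a run manifest (seed + resolved parameters) as JSON
#' @param config list of parameters (a \code{sim_config} or pipeline config).
#' @param path file path.
#' @param seed seed to record.
#' @export
write_manifest <- function(config, path, seed = config$seed) {
  obj <- list(seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
              config = unclass(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
}
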