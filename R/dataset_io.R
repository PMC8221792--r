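#' Read and write dataset tables
#'
#' Tab-separated text with a header row; scalar fields (dataset id, growth
#' rate, productivity, dry mass) travel in `#key<TAB>value` comment lines
#' before the header.
#'
#' @param data an [exchange_dataset()] or `c13_dataset`.
#' @param path file path.
#' @return the reading functions return the reconstructed object;
#'   the writers return `path` invisibly.
#' @name dataset_io
NULL

write_kv_header <- function(kv, path) {
  con <- file(path, "w")
  for (k in names(kv))
    cat("#", k, "\t", format(kv[[k]], digits = 17), "\n", sep = "",
        file = con)
  close(con)
}

read_kv_header <- function(path) {
  lines <- readLines(path)
  kv <- lines[startsWith(lines, "#")]
  parts <- strsplit(sub("^#", "", kv), "\t")
  stats::setNames(lapply(parts, `[`, 2), vapply(parts, `[`, "", 1))
}

#' @rdname dataset_io
#' @export
write_exchange_dataset <- function(data, path) {
  stopifnot(inherits(data, "exchange_dataset"))
  kv <- list(dataset_id = data$dataset_id, growth_rate = data$growth_rate,
             growth_sd = data$growth_sd, productivity = data$productivity,
             productivity_sd = data$productivity_sd,
             dry_mass = data$dry_mass)
  if (!is.null(data$product_aa_composition))
    kv$product_aa_composition <-
      paste(names(data$product_aa_composition),
            data$product_aa_composition, sep = "=", collapse = ",")
  write_kv_header(kv, path)
  suppressWarnings(utils::write.table(data$rates, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_exchange_dataset <- function(path) {
  kv <- read_kv_header(path)
  rates <- utils::read.delim(path, comment.char = "#")
  comp <- NULL
  if (!is.null(kv$product_aa_composition)) {
    parts <- strsplit(strsplit(kv$product_aa_composition, ",")[[1]], "=")
    comp <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                            vapply(parts, `[`, "", 1))
  }
  exchange_dataset(dataset_id = kv$dataset_id,
                   rates = rates,
                   growth_rate = as.numeric(kv$growth_rate),
                   growth_sd = as.numeric(kv$growth_sd),
                   productivity = as.numeric(kv$productivity),
                   productivity_sd = as.numeric(kv$productivity_sd),
                   product_aa_composition = comp,
                   dry_mass = as.numeric(kv$dry_mass))
}

#' @rdname dataset_io
#' @param exchange companion [exchange_dataset()] attached when reading a
#'   13C table.
#' @export
write_c13_dataset <- function(data, path) {
  stopifnot(inherits(data, "c13_dataset"))
  write_kv_header(list(dataset_id = data$dataset_id), path)
  suppressWarnings(utils::write.table(data$fluxes, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_c13_dataset <- function(path, exchange) {
  kv <- read_kv_header(path)
  fluxes <- utils::read.delim(path, comment.char = "#")
  c13_dataset(dataset_id = kv$dataset_id, fluxes = fluxes,
              exchange = exchange)
}
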