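#' Read and write MR datasets
#'
#' The on-disk dialect is a delimited text file with header columns
#' `id, Y, X, Z1..ZJ`; an empty cell or an NA token (`NA`, `nan`) in the `X`
#' column marks a missing exposure. Genotype columns are validated to contain
#' minor-allele counts 0/1/2 unless the sidecar records that the file holds
#' standardized values. `write_mr_data()` optionally writes a JSON sidecar
#' (`<path>.json`) with the standardization constants so a round trip
#' preserves the analysis scale.
#'
#' @param path File path; the delimiter is TAB for `.tsv` and comma for
#'   `.csv`.
#' @return `read_mr_data()` returns an `mr_data`; `write_mr_data()` returns
#'   `path` invisibly.
#' @export
read_mr_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, na = c("", "NA", "nan"),
                          show_col_types = FALSE, progress = FALSE)
  need <- c("Y", "X")
  if (!all(need %in% names(df))) {
    stop("header must contain columns Y, X and Z1..ZJ")
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  standardized <- isTRUE(meta$standardized)
  zcols <- grep("^Z[0-9]+$", names(df), value = TRUE)
  if (length(zcols) < 1L) stop("no instrument columns Z1..ZJ found")
  for (cc in c("Y", zcols)) {
    if (anyNA(df[[cc]])) {
      stop("malformed value in column ", cc, " at line ",
           which(is.na(df[[cc]]))[1L] + 1L)
    }
  }
  d <- mr_data(df, instruments = zcols, validate_genotypes = !standardized)
  d$standardized <- standardized
  if (!is.null(meta$scaling)) d$scaling <- meta$scaling
  d
}

#' @rdname read_mr_data
#' @param x An `mr_data` object.
#' @param sidecar Write the JSON sidecar with scaling constants and
#'   standardization state (default `TRUE`).
#' @export
write_mr_data <- function(x, path, sidecar = TRUE) {
  validate_mr_data(x)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- as_tibble(x)
  readr::write_delim(df, path, delim = delim, na = "")
  if (sidecar) {
    jsonlite::write_json(
      list(standardized = isTRUE(x$standardized),
           scaling = x$scaling,
           n_complete = n_complete(x), n_missing = n_missing(x)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
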