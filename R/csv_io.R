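# CSV ingestion and emission of fish records. Comma-separated, header row,
# '.' decimal separator, UTF-8. Numeric columns are written with 17
# significant digits so that a write/read cycle preserves every double
# bit-exactly.

#' Read a fish dataset from CSV
#'
#' Expects a header with at least `weight_g`, `tc_ratio` and one of
#' `length_cm` / `cf`; optional columns `id`, `species`, `stage`,
#' `dataset`, `sgr`, `sgr_true`. Validation failures (missing mandatory
#' columns, non-numeric or non-positive values) raise errors naming the
#' offending row and column. File row order becomes the stored record
#' order. Missing `cf` is derived from weight and length.
#'
#' @param path CSV file path.
#' @param dataset Optional label for records without a `dataset` value.
#' @return A `fish_dataset`.
#' @seealso [write_fish_csv()], [as_fish_dataset()]
#' @export
read_fish_csv <- function(path, dataset = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_validation("failed to read '%s': %s",
                                        path, conditionMessage(e)))
  as_fish_dataset(raw, dataset = dataset)
}

#' Write a fish dataset to CSV
#'
#' Numeric columns are formatted with 17 significant digits
#' (`"%.17g"`), which a standard CSV reader parses back to the identical
#' doubles; [read_fish_csv()] of the written file reproduces the dataset
#' exactly.
#'
#' @param data A `fish_dataset` (or coercible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fish_csv <- function(data, path) {
  data <- as_fish_dataset(data)
  out <- as.data.frame(data)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}
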