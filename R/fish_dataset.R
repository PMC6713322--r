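# Per-fish tabular records. A fish_dataset is a data.frame with a fixed
# column schema and validated invariants; stored row order is meaningful
# (records are presented to the reservoir in this order).

FISH_COLUMNS <- c("id", "species", "stage", "dataset",
                  "weight_g", "length_cm", "cf", "tc_ratio", "sgr", "sgr_true")
FEATURE_COLUMNS <- c("weight_g", "tc_ratio", "cf")

#' Validate and coerce a data frame of fish records
#'
#' Ensures the per-fish schema used throughout the package: mandatory
#' positive `weight_g` and `tc_ratio`, at least one of `length_cm` / `cf`
#' per row, and optional `sgr` (% day^-1), `sgr_true` (noiseless synthetic
#' ground truth, ignored by training), `id`, `species`, `stage` and
#' `dataset` labels. Missing optional columns are added as `NA`; missing
#' `cf` is derived from weight and length via [condition_factor()]. When
#' both `cf` and `length_cm` are present but disagree by more than 1%
#' relative, a warning is issued and the stored `cf` is kept.
#'
#' @param x A data frame (or `fish_dataset`).
#' @param dataset Optional label written into the `dataset` column where it
#'   is missing.
#' @return A `fish_dataset` (a validated data.frame).
#' @export
as_fish_dataset <- function(x, dataset = NULL) {
  if (!is.data.frame(x)) stop_validation("expected a data.frame of fish records")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_mandatory <- setdiff(c("weight_g", "tc_ratio"), names(x))
  if (length(missing_mandatory)) {
    stop_validation("missing mandatory column(s): %s",
                    paste(missing_mandatory, collapse = ", "))
  }
  if (!("length_cm" %in% names(x)) && !("cf" %in% names(x))) {
    stop_validation("at least one of 'length_cm' or 'cf' must be present")
  }
  for (col in FISH_COLUMNS) {
    if (!(col %in% names(x))) {
      x[[col]] <- if (col %in% c("id", "species", "stage", "dataset"))
        NA_character_ else NA_real_
    }
  }
  if (!is.null(dataset)) {
    x$dataset <- ifelse(is.na(x$dataset), as.character(dataset), x$dataset)
  }
  if (all(is.na(x$id))) x$id <- sprintf("fish%04d", seq_len(nrow(x)))

  for (col in c("weight_g", "length_cm", "cf", "tc_ratio", "sgr", "sgr_true")) {
    if (!is.numeric(x[[col]])) {
      bad <- which(!is.na(x[[col]]) & is.na(suppressWarnings(as.numeric(x[[col]]))))
      if (length(bad)) {
        stop_validation("non-numeric value in column '%s' at row %s",
                        col, paste(bad, collapse = ", "))
      }
      x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
    }
  }
  check_positive <- function(col, required) {
    v <- x[[col]]
    bad <- if (required) which(is.na(v) | v <= 0) else which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop_validation("column '%s' must be positive; offending row(s): %s",
                      col, paste(bad, collapse = ", "))
    }
  }
  check_positive("weight_g", TRUE)
  check_positive("tc_ratio", TRUE)
  check_positive("length_cm", FALSE)
  check_positive("cf", FALSE)
  no_shape <- which(is.na(x$length_cm) & is.na(x$cf))
  if (length(no_shape)) {
    stop_validation("rows missing both 'length_cm' and 'cf': %s",
                    paste(no_shape, collapse = ", "))
  }

  derive <- is.na(x$cf) & !is.na(x$length_cm)
  if (any(derive)) {
    x$cf[derive] <- condition_factor(x$weight_g[derive], x$length_cm[derive])
  }
  both <- !is.na(x$length_cm) & !derive
  if (any(both)) {
    implied <- condition_factor(x$weight_g[both], x$length_cm[both])
    rel <- abs(implied - x$cf[both]) / x$cf[both]
    if (any(rel > 0.01)) {
      warning(sprintf(
        "stored cf and 100*weight/length^3 disagree by >1%% at row(s) %s; keeping stored cf",
        paste(which(both)[rel > 0.01], collapse = ", ")))
    }
  }

  x <- x[, FISH_COLUMNS]
  rownames(x) <- NULL
  class(x) <- c("fish_dataset", "data.frame")
  x
}

#' @export
print.fish_dataset <- function(x, ...) {
  labs <- unique(x$dataset[!is.na(x$dataset)])
  cat(sprintf("<fish_dataset> %d records%s\n", nrow(x),
              if (length(labs)) paste0(" [", paste(labs, collapse = ", "), "]") else ""))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Concatenate fish datasets
#'
#' Row-binds datasets in the given order, keeping each part's `dataset`
#' labels (or assigning the part's name in `parts` where labels are absent).
#' A model trained on the combination computes its normalization ranges —
#' including the SGR range used to emit real-unit estimates — over all parts.
#'
#' @param parts A list of `fish_dataset`s (or coercible data frames).
#' @return A single `fish_dataset` with `sum(n)` records.
#' @export
combine_datasets <- function(parts) {
  if (!is.list(parts) || !length(parts)) {
    stop_validation("parts must be a non-empty list of fish datasets")
  }
  nm <- names(parts)
  parts <- lapply(seq_along(parts), function(i) {
    lab <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else sprintf("part%d", i)
    as_fish_dataset(parts[[i]], dataset = lab)
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  out$id <- make.unique(out$id)
  as_fish_dataset(out)
}

# Features + sgr completeness check used by training/estimation.
check_features <- function(data, features, need_sgr = FALSE) {
  bad_feat <- setdiff(features, FEATURE_COLUMNS)
  if (length(bad_feat)) {
    stop_validation("unknown input feature(s): %s (allowed: %s)",
                    paste(bad_feat, collapse = ", "),
                    paste(FEATURE_COLUMNS, collapse = ", "))
  }
  for (col in c(features, if (need_sgr) "sgr")) {
    bad <- which(is.na(data[[col]]))
    if (length(bad)) {
      stop_validation("column '%s' missing for record(s): %s",
                      col, paste(data$id[bad], collapse = ", "))
    }
  }
  invisible(TRUE)
}
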