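#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper p.adjust rpois runif cor median setNames
#' @importFrom utils read.delim write.table head
NULL

# Zero-padded readable ids: P0001, F0001, HERB01, CID0001
make_ids <- function(prefix, n, width = NULL) {
  if (is.null(width)) width <- max(4L, nchar(as.character(n)))
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}

#' Truncate (not round) to a number of decimal places
#'
#' Table display convention: `trunc_decimals(13.656, 2)` is `13.65`, never
#' `13.66`. Used by the fold-enrichment reporting helper.
#'
#' @param x numeric vector
#' @param digits non-negative integer number of decimals to keep
#' @return numeric vector truncated toward zero at `digits` decimals
#' @export
trunc_decimals <- function(x, digits) {
  stopifnot(is.numeric(x), digits >= 0)
  f <- 10^digits
  trunc(x * f) / f
}

# Read a TSV with mandatory columns; hard error on a missing column or an
# empty file; rows with empty/NA values in required columns are a hard error
# naming the offending row numbers.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- rep(FALSE, nrow(df))
  for (col in required) {
    v <- df[[col]]
    bad <- bad | is.na(v) | !nzchar(trimws(v))
  }
  if (any(bad)) {
    stop("malformed row(s) in ", basename(path), " (missing value in a ",
         "required column): row ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  for (col in required) df[[col]] <- trimws(df[[col]])
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Machine-parseable warning line for dropped/clamped items.
note_drop <- function(stage, what, n, detail = NULL) {
  if (n > 0L) {
    msg <- sprintf("[%s] dropped %d %s", stage, n, what)
    if (!is.null(detail)) msg <- paste0(msg, ": ", detail)
    warning(msg, call. = FALSE)
  }
  invisible(n)
}
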