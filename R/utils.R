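# shared helpers: normalisation, tolerant parsing, tabular input

norm_symbol <- function(x) toupper(trimws(as.character(x)))

# drug names match case-insensitively with punctuation stripped
norm_drug_name <- function(x) gsub("[^a-z0-9]", "", tolower(trimws(as.character(x))))

parse_num <- function(x) suppressWarnings(as.numeric(x))

parse_int <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  out <- suppressWarnings(as.integer(round(v)))
  out[!is.na(v) & abs(v - round(v)) > 1e-9] <- NA_integer_
  out
}

parse_logical <- function(x) {
  u <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(u))
  out[u %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[u %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

is_blank <- function(x) is.na(x) | trimws(as.character(x)) == ""

#' Read a delimited table with all columns as character
#'
#' Accepts a path to a TSV/CSV file or a data frame (coerced column-wise to
#' character so row-level validation is uniform regardless of source types).
#' @noRd
read_table_auto <- function(source) {
  if (is.data.frame(source)) {
    df <- tibble::as_tibble(source)
  } else {
    if (!is.character(source) || length(source) != 1L || !file.exists(source)) {
      stop("input file not found: ", source, call. = FALSE)
    }
    delim <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "," else "\t"
    df <- readr::read_delim(
      source, delim = delim, na = c("", "NA"),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
  }
  dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

sort_unique <- function(x) sort(unique(x))

write_tsv_out <- function(df, path) {
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

# collapse list-columns to ";"-joined strings so a table can be written as TSV
flatten_list_cols <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) paste(unlist(x), collapse = ";"),
                         character(1))
    }
  }
  df
}
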