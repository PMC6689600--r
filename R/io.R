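#' Read and write response matrices and truth labels
#'
#' Response matrices are stored as delimited text: a header row of individual
#' ids, a first column of question ids, and a numeric body. Truth files have
#' two columns (question id, 0/1 label), with or without a header. Tab is the
#' default delimiter; pass `delim = ","` for CSV.
#'
#' @param path File path.
#' @param delim Field delimiter; `"\t"` (default) or `","`.
#' @param state Optional state override passed to [response_matrix()]; by
#'   default binary matrices (all values 0/1, both present) are detected
#'   automatically.
#' @return `read_response_matrix()` a [response_matrix()];
#'   `read_ground_truth()` a [ground_truth()].
#' @export
read_response_matrix <- function(path, delim = "\t", state = NULL) {
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) abort("Expected a question-id column plus individual columns.")
  names(df)[1] <- "question"
  for (j in seq(2, ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        abort(sprintf("Non-numeric cell at (%s, %s): '%s'",
                      df$question[bad[1]], names(df)[j], col[bad[1]]))
      }
      df[[j]] <- num
    }
    if (anyNA(df[[j]])) {
      abort(sprintf("missing value at (%s, %s)",
                    df$question[which(is.na(df[[j]]))[1]], names(df)[j]))
    }
  }
  response_matrix(df, state = state)
}

#' @rdname read_response_matrix
#' @param x Object to write.
#' @export
write_response_matrix <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "response_matrix"))
  readr::write_delim(tibble::as_tibble(as.data.frame(x)), path, delim = delim)
  invisible(path)
}

#' @rdname read_response_matrix
#' @export
read_ground_truth <- function(path, delim = "\t") {
  first <- readr::read_lines(path, n_max = 1)
  if (!grepl(delim, first, fixed = TRUE) && grepl(",", first, fixed = TRUE)) delim <- ","
  fields <- strsplit(trimws(first), delim, fixed = TRUE)[[1]]
  has_header <- length(fields) >= 2 &&
    is.na(suppressWarnings(as.numeric(fields[2])))
  df <- readr::read_delim(path, delim = delim, col_names = has_header,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
  ground_truth(df)
}

#' @rdname read_response_matrix
#' @export
write_ground_truth <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "ground_truth"))
  readr::write_delim(tibble::as_tibble(as.data.frame(x)), path, delim = delim)
  invisible(path)
}
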