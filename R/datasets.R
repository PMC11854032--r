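# Packaged reliability datasets and plain-text numeric vector input.

.nlw_dataset_info <- list(
  failure_times = list(n = 84L,
    note = "failure times of 84 aircraft windshields (thousand hours)"),
  gauge_lengths = list(n = 63L,
    note = "63 gauge lengths of 10 mm carbon fibre specimens"),
  strength = list(n = 63L,
    note = "63 strength measurements"),
  student_grades = list(n = 48L,
    note = "mathematics scores of 48 students (slow pace program, 2013)"))

#' Packaged reliability datasets
#'
#' Four classical univariate lifetime/score datasets shipped as plain
#' text: `failure_times` (84 aircraft windshield failure times),
#' `gauge_lengths` (63 carbon-fibre gauge lengths), `strength` (63
#' strength values) and `student_grades` (48 mathematics scores).
#'
#' @param key dataset name; see `nlw_datasets()` for the available keys.
#' @return `load_dataset` returns the numeric data vector with attributes
#'   `name` and `note`; `nlw_datasets` the character vector of keys.
#' @examples
#' length(load_dataset("failure_times"))   # 84
#' @export
load_dataset <- function(key) {
  if (!is.character(key) || length(key) != 1L ||
      !key %in% names(.nlw_dataset_info))
    stop("unknown dataset '", paste(key, collapse = ","), "'; available: ",
         paste(names(.nlw_dataset_info), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(key, ".txt"), package = "nlwdist",
                      mustWork = TRUE)
  x <- read_numeric_vector(path)
  stopifnot(length(x) == .nlw_dataset_info[[key]]$n)
  attr(x, "name") <- key
  attr(x, "note") <- .nlw_dataset_info[[key]]$note
  x
}

#' @rdname load_dataset
#' @export
nlw_datasets <- function() names(.nlw_dataset_info)

#' Read a numeric vector from a delimited text file
#'
#' Values may be separated by whitespace and/or commas and spread over
#' any number of lines. Lines starting with `#` are comments. A single
#' leading non-numeric header line is skipped automatically; any other
#' non-numeric token is an error naming the token and its line.
#'
#' @param path path to an existing file.
#' @return Numeric vector in file order.
#' @examples
#' f <- tempfile(); writeLines("1.0 2.0, 3.0", f)
#' read_numeric_vector(f)
#' @export
read_numeric_vector <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data in file: ", path, call. = FALSE)
  toks <- lapply(lines, function(l)
    Filter(nzchar, strsplit(trimws(l), "[,[:space:]]+")[[1L]]))
  parse_line <- function(t) suppressWarnings(as.numeric(t))
  vals <- lapply(toks, parse_line)
  bad <- which(vapply(vals, anyNA, logical(1L)))
  if (length(bad) && bad[1L] == 1L && length(bad) == 1L && length(toks) > 1L) {
    # single leading header line
    toks <- toks[-1L]; vals <- vals[-1L]; lineno <- lineno[-1L]
    bad <- which(vapply(vals, anyNA, logical(1L)))
  }
  if (length(bad)) {
    i <- bad[1L]
    tok <- toks[[i]][which(is.na(vals[[i]]))[1L]]
    stop("cannot parse token '", tok, "' on line ", lineno[i], " of ",
         path, call. = FALSE)
  }
  out <- unlist(vals, use.names = FALSE)
  if (!length(out)) stop("no data in file: ", path, call. = FALSE)
  if (!all(is.finite(out)))
    stop("non-finite value in ", path, call. = FALSE)
  out
}
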