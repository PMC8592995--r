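#' Protein-by-sample quantification table
#'
#' A `quant_table` is a non-negative numeric matrix with proteins as rows and
#' samples as columns. Missing quantifications (a protein not observed in a
#' sample) are `NA`. Intensities are in arbitrary abundance units, typically
#' summed MS1 spectral intensities spanning roughly 1e4 to 3e9.
#'
#' @param x numeric matrix with unique, non-empty rownames (protein ids) and
#'   colnames (sample ids); entries non-negative or `NA`.
#' @return `x` with class `quant_table` prepended, after validation.
#' @examples
#' m <- matrix(c(1e6, NA, 2e5, 3e5), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' quant_table(m)
#' @export
quant_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("quant_table: `x` must be a numeric matrix", call. = FALSE)
  }
  if (ncol(x) < 1L) stop("quant_table: at least one sample is required", call. = FALSE)
  pid <- rownames(x)
  sid <- colnames(x)
  if (is.null(pid) || anyNA(pid) || any(pid == "")) {
    stop("quant_table: rownames (protein ids) are required", call. = FALSE)
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop("quant_table: colnames (sample ids) are required", call. = FALSE)
  }
  if (anyDuplicated(pid)) {
    stop("quant_table: duplicate protein id(s): ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("quant_table: duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) {
    stop("quant_table: negative intensities are not allowed", call. = FALSE)
  }
  class(x) <- c("quant_table", class(matrix()))
  x
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  n <- min(nrow(x), 6L)
  print(unclass(x)[seq_len(n), , drop = FALSE])
  if (nrow(x) > n) cat(sprintf("... %d more proteins\n", nrow(x) - n))
  invisible(x)
}

#' Read a quantification table from tab-separated text
#'
#' The expected layout is one header row of sample ids, one row per protein,
#' first column the protein id. Empty cells are read as missing (`NA`).
#' Lines starting with `#` are treated as comments and skipped.
#'
#' @param path path to a tab-separated file.
#' @return a [quant_table()].
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("read_quant_table: file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("read_quant_table: need a protein id column plus >= 1 sample", call. = FALSE)
  pid <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- pid
  quant_table(m)
}

#' Write a quantification table as tab-separated text
#'
#' Missing entries are written as empty cells. Optional `comments` are written
#' first, each prefixed with `# `.
#'
#' @param table a [quant_table()] (or compatible matrix).
#' @param path output path.
#' @param comments optional character vector of header comment lines.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path, comments = NULL) {
  table <- quant_table(as.matrix(table))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("protein_id", colnames(table)), collapse = "\t"), con)
  body <- apply(unclass(table), 1L, function(row) {
    txt <- formatC(row, format = "g", digits = 15)
    txt[is.na(row)] <- ""
    paste(txt, collapse = "\t")
  })
  writeLines(paste(rownames(table), body, sep = "\t"), con)
  invisible(path)
}
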