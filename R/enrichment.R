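#' Gene-set collections
#'
#' A `gene_set_collection` is a named list of character vectors (term id ->
#' member identifiers) with an optional parallel vector of descriptions.
#' Members are de-duplicated within each term; empty terms are rejected.
#'
#' @param sets named list of character vectors of member ids.
#' @param descriptions optional character vector, same length/names as
#'   `sets`; defaults to the term ids.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("gene_set_collection: `sets` must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("gene_set_collection: duplicate term id(s)", call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) {
    stop("gene_set_collection: empty member list(s)", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- names(sets)
  if (length(descriptions) != length(sets)) {
    stop("gene_set_collection: descriptions length mismatch", call. = FALSE)
  }
  structure(sets, descriptions = stats::setNames(as.character(descriptions), names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, member counts %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one term per line as
#' `term_id <TAB> description <TAB> member1 <TAB> member2 ...`. Reading is
#' delegated to [fgsea::gmtPathways()] (which discards the description
#' column); writing emits the collection's stored descriptions.
#'
#' @param path file path.
#' @param collection a [gene_set_collection()].
#' @return `read_gmt()` returns a [gene_set_collection()]; `write_gmt()`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path, call. = FALSE)
  gene_set_collection(fgsea::gmtPathways(path))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(term) {
    paste(c(term, desc[[term]], collection[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Overrepresentation analysis by the hypergeometric upper tail
#'
#' Tests each annotation term for overrepresentation of `query` within
#' `universe`: with `N = |universe|`, `K = |term members in universe|`,
#' `n = |query|` and `k = |term members in query|`, the p-value is the
#' upper-tail hypergeometric probability `P(X >= k)`. Terms with fewer than
#' `min_term_size` members in the universe are excluded from testing;
#' q-values are Benjamini-Hochberg over the tested terms.
#'
#' @param query character vector of proteins of interest; must be a subset
#'   of `universe`.
#' @param universe character vector of all quantified proteins (the
#'   background).
#' @param collection a [gene_set_collection()].
#' @param min_term_size minimum in-universe term size to test (default 3).
#' @param alpha significance level recorded alongside the rows (default
#'   0.05); does not filter the output.
#' @return data.frame sorted by ascending p-value with columns `term`,
#'   `description`, `universe_size`, `term_size`, `query_size`, `overlap`,
#'   `p_value`, `q_value`, `neglog10_p` (base-10).
#' @export
ora <- function(query, universe, collection, min_term_size = 3, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) stop("ora: empty universe", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("ora: query protein(s) not in universe: ",
         paste(utils::head(outside, 5L), collapse = ", "),
         if (length(outside) > 5L) sprintf(" (+%d more)", length(outside) - 5L),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], universe)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, description = desc[[term]],
               universe_size = N, term_size = K, query_size = n, overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), description = character(),
                      universe_size = integer(), term_size = integer(),
                      query_size = integer(), overlap = integer(),
                      p_value = double(), q_value = double(),
                      neglog10_p = double(), stringsAsFactors = FALSE)
    attr(out, "alpha") <- alpha
    return(out)
  }
  out$q_value <- bh_fdr(out$p_value)
  out$neglog10_p <- -log10(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegated to [stats::p.adjust()] with `method = "BH"`). Input order is
#' preserved.
#'
#' @param p_values numeric vector of p-values, all in (0, 1].
#' @return q-values, same length and order as `p_values`.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) stop("bh_fdr: numeric p-values required", call. = FALSE)
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Significance heatmap matrix of -log10 p-values
#'
#' Builds the term-by-condition matrix used for enrichment heatmaps: a cell
#' holds `-log10(p)` when `p < alpha` (strict) and 0 otherwise, and only
#' terms significant in at least one condition are kept.
#'
#' @param results named list of [ora()] result data.frames, one per
#'   condition; names become column names.
#' @param alpha significance cutoff (default 0.05, strict inequality).
#' @return numeric matrix (possibly 0-row) of terms x conditions.
#' @export
neglog_p_matrix <- function(results, alpha = 0.05) {
  if (!is.list(results) || is.null(names(results)) || any(names(results) == "")) {
    stop("neglog_p_matrix: `results` must be a named list of ora() tables",
         call. = FALSE)
  }
  terms <- unique(unlist(lapply(results, function(r) r$term)))
  m <- matrix(0, length(terms), length(results),
              dimnames = list(terms, names(results)))
  for (cond in names(results)) {
    r <- results[[cond]]
    sig <- r$p_value < alpha
    m[r$term[sig], cond] <- -log10(r$p_value[sig])
  }
  m[rowSums(m > 0) > 0, , drop = FALSE]
}
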