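#' Ternary dose-response pattern codes
#'
#' A pattern code summarizes a protein's response to an increasing androgen
#' dose series as one ternary digit per treated dose relative to the vehicle
#' baseline: `"d"` (down), `"s"` (same/unchanged) or `"u"` (up). A 3-dose
#' design therefore admits 3^3 = 27 theoretical patterns. Codes are stored as
#' compact strings, e.g. `"sdd"` = unchanged at the lowest dose, decreased at
#' the two higher doses.
#'
#' Codes map to integer indices by base-3 encoding with d = 0, s = 1, u = 2
#' and the first dose as the most significant digit, so `"ddd"` has index 0
#' and `"sss"` (flat) has index 13 in the 3-dose frame.
#'
#' @param code pattern string(s) over the alphabet `d`, `s`, `u`.
#' @param index integer index(es) in `[0, 3^n_doses)`.
#' @param n_doses number of treated doses (digits).
#' @return `pattern_index()` returns integer indices; `pattern_from_index()`
#'   returns code strings; `pattern_digits()` returns a character vector of
#'   `"down"`/`"same"`/`"up"` labels for a single code.
#' @name pattern_code
NULL

.pattern_alphabet <- c(d = 0L, s = 1L, u = 2L)

.check_pattern_code <- function(code) {
  if (!is.character(code) || !length(code)) {
    stop("pattern code must be a character vector", call. = FALSE)
  }
  chars <- strsplit(code, "", fixed = TRUE)
  ok <- vapply(chars, function(ch) length(ch) > 0 && all(ch %in% names(.pattern_alphabet)),
               logical(1))
  if (!all(ok)) {
    stop("invalid pattern code(s): ", paste(code[!ok], collapse = ", "),
         " (alphabet is d/s/u)", call. = FALSE)
  }
  chars
}

#' @rdname pattern_code
#' @export
pattern_index <- function(code) {
  chars <- .check_pattern_code(code)
  vapply(chars, function(ch) {
    as.integer(sum(.pattern_alphabet[ch] * 3^rev(seq_along(ch) - 1L)))
  }, integer(1))
}

#' @rdname pattern_code
#' @export
pattern_from_index <- function(index, n_doses = 3) {
  if (any(index < 0 | index >= 3^n_doses)) {
    stop("pattern index out of range [0, 3^n_doses)", call. = FALSE)
  }
  vapply(as.integer(index), function(i) {
    digits <- integer(n_doses)
    for (pos in seq_len(n_doses)) {
      digits[n_doses - pos + 1L] <- i %% 3L
      i <- i %/% 3L
    }
    paste(names(.pattern_alphabet)[digits + 1L], collapse = "")
  }, character(1))
}

#' @rdname pattern_code
#' @export
pattern_digits <- function(code) {
  stopifnot(length(code) == 1L)
  ch <- .check_pattern_code(code)[[1L]]
  c(d = "down", s = "same", u = "up")[ch]
}

#' Enumerate all theoretical dose-response patterns
#'
#' Returns every ternary direction code for `n_doses` treated doses, in
#' ascending index order: 27 codes for the canonical 3-dose frame.
#'
#' @param n_doses number of treated doses; must be >= 1.
#' @return character vector of 3^`n_doses` distinct pattern codes.
#' @examples
#' length(enumerate_theoretical_patterns(3)) # 27
#' @export
enumerate_theoretical_patterns <- function(n_doses = 3) {
  if (length(n_doses) != 1L || is.na(n_doses) || n_doses < 1) {
    stop("enumerate_theoretical_patterns: n_doses must be >= 1", call. = FALSE)
  }
  pattern_from_index(seq_len(3^n_doses) - 1L, n_doses = n_doses)
}

#' Dose design for direction coding
#'
#' Declares which sample is the vehicle baseline (0 nM), the ordered treated
#' samples (e.g. 0.1, 1.0 and 10 nM R1881), and which treated position is the
#' supraphysiologic dose (SPA; default the last).
#'
#' @param baseline sample id of the vehicle (0 nM) column.
#' @param treated ordered character vector of treated sample ids.
#' @param spa_index position of the supraphysiologic dose within `treated`.
#' @return an object of class `dose_design`.
#' @export
dose_design <- function(baseline, treated, spa_index = length(treated)) {
  if (length(baseline) != 1L) stop("dose_design: one baseline sample", call. = FALSE)
  if (baseline %in% treated) {
    stop("dose_design: baseline must not appear among treated samples", call. = FALSE)
  }
  if (length(treated) < 1L) stop("dose_design: >= 1 treated sample required", call. = FALSE)
  if (anyDuplicated(treated)) stop("dose_design: duplicate treated samples", call. = FALSE)
  if (spa_index < 1 || spa_index > length(treated)) {
    stop("dose_design: spa_index out of range", call. = FALSE)
  }
  structure(list(baseline = as.character(baseline),
                 treated = as.character(treated),
                 spa_index = as.integer(spa_index)),
            class = "dose_design")
}

#' Direction-coding parameters
#'
#' @param fold_threshold ratio above which a dose counts as "up" (and below
#'   whose reciprocal as "down"); must exceed 1. Default 1.5. Boundaries are
#'   inclusive toward "changed".
#' @param missing_policy what to do when a treated intensity is missing:
#'   `"drop-protein"` (code the protein as `NA`), `"treat-as-down"` (absence
#'   read as loss of the protein at that dose) or `"error"`.
#' @return an object of class `direction_params`.
#' @export
direction_params <- function(fold_threshold = 1.5,
                             missing_policy = c("drop-protein", "treat-as-down", "error")) {
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      !is.finite(fold_threshold) || fold_threshold <= 1) {
    stop("direction_params: fold_threshold must be a single number > 1", call. = FALSE)
  }
  structure(list(fold_threshold = fold_threshold,
                 missing_policy = match.arg(missing_policy)),
            class = "direction_params")
}

#' Code one dose-response profile as a ternary pattern
#'
#' A treated dose is `"u"` if `intensity / baseline >= fold_threshold`, `"d"`
#' if the ratio is `<= 1/fold_threshold`, and `"s"` otherwise. The call is
#' invariant under rescaling the whole profile by a positive constant.
#'
#' @param baseline vehicle intensity (must be present and > 0 unless the
#'   missing policy tolerates it).
#' @param treated numeric vector of intensities at the treated doses, in dose
#'   order; may contain `NA`.
#' @param params a [direction_params()] object.
#' @return a single pattern code string, or `NA_character_` when the protein
#'   is dropped under the `"drop-protein"` policy.
#' @examples
#' call_directions(9.66e7, c(9.03e7, 2.48e7, 3.06e7)) # "sdd"
#' @export
call_directions <- function(baseline, treated, params = direction_params()) {
  if (!inherits(params, "direction_params")) {
    stop("`params` must come from direction_params()", call. = FALSE)
  }
  if (length(baseline) != 1L || !is.numeric(treated)) {
    stop("call_directions: one baseline value and a numeric treated vector",
         call. = FALSE)
  }
  if (is.na(baseline) || baseline <= 0) {
    if (params$missing_policy == "error") {
      stop("call_directions: baseline intensity missing or non-positive", call. = FALSE)
    }
    return(NA_character_)
  }
  if (anyNA(treated)) {
    if (params$missing_policy == "error") {
      stop("call_directions: missing treated intensity", call. = FALSE)
    }
    if (params$missing_policy == "drop-protein") return(NA_character_)
  }
  ratio <- treated / baseline
  digit <- ifelse(is.na(ratio), "d",             # treat-as-down
                  ifelse(ratio >= params$fold_threshold, "u",
                         ifelse(ratio <= 1 / params$fold_threshold, "d", "s")))
  paste(digit, collapse = "")
}

#' Direction-code every protein of a quantification table
#'
#' Applies [call_directions()] row-wise under a [dose_design()] and flags
#' which called patterns are SPA-associated (see [select_spa_associated()]).
#'
#' @param table a [quant_table()] containing the design's samples.
#' @param design a [dose_design()].
#' @param params a [direction_params()].
#' @return data.frame with columns `protein_id`, `pattern`, `index`,
#'   `spa_associated`; proteins dropped by the missing policy carry `NA`s.
#' @export
pattern_table <- function(table, design, params = direction_params()) {
  table <- quant_table(as.matrix(table))
  stopifnot(inherits(design, "dose_design"))
  samples <- c(design$baseline, design$treated)
  absent <- setdiff(samples, colnames(table))
  if (length(absent)) {
    stop("pattern_table: design sample(s) not in table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  codes <- vapply(seq_len(nrow(table)), function(i) {
    call_directions(unclass(table)[i, design$baseline],
                    unclass(table)[i, design$treated], params)
  }, character(1))
  spa_set <- select_spa_associated(enumerate_theoretical_patterns(length(design$treated)),
                                   design)
  data.frame(protein_id = rownames(table),
             pattern = codes,
             index = ifelse(is.na(codes), NA_integer_, pattern_index(ifelse(is.na(codes), "s", codes))),
             spa_associated = !is.na(codes) & codes %in% spa_set,
             stringsAsFactors = FALSE)
}

#' Select SPA-associated patterns
#'
#' A pattern is associated with the supraphysiologic-androgen (SPA) response
#' when its SPA digit differs from the digit at every other (proliferative)
#' treated dose -- the SPA response is discordant with both
#' proliferation-stimulating doses and hence concordant with the
#' non-proliferative baseline state. In the 3-dose frame exactly 12 of the 27
#' theoretical patterns qualify.
#'
#' @param patterns character vector of pattern codes of equal length.
#' @param design a [dose_design()] supplying the SPA position.
#' @return the qualifying subset of `patterns`, order preserved.
#' @examples
#' length(select_spa_associated(enumerate_theoretical_patterns(3),
#'                              dose_design("0", c("0.1", "1.0", "10")))) # 12
#' @export
select_spa_associated <- function(patterns, design) {
  stopifnot(inherits(design, "dose_design"))
  chars <- .check_pattern_code(patterns)
  spa <- design$spa_index
  keep <- vapply(chars, function(ch) {
    if (spa > length(ch)) stop("pattern has no digit at the SPA position", call. = FALSE)
    all(ch[-spa] != ch[spa])
  }, logical(1))
  patterns[keep]
}
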