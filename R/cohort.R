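#' Cohort design: sample-to-group assignments with optional pairing
#'
#' Declares the tissue group (e.g. NAT, BPH, PCa, mPCa) or cell-line dose
#' label of every sample, and optionally pairs each tumor sample with the
#' normal-adjacent-tissue (NAT) sample of the same case via a shared
#' `pair_id`. A pair must consist of exactly one NAT sample and one
#' non-NAT sample.
#'
#' @param sample_id character vector of sample ids (unique).
#' @param group character vector of group labels, parallel to `sample_id`.
#' @param pair_id optional character vector of case ids linking a tumor
#'   sample to its NAT sample; `NA` for unpaired samples.
#' @return data.frame of class `cohort_design` with columns `sample_id`,
#'   `group`, `pair_id`.
#' @export
cohort_design <- function(sample_id, group, pair_id = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) {
    stop("cohort_design: sample_id and group lengths differ", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("cohort_design: duplicate sample id(s)", call. = FALSE)
  }
  if (is.null(pair_id)) pair_id <- rep(NA_character_, length(sample_id))
  pair_id <- as.character(pair_id)
  if (length(pair_id) != length(sample_id)) {
    stop("cohort_design: pair_id length mismatch", call. = FALSE)
  }
  paired <- !is.na(pair_id)
  if (any(paired)) {
    tab <- table(pair_id[paired])
    if (any(tab != 2L)) {
      stop("cohort_design: each pair_id must link exactly two samples",
           call. = FALSE)
    }
    for (pid in names(tab)) {
      grp <- group[paired & pair_id == pid]
      if (sum(grp == "NAT") != 1L) {
        stop("cohort_design: pair ", pid,
             " must link one NAT sample with one tumor sample", call. = FALSE)
      }
    }
  }
  structure(data.frame(sample_id = sample_id, group = group, pair_id = pair_id,
                       stringsAsFactors = FALSE),
            class = c("cohort_design", "data.frame"))
}

#' Read a cohort design from tab-separated text
#'
#' Expects columns `sample_id`, `group` and optionally `pair_id`.
#'
#' @param path file path.
#' @return a [cohort_design()].
#' @export
read_cohort_design <- function(path) {
  if (!file.exists(path)) stop("read_cohort_design: file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("read_cohort_design: columns sample_id and group are required", call. = FALSE)
  }
  cohort_design(df$sample_id, df$group,
                if ("pair_id" %in% names(df)) df$pair_id else NULL)
}

#' Capped log display transform for expression heatmaps
#'
#' Maps intensities onto the 0-to-`cap` display scale used for expression
#' clustergrams: missing values (undetectable expression) map to 0; present
#' intensities are log10-transformed (with a pseudo-intensity offset),
#' shifted so that the table's smallest positive intensity sits at the
#' bottom of the scale, floored at 0 and saturated at `cap` (default 5,
#' i.e. black at no expression through saturation five decades up).
#' The transform is monotone in the intensity below the cap.
#'
#' Note the display convention differs from the statistics: contrasts in
#' [group_contrast()] exclude missing values rather than treating them as 0,
#' to avoid inflating fold changes.
#'
#' @param table a [quant_table()].
#' @param cap saturation value on the display scale (default 5).
#' @param pseudo_intensity positive offset added before the log (default 1).
#' @param floor_log10 log10 intensity mapped to 0; default the log10 of the
#'   smallest positive intensity in the table.
#' @return numeric matrix on the display scale, same dimensions as `table`.
#' @export
log_cap_transform <- function(table, cap = 5, pseudo_intensity = 1,
                              floor_log10 = NULL) {
  table <- quant_table(as.matrix(table))
  if (cap <= 0) stop("log_cap_transform: cap must be > 0", call. = FALSE)
  x <- unclass(table)
  if (is.null(floor_log10)) {
    pos <- x[!is.na(x) & x > 0]
    floor_log10 <- if (length(pos)) log10(min(pos) + pseudo_intensity) else 0
  }
  out <- pmin(pmax(log10(x + pseudo_intensity) - floor_log10, 0), cap)
  out[is.na(x)] <- 0
  out
}

#' Pearson-correlation distance
#'
#' Distance `1 - r` between two numeric vectors, computed over
#' pairwise-complete positions; ranges from 0 (perfect positive correlation)
#' to 2 (perfect anticorrelation). Invariant under positive affine
#' transforms of either vector.
#'
#' @param x,y numeric vectors of equal length.
#' @return a single number in `[0, 2]`.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pearson_distance: vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) {
    stop("pearson_distance: fewer than 2 complete pairs", call. = FALSE)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("pearson_distance: zero variance on complete pairs", call. = FALSE)
  }
  1 - stats::cor(x[ok], y[ok])
}

# All-pairs Pearson distance for the rows of a matrix; errors name the first
# offending pair so degenerate inputs are not silently clustered.
.pearson_dist_matrix <- function(m) {
  labs <- rownames(m)
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  if (anyNA(r)) {
    idx <- which(is.na(r), arr.ind = TRUE)[1L, ]
    # recompute the offending pair for the precise error
    pearson_distance(m[idx[1L], ], m[idx[2L], ])
    stop("pearson distance undefined for pair (", labs[idx[1L]], ", ",
         labs[idx[2L]], ")", call. = FALSE)
  }
  stats::as.dist(1 - r)
}

#' Supervised hierarchical clustering with Pearson distance
#'
#' Agglomerative complete-linkage clustering (via [stats::hclust()]) of the
#' rows (proteins; default, the supervised convention with sample columns
#' fixed) or columns of an expression matrix, using `1 - r` Pearson
#' correlation distance on pairwise-complete values. Merge heights are the
#' maximum cross-pair distances and are non-decreasing.
#'
#' @param m numeric matrix (e.g. from [log_cap_transform()]).
#' @param axis `"rows"` (default) or `"columns"`.
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return object of class `glyco_dendrogram`: list with `merge`, `height`,
#'   `order`, `labels` and the underlying `hclust` fit.
#' @export
hierarchical_cluster <- function(m, axis = c("rows", "columns"),
                                 linkage = "complete") {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2L) {
    stop("hierarchical_cluster: need >= 2 items on the clustered axis",
         call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  d <- .pearson_dist_matrix(m)
  hc <- stats::hclust(d, method = linkage)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "glyco_dendrogram")
}

#' @export
print.glyco_dendrogram <- function(x, ...) {
  cat(sprintf("glyco_dendrogram: %d leaves, %d merges, height range [%.3g, %.3g]\n",
              length(x$labels), length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

#' Export a dendrogram as a Newick string or merge table
#'
#' `dendrogram_newick()` writes the tree with merge heights as cumulative
#' branch lengths (via [ape::as.phylo()]); `dendrogram_merge_table()`
#' returns the flat merge list (negative entries index leaves, positive
#' entries earlier merges, following the [stats::hclust()] convention).
#'
#' @param dendro a [hierarchical_cluster()] result.
#' @param path optional file to write the Newick string to.
#' @return `dendrogram_newick()` returns the Newick string (invisibly when
#'   `path` is given); `dendrogram_merge_table()` returns a data.frame with
#'   columns `node_a`, `node_b`, `height`.
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "glyco_dendrogram"))
  phy <- ape::as.phylo(dendro$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname dendrogram_newick
#' @export
dendrogram_merge_table <- function(dendro) {
  stopifnot(inherits(dendro, "glyco_dendrogram"))
  data.frame(node_a = dendro$merge[, 1L], node_b = dendro$merge[, 2L],
             height = dendro$height)
}

#' Per-protein log10 fold change between two sample groups
#'
#' For every protein, the mean of `log10(intensity + pseudo_intensity)` over
#' group `a` samples minus the same mean over group `b` samples. Missing
#' intensities are excluded from the means (not imputed as zero); the number
#' of quantifying samples per group is reported. Antisymmetric in its group
#' arguments.
#'
#' @param table a [quant_table()].
#' @param design a [cohort_design()] covering the table's samples.
#' @param group_a,group_b group labels (each may be a vector of labels to
#'   pool, e.g. `c("PCa", "mPCa")`).
#' @param pseudo_intensity positive offset added before the log (default 1).
#' @return data.frame with columns `protein_id`, `log10_fc`, `n_a`, `n_b`.
#' @export
group_contrast <- function(table, design, group_a, group_b,
                           pseudo_intensity = 1) {
  table <- quant_table(as.matrix(table))
  stopifnot(inherits(design, "cohort_design"))
  unknown <- setdiff(c(group_a, group_b), design$group)
  if (length(unknown)) {
    stop("group_contrast: unknown group label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cols_a <- intersect(design$sample_id[design$group %in% group_a], colnames(table))
  cols_b <- intersect(design$sample_id[design$group %in% group_b], colnames(table))
  if (!length(cols_a) || !length(cols_b)) {
    stop("group_contrast: both groups must have samples in the table", call. = FALSE)
  }
  lx <- log10(unclass(table) + pseudo_intensity)
  mean_a <- rowMeans(lx[, cols_a, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(lx[, cols_b, drop = FALSE], na.rm = TRUE)
  data.frame(protein_id = rownames(table),
             log10_fc = mean_a - mean_b,
             n_a = rowSums(!is.na(lx[, cols_a, drop = FALSE])),
             n_b = rowSums(!is.na(lx[, cols_b, drop = FALSE])),
             stringsAsFactors = FALSE)
}

#' Candidate biomarker triage: androgen-regulated and tumor-upregulated
#'
#' Formalizes the screen for cell-line glycoproteins whose expression
#' responds to androgen dose and which are also upregulated in cancerous
#' tissue. A protein passes when (1) its cell-line dose pattern is non-flat
#' (not all-"same"), (2) its tumor (PCa and mPCa pooled) vs BPH log10 fold
#' change is at least `min_log10_fc`, and (3) when `require_pairs = TRUE`,
#' the median paired tumor-minus-NAT log10 difference is positive.
#' Candidates are ranked by the tumor-vs-BPH contrast, descending.
#'
#' @param cell_line_patterns named character vector of pattern codes per
#'   protein (e.g. the `pattern` column of [pattern_table()]).
#' @param tissue a [quant_table()] of tissue intensities.
#' @param design a [cohort_design()] for the tissue samples.
#' @param min_log10_fc minimum tumor-vs-BPH log10 fold change (default 0.5).
#' @param require_pairs additionally require positive median paired
#'   tumor-NAT difference (default `FALSE`).
#' @param pseudo_intensity positive offset added before logs (default 1).
#' @return data.frame sorted by descending `rank_score`, columns
#'   `protein_id`, `cell_line_pattern`, `tumor_vs_bph_log10_fc`,
#'   `tumor_vs_nat_log10_fc` (`NA` when unpaired), `passes`, `rank_score`.
#' @export
candidate_biomarkers <- function(cell_line_patterns, tissue, design,
                                 min_log10_fc = 0.5, require_pairs = FALSE,
                                 pseudo_intensity = 1) {
  tissue <- quant_table(as.matrix(tissue))
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(names(cell_line_patterns))) {
    stop("candidate_biomarkers: cell_line_patterns must be named by protein",
         call. = FALSE)
  }
  shared <- intersect(names(cell_line_patterns), rownames(tissue))
  if (!length(shared)) {
    stop("candidate_biomarkers: no proteins shared between the cell-line ",
         "patterns and the tissue table", call. = FALSE)
  }
  tumor_groups <- intersect(c("PCa", "mPCa"), design$group)
  if (!length(tumor_groups) || !"BPH" %in% design$group) {
    stop("candidate_biomarkers: design must contain BPH and PCa/mPCa samples",
         call. = FALSE)
  }
  fc <- group_contrast(tissue, design, tumor_groups, "BPH", pseudo_intensity)
  fc <- stats::setNames(fc$log10_fc, fc$protein_id)[shared]

  paired_med <- stats::setNames(rep(NA_real_, length(shared)), shared)
  pairs <- design[!is.na(design$pair_id), , drop = FALSE]
  if (nrow(pairs)) {
    lx <- log10(unclass(tissue) + pseudo_intensity)
    diffs <- list()
    for (pid in unique(pairs$pair_id)) {
      two <- pairs[pairs$pair_id == pid, ]
      nat <- two$sample_id[two$group == "NAT"]
      tum <- two$sample_id[two$group != "NAT"]
      if (!all(c(nat, tum) %in% colnames(tissue))) next
      diffs[[pid]] <- lx[shared, tum] - lx[shared, nat]
    }
    if (length(diffs)) {
      dm <- do.call(cbind, diffs)
      med <- apply(dm, 1L, stats::median, na.rm = TRUE)
      med[is.nan(med)] <- NA_real_
      paired_med <- stats::setNames(med, shared)
    }
  }

  patt <- as.character(cell_line_patterns[shared])
  flat <- vapply(patt, function(p) {
    if (is.na(p)) return(NA)
    identical(p, strrep("s", nchar(p)))
  }, logical(1))
  passes <- !is.na(patt) & !flat & !is.na(fc) & fc >= min_log10_fc
  if (require_pairs) passes <- passes & !is.na(paired_med) & paired_med > 0

  out <- data.frame(protein_id = shared,
                    cell_line_pattern = patt,
                    tumor_vs_bph_log10_fc = unname(fc),
                    tumor_vs_nat_log10_fc = unname(paired_med[shared]),
                    passes = unname(passes),
                    rank_score = unname(fc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank_score, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
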