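#' Standardize dose-response profiles for clustering
#'
#' Restricts the table to the design's samples (baseline first), transforms
#' intensities as `log10(x + pseudo_intensity)`, then centers and scales each
#' protein's profile to zero mean and unit variance. Zero-variance (constant)
#' profiles map to all-zero rows. Proteins with any missing intensity among
#' the design's samples are dropped; their ids are recorded in the
#' `"dropped"` attribute.
#'
#' @param table a [quant_table()].
#' @param design a [dose_design()].
#' @param pseudo_intensity small positive offset added before the log
#'   (default 1, negligible against typical intensities of 1e4-1e9).
#' @return numeric matrix of standardized profiles (rows = proteins).
#' @export
standardize_profiles <- function(table, design, pseudo_intensity = 1) {
  table <- quant_table(as.matrix(table))
  stopifnot(inherits(design, "dose_design"), pseudo_intensity >= 0)
  samples <- c(design$baseline, design$treated)
  absent <- setdiff(samples, colnames(table))
  if (length(absent)) {
    stop("standardize_profiles: design sample(s) not in table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- unclass(table)[, samples, drop = FALSE]
  complete <- rowSums(is.na(x)) == 0L
  dropped <- rownames(x)[!complete]
  x <- log10(x[complete, , drop = FALSE] + pseudo_intensity)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  attr(z, "dropped") <- dropped
  z
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1L]) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2_new <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of standardized profiles
#'
#' Runs Lloyd's algorithm (via [stats::kmeans()]) from k-means++ seedings,
#' keeping the best of `n_init` restarts by total within-cluster sum of
#' squares. All randomness derives from `seed`, so results are reproducible;
#' the caller's RNG state is left untouched.
#'
#' The default `k = 27` assigns one empirical cluster per theoretical
#' ternary pattern of a 3-dose design.
#'
#' @param x numeric matrix of profiles, e.g. from [standardize_profiles()].
#' @param k number of clusters (<= `nrow(x)`).
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return an object of class `cluster_model`: list with `k`, `assignments`
#'   (named integer vector, cluster ids contiguous from 1), `centroids`,
#'   `sizes`, `inertia` and `seed`.
#' @export
kmeans_profiles <- function(x, k = 27, seed = 1, n_init = 10, max_iter = 300) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (k < 1 || k > nrow(x)) {
    stop("kmeans_profiles: k must lie in [1, number of profiles]", call. = FALSE)
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (init in seq_len(n_init)) {
      fit <- NULL
      for (attempt in 1:20) {
        centers <- .kmeanspp_centers(x, k)
        fit <- tryCatch(
          stats::kmeans(x, centers = centers, iter.max = max_iter,
                        algorithm = "Lloyd"),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) {
        stop("kmeans_profiles: could not obtain a k-means fit without empty clusters",
             call. = FALSE)
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  assignments <- stats::setNames(as.integer(best$cluster), rownames(x))
  structure(list(k = as.integer(k),
                 assignments = assignments,
                 centroids = best$centers,
                 sizes = as.integer(best$size),
                 inertia = best$tot.withinss,
                 seed = as.integer(seed)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, n = %d, inertia = %.4g, seed = %d\n",
              x$k, length(x$assignments), x$inertia, x$seed))
  invisible(x)
}

#' Match empirical clusters to theoretical patterns
#'
#' For every cluster, the representative profile is the per-sample median of
#' the member proteins' raw intensities; that profile is direction-coded with
#' [call_directions()] and flagged if the resulting pattern is
#' SPA-associated. Matching is many-to-one: several empirical clusters may
#' land on the same theoretical pattern. Empty clusters are reported with an
#' `empty` flag and `NA` pattern (with a warning), never dropped silently.
#'
#' @param model a [kmeans_profiles()] result.
#' @param table the [quant_table()] of raw intensities the model's proteins
#'   come from.
#' @param design a [dose_design()].
#' @param params a [direction_params()].
#' @return data.frame with one row per cluster id: `cluster`, `n_members`,
#'   `pattern`, `index`, `spa_associated`, `empty`, plus the representative
#'   median intensity per design sample.
#' @export
match_clusters_to_patterns <- function(model, table, design,
                                       params = direction_params()) {
  stopifnot(inherits(model, "cluster_model"), inherits(design, "dose_design"))
  table <- quant_table(as.matrix(table))
  absent <- setdiff(names(model$assignments), rownames(table))
  if (length(absent)) {
    stop("match_clusters_to_patterns: model protein(s) missing from table: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  samples <- c(design$baseline, design$treated)
  spa_set <- select_spa_associated(enumerate_theoretical_patterns(length(design$treated)),
                                   design)
  rows <- lapply(seq_len(model$k), function(cl) {
    members <- names(model$assignments)[model$assignments == cl]
    if (!length(members)) {
      return(data.frame(cluster = cl, n_members = 0L, pattern = NA_character_,
                        index = NA_integer_, spa_associated = NA, empty = TRUE,
                        t(stats::setNames(rep(NA_real_, length(samples)), samples)),
                        check.names = FALSE, stringsAsFactors = FALSE))
    }
    med <- apply(unclass(table)[members, samples, drop = FALSE], 2L,
                 stats::median, na.rm = TRUE)
    code <- call_directions(med[design$baseline], med[design$treated], params)
    data.frame(cluster = cl, n_members = length(members), pattern = code,
               index = if (is.na(code)) NA_integer_ else pattern_index(code),
               spa_associated = if (is.na(code)) NA else code %in% spa_set,
               empty = FALSE, t(med), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$empty)) {
    warning("match_clusters_to_patterns: ", sum(out$empty),
            " empty cluster(s) reported with NA pattern", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
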