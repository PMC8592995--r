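#' Configuration for the dose-response study simulator
#'
#' Defaults emulate the statistical shape of a label-free glycoproteomic
#' dose-response profiling experiment in androgen-treated LNCaP cells: a
#' union of 3,341 proteins quantified across four R1881 conditions
#' (0, 0.1, 1.0 and 10 nM), log10-normal base abundances (mean 7, sd 1, so
#' intensities span roughly 1e4 to 3e9), per-condition missingness tuned so
#' the expected per-condition protein counts are about 1540 / 1558 / 1668 /
#' 1586, and a BSA spike-in channel at a 1:75 intensity fraction.
#'
#' Noise is specified on the log10 ratio-to-vehicle scale: the vehicle
#' column carries a protein's base abundance and each treated dose deviates
#' from it by the planted direction step plus `Normal(0, noise_log10_sd)`.
#'
#' @param n_proteins number of (non-spike) proteins (>= 1).
#' @param doses ordered dose labels; first is the vehicle baseline.
#' @param pattern_frequencies named numeric vector mapping pattern codes
#'   (over the treated doses) to probabilities summing to 1; default uniform
#'   over all theoretical patterns.
#' @param base_log10_intensity_mean,base_log10_intensity_sd parameters of
#'   the per-protein base abundance on the log10 scale (defaults 7 and 1).
#' @param effect_log10 magnitude of one "up"/"down" step in log10 units
#'   (> 0; default 1, i.e. tenfold).
#' @param noise_log10_sd sd of the log10 ratio noise (default 0.2).
#' @param missing_rate_per_condition per-condition probabilities that a
#'   protein is unobserved; all in `[0, 1]`.
#' @param spike_fraction spike-channel intensity as a fraction of a typical
#'   sample total (default 1/75).
#' @param seed integer seed; all randomness in [simulate_dose_response()]
#'   derives from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 3341,
                              doses = c("0", "0.1", "1.0", "10"),
                              pattern_frequencies = NULL,
                              base_log10_intensity_mean = 7,
                              base_log10_intensity_sd = 1,
                              effect_log10 = 1,
                              noise_log10_sd = 0.2,
                              missing_rate_per_condition =
                                1 - c(1540, 1558, 1668, 1586) / 3341,
                              spike_fraction = 1 / 75,
                              seed = 1) {
  if (n_proteins < 1) stop("simulation_config: n_proteins must be >= 1", call. = FALSE)
  if (length(doses) < 2L) stop("simulation_config: need a baseline plus >= 1 treated dose", call. = FALSE)
  n_treated <- length(doses) - 1L
  if (is.null(pattern_frequencies)) {
    codes <- enumerate_theoretical_patterns(n_treated)
    pattern_frequencies <- stats::setNames(rep(1 / length(codes), length(codes)), codes)
  }
  if (is.null(names(pattern_frequencies))) {
    stop("simulation_config: pattern_frequencies must be named by pattern code",
         call. = FALSE)
  }
  .check_pattern_code(names(pattern_frequencies))
  if (any(nchar(names(pattern_frequencies)) != n_treated)) {
    stop("simulation_config: pattern_frequencies codes must have one digit ",
         "per treated dose", call. = FALSE)
  }
  if (abs(sum(pattern_frequencies) - 1) > 1e-9 || any(pattern_frequencies < 0)) {
    stop("simulation_config: pattern_frequencies must be non-negative and ",
         "sum to 1", call. = FALSE)
  }
  if (length(missing_rate_per_condition) != length(doses)) {
    stop("simulation_config: missing_rate_per_condition needs one rate per dose",
         call. = FALSE)
  }
  if (any(missing_rate_per_condition < 0 | missing_rate_per_condition > 1)) {
    stop("simulation_config: missing_rate_per_condition must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.finite(effect_log10) || effect_log10 <= 0) {
    stop("simulation_config: effect_log10 must be > 0", call. = FALSE)
  }
  if (noise_log10_sd < 0) stop("simulation_config: noise_log10_sd must be >= 0", call. = FALSE)
  if (spike_fraction <= 0) stop("simulation_config: spike_fraction must be > 0", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 doses = as.character(doses),
                 pattern_frequencies = pattern_frequencies,
                 base_log10_intensity_mean = base_log10_intensity_mean,
                 base_log10_intensity_sd = base_log10_intensity_sd,
                 effect_log10 = effect_log10,
                 noise_log10_sd = noise_log10_sd,
                 missing_rate_per_condition = missing_rate_per_condition,
                 spike_fraction = spike_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.step_values <- c(d = -1, s = 0, u = 1)

#' Simulate a dose-response glycoproteomic study
#'
#' Draws one ternary direction pattern per protein from the configured
#' pattern frequencies and generates intensities
#' `10^(base + step * effect_log10 + noise)` at each treated dose, with the
#' vehicle column at `10^base`. Per-condition missingness is applied
#' completely at random (or, optionally, preferentially to low-abundance
#' values), and a BSA-like spike-in row with identical intensity in every
#' sample is appended before any sample-loading distortion. Optional
#' `sample_effects` multiply whole columns (including the spike), emulating
#' unequal loading that [normalize_to_spike()] can undo.
#'
#' @param config a [simulation_config()].
#' @param n_replicates columns per condition (default 1; replicate columns
#'   are labelled `_r1`, `_r2`, ... and each carries its own noise,
#'   including the baseline replicates beyond the first).
#' @param sample_effects optional positive multipliers, one per output
#'   sample column, applied after the spike row is added.
#' @param intensity_dependent_missing if `TRUE`, missingness within a
#'   condition is concentrated on the lower-intensity half of proteins
#'   while preserving the configured marginal rate (default `FALSE`,
#'   missing completely at random).
#' @return an object of class `simulated_study`: list with `quant`
#'   (a [quant_table()] including the spike row), `spike_rows`,
#'   `truth_patterns` (named pattern codes), `design` (a [dose_design()])
#'   and `config`.
#' @export
simulate_dose_response <- function(config, n_replicates = 1,
                                   sample_effects = NULL,
                                   intensity_dependent_missing = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_proteins
  doses <- config$doses
  n_treated <- length(doses) - 1L
  sample_ids <- unlist(lapply(paste0(doses, "nM"), function(d)
    if (n_replicates == 1L) d else paste0(d, "_r", seq_len(n_replicates))))
  cond_of <- rep(seq_along(doses), each = n_replicates)

  withr::with_seed(config$seed, {
    base <- stats::rnorm(n, config$base_log10_intensity_mean,
                         config$base_log10_intensity_sd)
    patt <- sample(names(config$pattern_frequencies), n, replace = TRUE,
                   prob = config$pattern_frequencies)
    steps <- t(vapply(strsplit(patt, "", fixed = TRUE),
                      function(ch) .step_values[ch], numeric(n_treated)))
    m <- matrix(NA_real_, n, length(sample_ids),
                dimnames = list(sprintf("P%04d", seq_len(n)), sample_ids))
    for (j in seq_along(sample_ids)) {
      cond <- cond_of[j]
      if (cond == 1L) {
        # vehicle defines the reference level; replicate vehicle columns
        # beyond the first carry ratio noise of their own
        eps <- if (j == 1L) 0 else stats::rnorm(n, 0, config$noise_log10_sd)
        m[, j] <- 10^(base + eps)
      } else {
        eps <- stats::rnorm(n, 0, config$noise_log10_sd)
        m[, j] <- 10^(base + steps[, cond - 1L] * config$effect_log10 + eps)
      }
    }
    for (j in seq_along(sample_ids)) {
      rate <- config$missing_rate_per_condition[cond_of[j]]
      if (rate <= 0) next
      if (intensity_dependent_missing) {
        rk <- rank(m[, j], ties.method = "first")
        w <- 2 * (1 - (rk - 0.5) / n)          # low intensity -> weight near 2
        p <- pmin(rate * w, 1)
        drop <- stats::runif(n) < p
      } else {
        drop <- stats::runif(n) < rate
      }
      m[drop, j] <- NA_real_
    }
    spike_level <- config$spike_fraction *
      10^(config$base_log10_intensity_mean) * n
    spike <- matrix(spike_level, 1L, length(sample_ids),
                    dimnames = list("BSA_spike", sample_ids))
    m <- rbind(m, spike)
    if (!is.null(sample_effects)) {
      if (length(sample_effects) != length(sample_ids) || any(sample_effects <= 0)) {
        stop("simulate_dose_response: sample_effects needs one positive ",
             "multiplier per sample", call. = FALSE)
      }
      m <- sweep(m, 2L, sample_effects, `*`)
    }
  })
  baseline_id <- sample_ids[1L]
  treated_first <- sample_ids[match(2:length(doses), cond_of)]
  structure(list(quant = quant_table(m),
                 spike_rows = "BSA_spike",
                 truth_patterns = stats::setNames(patt, rownames(m)[seq_len(n)]),
                 design = dose_design(baseline_id, treated_first),
                 config = config),
            class = "simulated_study")
}

#' Simulate gene-set annotations with planted enrichment
#'
#' Builds an annotation collection over the simulated proteins in which
#' `n_enriched` designated terms draw their members preferentially (odds
#' multiplied by `enrichment_factor`) from one pattern class -- by default
#' the most frequent SPA-associated pattern among `truth_patterns` -- while
#' the remaining terms sample uniformly. With `enrichment_factor = 1`
#' enriched and null terms are distributionally identical, so
#' overrepresentation p-values are null-calibrated.
#'
#' @param n_terms total number of terms (>= `n_enriched`).
#' @param set_size_range length-2 integer range of term sizes (default
#'   `c(20, 200)`, typical of curated pathway collections).
#' @param n_enriched number of terms with planted enrichment.
#' @param enrichment_factor odds multiplier (>= 1) for members of the target
#'   pattern class.
#' @param truth_patterns named pattern codes per protein, e.g. from
#'   [simulate_dose_response()].
#' @param seed integer seed.
#' @param target_pattern pattern code of the enriched class; default the
#'   most frequent SPA-associated pattern present.
#' @return list with `gene_sets` (a [gene_set_collection()]),
#'   `enriched_terms` (character) and `target_pattern`.
#' @export
simulate_gene_sets <- function(n_terms, set_size_range = c(20, 200),
                               n_enriched, enrichment_factor,
                               truth_patterns, seed,
                               target_pattern = NULL) {
  universe <- names(truth_patterns)
  if (!length(universe)) stop("simulate_gene_sets: empty universe", call. = FALSE)
  if (n_enriched > n_terms) {
    stop("simulate_gene_sets: n_enriched must be <= n_terms", call. = FALSE)
  }
  if (any(set_size_range < 1) || length(set_size_range) != 2L) {
    stop("simulate_gene_sets: set sizes must be >= 1", call. = FALSE)
  }
  if (enrichment_factor < 1) {
    stop("simulate_gene_sets: enrichment_factor must be >= 1", call. = FALSE)
  }
  if (is.null(target_pattern)) {
    k <- nchar(truth_patterns[[1L]])
    spa_set <- select_spa_associated(
      enumerate_theoretical_patterns(k),
      dose_design("baseline", paste0("dose", seq_len(k))))
    present <- table(truth_patterns[truth_patterns %in% spa_set])
    if (!length(present)) {
      stop("simulate_gene_sets: no SPA-associated patterns present; supply ",
           "target_pattern", call. = FALSE)
    }
    target_pattern <- names(present)[which.max(present)]
  }
  weights <- ifelse(truth_patterns == target_pattern, enrichment_factor, 1)
  withr::with_seed(as.integer(seed), {
    size_pool <- seq.int(set_size_range[1L], set_size_range[2L])
    sizes <- size_pool[sample.int(length(size_pool), n_terms, replace = TRUE)]
    sizes <- pmin(sizes, length(universe))
    ids <- sprintf("T%04d", seq_len(n_terms))
    sets <- lapply(seq_len(n_terms), function(i) {
      if (i <= n_enriched && enrichment_factor > 1) {
        sample(universe, sizes[i], prob = weights)
      } else {
        sample(universe, sizes[i])
      }
    })
    names(sets) <- ids
  })
  list(gene_sets = gene_set_collection(sets),
       enriched_terms = if (n_enriched) ids[seq_len(n_enriched)] else character(0),
       target_pattern = target_pattern)
}

#' Simulate a prostate tissue cohort with planted biomarkers
#'
#' Generates a tissue quantification table over groups drawn from
#' NAT / BPH / PCa / mPCa, together with a paired cell-line dose-response
#' table over the same proteins. Planted marker classes: `tumor_up`
#' proteins are elevated by `effect_log10` in PCa and mPCa relative to BPH
#' and NAT; `bph_up` proteins are elevated in BPH; one
#' `androgen_biphasic_tumor_up` archetype is tumor-elevated in tissue and
#' biphasic in the cell line (rising through the physiologic doses, peaking
#' at the second-highest dose and falling below baseline at the
#' supraphysiologic dose, pattern `"uud"`); all remaining proteins are
#' `null` with flat cell-line profiles. NAT samples are paired with PCa
#' samples (`pair_id`) where counts allow.
#'
#' @param n_per_group named integer vector of sample counts; names from
#'   `NAT`, `BPH`, `PCa`, `mPCa`. Default the cohort shape of a typical
#'   profiling study: 8 NAT, 10 BPH, 13 PCa, 6 mPCa.
#' @param n_proteins total proteins (default 1759).
#' @param n_markers number of planted `tumor_up` markers and, equally, of
#'   `bph_up` markers (default 50).
#' @param effect_log10 planted group effect in log10 units (>= 0).
#' @param noise_log10_sd per-sample log10 noise sd (default 0.2).
#' @param base_log10_intensity_mean,base_log10_intensity_sd base abundance
#'   distribution (defaults 7 and 1).
#' @param seed integer seed.
#' @return an object of class `simulated_cohort`: list with `quant`,
#'   `design` (a [cohort_design()]), `truth_markers` (named classes),
#'   `cell_line` (a [quant_table()] over doses 0/0.1/1.0/10 nM),
#'   `cell_line_patterns` (named truth codes) and `cell_line_design`.
#' @export
simulate_tissue_cohort <- function(n_per_group = c(NAT = 8, BPH = 10, PCa = 13, mPCa = 6),
                                   n_proteins = 1759, n_markers = 50,
                                   effect_log10 = 1, noise_log10_sd = 0.2,
                                   base_log10_intensity_mean = 7,
                                   base_log10_intensity_sd = 1,
                                   seed = 1) {
  groups <- names(n_per_group)
  unknown <- setdiff(groups, c("NAT", "BPH", "PCa", "mPCa"))
  if (length(unknown)) {
    stop("simulate_tissue_cohort: unknown group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(n_per_group < 1)) {
    stop("simulate_tissue_cohort: group counts must be >= 1", call. = FALSE)
  }
  if (2 * n_markers + 1 > n_proteins) {
    stop("simulate_tissue_cohort: n_markers too large for n_proteins", call. = FALSE)
  }
  if (effect_log10 < 0) stop("simulate_tissue_cohort: effect_log10 must be >= 0", call. = FALSE)

  proteins <- sprintf("P%04d", seq_len(n_proteins))
  classes <- rep("null", n_proteins)
  classes[seq_len(n_markers)] <- "tumor_up"
  if (n_markers > 0) classes[n_markers + seq_len(n_markers)] <- "bph_up"
  classes[2 * n_markers + 1L] <- "androgen_biphasic_tumor_up"
  names(classes) <- proteins

  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(n_per_group[[g]]))))
  sample_group <- rep(groups, times = n_per_group)
  pair_id <- rep(NA_character_, length(sample_ids))
  if (all(c("NAT", "PCa") %in% groups)) {
    n_pairs <- min(n_per_group[["NAT"]], n_per_group[["PCa"]])
    for (i in seq_len(n_pairs)) {
      pid <- sprintf("case%02d", i)
      pair_id[sample_ids == sprintf("NAT_%02d", i)] <- pid
      pair_id[sample_ids == sprintf("PCa_%02d", i)] <- pid
    }
  }
  design <- cohort_design(sample_ids, sample_group, pair_id)

  doses <- c("0", "0.1", "1.0", "10")
  cl_ids <- paste0(doses, "nM")
  non_flat <- setdiff(enumerate_theoretical_patterns(3), "sss")

  withr::with_seed(as.integer(seed), {
    base <- stats::rnorm(n_proteins, base_log10_intensity_mean,
                         base_log10_intensity_sd)
    shift <- matrix(0, n_proteins, length(sample_ids),
                    dimnames = list(proteins, sample_ids))
    tumor_cols <- sample_group %in% c("PCa", "mPCa")
    bph_cols <- sample_group == "BPH"
    up_rows <- classes %in% c("tumor_up", "androgen_biphasic_tumor_up")
    shift[up_rows, tumor_cols] <- effect_log10
    shift[classes == "bph_up", bph_cols] <- effect_log10
    noise <- matrix(stats::rnorm(n_proteins * length(sample_ids), 0, noise_log10_sd),
                    n_proteins, length(sample_ids))
    tissue <- 10^(base + shift + noise)
    dimnames(tissue) <- list(proteins, sample_ids)

    cl_patterns <- rep("sss", n_proteins)
    marker_rows <- classes %in% c("tumor_up", "bph_up")
    cl_patterns[marker_rows] <- sample(non_flat, sum(marker_rows), replace = TRUE)
    cl_patterns[classes == "androgen_biphasic_tumor_up"] <- "uud"
    names(cl_patterns) <- proteins
    steps <- t(vapply(strsplit(cl_patterns, "", fixed = TRUE),
                      function(ch) .step_values[ch], numeric(3)))
    cl <- matrix(NA_real_, n_proteins, 4L, dimnames = list(proteins, cl_ids))
    cl[, 1L] <- 10^base
    for (j in 2:4) {
      cl[, j] <- 10^(base + steps[, j - 1L] * effect_log10 +
                       stats::rnorm(n_proteins, 0, noise_log10_sd))
    }
  })

  structure(list(quant = quant_table(tissue),
                 design = design,
                 truth_markers = classes,
                 cell_line = quant_table(cl),
                 cell_line_patterns = cl_patterns,
                 cell_line_design = dose_design(cl_ids[1L], cl_ids[-1L]),
                 effect_log10 = effect_log10,
                 noise_log10_sd = noise_log10_sd,
                 seed = as.integer(seed)),
            class = "simulated_cohort")
}

#' Write simulated truth tables as tab-separated text
#'
#' @param study a `simulated_study` from [simulate_dose_response()].
#' @param path output path for the per-protein truth pattern table.
#' @return `path`, invisibly.
#' @export
write_truth_patterns <- function(study, path) {
  stopifnot(inherits(study, "simulated_study"))
  df <- data.frame(protein_id = names(study$truth_patterns),
                   pattern = unname(study$truth_patterns),
                   index = pattern_index(unname(study$truth_patterns)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
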