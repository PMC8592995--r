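# Small in-code fixtures shared across the suite.

# minimal quant matrix with explicit dimnames
make_quant <- function(values, proteins, samples) {
  quant_table(matrix(values, nrow = length(proteins), byrow = TRUE,
                     dimnames = list(proteins, samples)))
}

# random positive quant table with a positive spike row appended
random_spiked_table <- function(n_proteins, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(10^runif(n_proteins * n_samples, 3, 9), n_proteins, n_samples,
                dimnames = list(sprintf("P%02d", seq_len(n_proteins)),
                                sprintf("s%d", seq_len(n_samples))))
    spike <- matrix(10^runif(n_samples, 4, 6), 1, n_samples,
                    dimnames = list("SPIKE", colnames(m)))
    quant_table(rbind(m, spike))
  })
}

example_quant_path <- function() {
  system.file("extdata", "lncap_example_quant.tsv", package = "glycopattern",
              mustWork = TRUE)
}

# one PSM record with all-passing defaults, fields overridable
make_psm <- function(protein_id = "P1", sequence = "PEPTIDEK", score = 5,
                     fwd_rev_score = 2, rank12_score = 3, spi_percent = 60,
                     intensity = 1e5, sample_id = "s1") {
  data.frame(protein_id = protein_id, sequence = sequence, score = score,
             fwd_rev_score = fwd_rev_score, rank12_score = rank12_score,
             spi_percent = spi_percent, intensity = intensity,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# brute-force complete-linkage agglomeration over a distance matrix;
# returns merge heights in merge order
brute_force_complete_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}
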