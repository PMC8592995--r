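test_that("quant table round-trips through tab-separated text", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  q <- make_quant(c(1e6, NA, 2.5e5, 3e5), c("P1", "P2"), c("s1", "s2"))
  write_quant_table(q, tmp)
  back <- read_quant_table(tmp)
  expect_identical(dimnames(back), dimnames(q))
  expect_true(is.na(back["P1", "s2"]))
  expect_equal(unclass(back), unclass(q), tolerance = 1e-9)

  # a larger random table with missingness, including a comment header
  q2 <- random_spiked_table(30, 5, seed = 11)
  q2[sample(length(q2), 20)] <- NA
  q2 <- quant_table(unclass(q2))
  write_quant_table(q2, tmp, comments = "simulated fixture")
  expect_equal(unclass(read_quant_table(tmp)), unclass(q2), tolerance = 1e-9)
})

test_that("malformed quant tables are rejected with informative errors", {
  m <- matrix(1, 2, 2, dimnames = list(c("P1", "P1"), c("s1", "s2")))
  expect_error(quant_table(m), "duplicate protein id.*P1")
  m2 <- matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("P1", "P2"), c("s1", "s2")))
  expect_error(quant_table(m2), "negative")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1", "P1\t1", "P1\t2"), tmp)
  expect_error(read_quant_table(tmp), "duplicate")
})

test_that("the example LNCaP table reads back the printed intensities", {
  q <- read_quant_table(example_quant_path())
  expect_equal(unname(unclass(q)["PRKDC", ]),
               c(3.72e7, 2.71e7, 3.29e7, 2.44e7))
  expect_equal(colnames(q), c("0nM", "0.1nM", "1.0nM", "10nM"))
  expect_equal(nrow(q), 4L)
})

test_that("filter_psms keeps exactly the records passing every threshold", {
  expect_equal(nrow(filter_psms(make_psm()[0, ])), 0L)

  # record sitting exactly at all four thresholds is kept (inclusive >=)
  at <- make_psm(score = 3, fwd_rev_score = 1.2, rank12_score = 2,
                 spi_percent = 30)
  expect_equal(nrow(filter_psms(at)), 1L)

  # brute-force: every pass/fail combination of the four criteria;
  # only the all-pass record must survive
  lo <- list(score = 2.9, fwd_rev_score = 1.1, rank12_score = 1.9,
             spi_percent = 29)
  hi <- list(score = 3, fwd_rev_score = 1.2, rank12_score = 2,
             spi_percent = 30)
  grid <- expand.grid(s = 1:2, f = 1:2, r = 1:2, p = 1:2)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    make_psm(protein_id = paste0("P", i),
             score = c(lo$score, hi$score)[g$s],
             fwd_rev_score = c(lo$fwd_rev_score, hi$fwd_rev_score)[g$f],
             rank12_score = c(lo$rank12_score, hi$rank12_score)[g$r],
             spi_percent = c(lo$spi_percent, hi$spi_percent)[g$p])
  }))
  kept <- filter_psms(recs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$protein_id, paste0("P", nrow(grid)))  # the all-hi row

  # subset of input, order preserved, idempotent
  mixed <- rbind(make_psm(protein_id = "A"), make_psm(protein_id = "B", score = 1),
                 make_psm(protein_id = "C"))
  once <- filter_psms(mixed)
  expect_equal(once$protein_id, c("A", "C"))
  expect_identical(filter_psms(once), once)
})

test_that("aggregate_psms sums member intensities and conserves totals", {
  one <- make_psm(intensity = 123)
  t1 <- aggregate_psms(one)
  expect_equal(unname(unclass(t1)[1, 1]), 123)

  two <- rbind(make_psm(intensity = 10), make_psm(intensity = 32))
  expect_equal(unname(unclass(aggregate_psms(two))[1, 1]), 42)

  # 6 PSMs over 2 proteins x 2 samples, sums enumerated by hand
  recs <- rbind(make_psm("P1", intensity = 1, sample_id = "s1"),
                make_psm("P1", intensity = 2, sample_id = "s1"),
                make_psm("P1", intensity = 4, sample_id = "s2"),
                make_psm("P2", intensity = 8, sample_id = "s1"),
                make_psm("P2", intensity = 16, sample_id = "s2"),
                make_psm("P2", intensity = 32, sample_id = "s2"))
  tab <- aggregate_psms(recs)
  expect_equal(unclass(tab),
               matrix(c(3, 8, 4, 48), 2, 2,
                      dimnames = list(c("P1", "P2"), c("s1", "s2"))))
  expect_equal(sum(tab, na.rm = TRUE), sum(recs$intensity))
  # mean/median rollups
  expect_equal(unname(unclass(aggregate_psms(recs, "mean"))["P2", "s2"]), 24)
  expect_equal(unname(unclass(aggregate_psms(recs, "median"))["P1", "s1"]), 1.5)
})

test_that("spike normalization rescales per sample and drops spike rows", {
  q <- make_quant(c(10, 20, 40,
                    2,  4,  8,
                    5,  5,  5), c("P1", "P2", "BSA"), c("a", "b", "c"))
  out <- normalize_to_spike(q, "BSA")
  expect_equal(rownames(out), c("P1", "P2"))
  expect_equal(unclass(out), unclass(q)[1:2, ])  # equal spikes: identity

  q2 <- make_quant(c(10, 20,
                     5, 10), c("P1", "BSA"), c("a", "b"))
  out2 <- normalize_to_spike(q2, "BSA")  # b's spike is 2x reference
  expect_equal(unname(unclass(out2)["P1", ]), c(10, 10))

  # reference sample is unchanged under any reference choice
  out3 <- normalize_to_spike(q2, "BSA", reference = "b")
  expect_equal(unname(unclass(out3)["P1", "b"]), 20)
})

test_that("spike normalization matches a direct ratio oracle and is idempotent", {
  for (seed in 1:5) {
    q <- random_spiked_table(5, 3, seed = seed)
    out <- normalize_to_spike(q, "SPIKE")
    # oracle: per-sample ratio computed directly
    spike <- unclass(q)["SPIKE", ]
    expected <- sweep(unclass(q)[1:5, ], 2, spike[1] / spike, `*`)
    expect_equal(unclass(out), expected, tolerance = 1e-12)

    # global rescaling invariance
    out_scaled <- normalize_to_spike(quant_table(unclass(q) * 7.3), "SPIKE")
    expect_equal(unclass(out_scaled), unclass(out) * 7.3, tolerance = 1e-9)

    # idempotence: renormalizing with a unit spike row leaves it fixed
    unit <- matrix(1, 1, 3, dimnames = list("UNIT", colnames(q)))
    again <- normalize_to_spike(quant_table(rbind(unclass(out), unit)), "UNIT")
    expect_equal(unclass(again), unclass(out), tolerance = 1e-12)
  }
})

test_that("spike normalization rejects zero or missing spike totals by name", {
  q <- make_quant(c(1, 2, 5, 0), c("P1", "BSA"), c("a", "bad_sample"))
  expect_error(normalize_to_spike(q, "BSA"), "bad_sample")
  q2 <- make_quant(c(1, 2, 5, NA), c("P1", "BSA"), c("a", "nospike"))
  expect_error(normalize_to_spike(q2, "BSA"), "nospike")
  expect_error(normalize_to_spike(q, "NOT_THERE"), "NOT_THERE")
})

test_that("comparative Ct fold changes follow the doubling-per-cycle rule", {
  veh <- list(gene = "ENTPD5", condition = "0nM", ct_target = 24, ct_reference = 18)
  trt <- list(gene = "ENTPD5", condition = "1nM", ct_target = 24, ct_reference = 18)
  expect_equal(ddct_fold_change(trt, veh), 1.0)

  trt2 <- list(gene = "ENTPD5", condition = "1nM", ct_target = 23, ct_reference = 18)
  expect_equal(ddct_fold_change(trt2, veh), 2.0)

  # adding a constant to all four Ct values changes nothing
  shift <- function(x, c) {
    x$ct_target <- x$ct_target + c
    x$ct_reference <- x$ct_reference + c
    x
  }
  expect_equal(ddct_fold_change(shift(trt2, 3.7), shift(veh, 3.7)), 2.0)

  other <- list(gene = "KLK3", condition = "0nM", ct_target = 20, ct_reference = 18)
  expect_error(ddct_fold_change(trt, other), "gene mismatch")
})
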