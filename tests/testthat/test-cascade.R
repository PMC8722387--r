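# The six-screen filtering cascade.

test_that("alt fraction is a ratio with an explicit undefined sentinel", {
  expect_equal(alt_fraction(0, 30), 1)
  expect_equal(alt_fraction(30, 0), 0)
  expect_equal(alt_fraction(15, 5), 0.25)
  expect_true(is.na(alt_fraction(0, 0)))
  expect_error(alt_fraction(-1, 5), class = "poolscreen_validation_error")
})

test_that("screen 1 calls homozygous difference with configurable stringency", {
  th <- screen_thresholds()
  expect_true(screen1_hom_difference(row_with_counts(wt = c(20L, 0L),
                                                     mut = c(0L, 25L)), th))
  # mutant pool not homozygous at the default 0.9 cut
  expect_false(screen1_hom_difference(row_with_counts(wt = c(20L, 0L),
                                                      mut = c(12L, 13L)), th))
  # undefined WT fraction fails conservatively
  expect_false(screen1_hom_difference(row_with_counts(wt = c(0L, 0L),
                                                      mut = c(0L, 25L)), th))
  # both pools fixed for the same allele is not a difference
  expect_false(screen1_hom_difference(row_with_counts(wt = c(0L, 20L),
                                                      mut = c(0L, 25L)), th))
  # near-fixed passes at 0.9 but not at 1.0
  near <- row_with_counts(wt = c(19L, 1L), mut = c(1L, 19L))
  expect_true(screen1_hom_difference(near, th))
  strict <- screen_thresholds(screen1_hom_fraction = 1.0)
  expect_false(screen1_hom_difference(near, strict))
})

test_that("screen 2 demands exact 100%/0% enrichment", {
  th <- screen_thresholds()
  expect_true(screen2_full_enrichment(row_with_counts(wt = c(15L, 0L),
                                                      mut = c(0L, 9L)), th))
  expect_false(screen2_full_enrichment(row_with_counts(wt = c(15L, 1L),
                                                       mut = c(0L, 9L)), th))
  expect_false(screen2_full_enrichment(row_with_counts(wt = c(15L, 0L),
                                                       mut = c(1L, 9L)), th))
  expect_false(screen2_full_enrichment(row_with_counts(wt = c(0L, 0L),
                                                       mut = c(0L, 9L)), th))
})

test_that("depth and sibling screens use strict 'more than' comparisons", {
  th <- screen_thresholds()
  expect_true(screen3_wt_depth(row_with_counts(wt = c(11L, 0L)), th))
  expect_false(screen3_wt_depth(row_with_counts(wt = c(10L, 0L)), th))
  expect_false(screen3_wt_depth(row_with_counts(wt = c(0L, 0L)), th))

  expect_true(screen4_mut_depth(row_with_counts(mut = c(0L, 6L)), th))
  expect_false(screen4_mut_depth(row_with_counts(mut = c(0L, 5L)), th))

  expect_true(screen5_sib_het(row_with_counts(sib = c(5L, 5L)), th))
  expect_false(screen5_sib_het(row_with_counts(sib = c(4L, 9L)), th))
  expect_false(screen5_sib_het(row_with_counts(sib = c(0L, 50L)), th))

  expect_true(screen6_sib_ratio(row_with_counts(sib = c(12L, 7L)), th))
  expect_false(screen6_sib_ratio(row_with_counts(sib = c(7L, 7L)), th))
  expect_false(screen6_sib_ratio(row_with_counts(sib = c(7L, 12L)), th))
})

test_that("threshold validation refuses impossible settings", {
  expect_error(screen_thresholds(wt_alt_fraction_max = 1,
                                 mut_alt_fraction_required = 1),
               class = "poolscreen_config_error")
  expect_error(screen_thresholds(screen1_hom_fraction = 0.4),
               class = "poolscreen_config_error")
  expect_error(screen_thresholds(wt_min_total = -1),
               class = "poolscreen_config_error")
})

test_that("the cascade narrows monotonically and matches the row oracle", {
  set.seed(7)
  for (i in 1:200) {
    tab <- random_variant_table(sample(c(5:60, 200), 1))
    rep <- run_cascade(tab, nonsyn_mode = "off")
    expect_true(all(diff(rep$screens$n_survivors) <= 0))
    expect_identical(sort(rep$candidates$variant_id), oracle_final_set(tab))
  }
})

test_that("the final set is order-invariant and shrinks under tightening", {
  set.seed(15)
  for (i in 1:25) {
    tab <- random_variant_table(80)
    base <- run_cascade(tab, nonsyn_mode = "off")$candidates$variant_id
    # conjunction computed in one pass equals the ordered cascade
    th <- screen_thresholds()
    conj <- tab$variant_id[screen1_hom_difference(tab, th) &
                             screen2_full_enrichment(tab, th) &
                             screen3_wt_depth(tab, th) &
                             screen4_mut_depth(tab, th) &
                             screen5_sib_het(tab, th) &
                             screen6_sib_ratio(tab, th)]
    expect_setequal(base, conj)
    # tightening any count threshold never enlarges the final set
    tighter <- run_cascade(tab, screen_thresholds(wt_min_total = 20,
                                                  mut_min_total = 12,
                                                  sib_min_each_allele = 8,
                                                  require_nonsynonymous = FALSE))
    expect_true(all(tighter$candidates$variant_id %in% base))
  }
})

test_that("empty input yields an all-zero report", {
  rep <- run_cascade(random_variant_table(5)[0, ], nonsyn_mode = "off")
  expect_true(all(rep$screens$n_survivors == 0L))
  expect_identical(nrow(rep$candidates), 0L)
})

test_that("the non-synonymous condition is enforced and placement-invariant", {
  tab <- rbind(row_with_counts(id = "mis"), row_with_counts(id = "syn"))
  tab$position <- c(5L, 6L)
  classes <- c(mis = "missense", syn = "synonymous")

  expect_error(run_cascade(tab, nonsyn_mode = "final"),
               class = "poolscreen_config_error")

  final <- run_cascade(tab, consequences = classes, nonsyn_mode = "final")
  pre <- run_cascade(tab, consequences = classes, nonsyn_mode = "prefilter")
  expect_identical(final$candidates$variant_id, "mis")
  expect_identical(final$candidates$variant_id, pre$candidates$variant_id)
  # only per-screen counts differ between placements
  expect_identical(final$screens$n_survivors[7], 1L)
  expect_identical(pre$screens$n_survivors[1], 1L)

  # a surviving variant without a call is a configuration error
  expect_error(run_cascade(tab, consequences = c(syn = "synonymous"),
                           nonsyn_mode = "final"),
               "mis", class = "poolscreen_config_error")

  off <- run_cascade(tab, nonsyn_mode = "off")
  expect_setequal(off$candidates$variant_id, c("mis", "syn"))
})

test_that("candidates report per-pool alt fractions sorted by locus", {
  tab <- rbind(row_with_counts(id = "b"), row_with_counts(id = "a"))
  tab$transcript_id <- c("tx2", "tx1")
  rep <- run_cascade(tab, nonsyn_mode = "off")
  expect_identical(rep$candidates$transcript_id, c("tx1", "tx2"))
  expect_equal(rep$candidates$mut_alt_fraction, c(1, 1))
  expect_equal(rep$candidates$wt_alt_fraction, c(0, 0))
})
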