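# Synthetic selfing-cross generator: segregation, pooling, sequencing.

test_that("selfing segregation follows the 1:2:1 law and rejects bad input", {
  expect_error(segregate_selfing("hom_ref", 10), class = "poolscreen_config_error")
  expect_error(segregate_selfing("hom_alt", 10), class = "poolscreen_config_error")
  expect_error(segregate_selfing("wild", 10), class = "poolscreen_config_error")
  expect_identical(segregate_selfing("het", 0), character(0))

  set.seed(101)
  g <- segregate_selfing("het", 10000)
  expect_setequal(unique(g), c("hom_ref", "het", "hom_alt"))
  # 3 binomial standard errors around the Mendelian expectations
  se25 <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(g == "hom_alt") - 0.25), 3 * se25)
  expect_lt(abs(mean(g == "hom_ref") - 0.25), 3 * se25)
  expect_lt(abs(mean(g == "het") - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
})

test_that("pools condition on phenotype only at the causal site", {
  m <- cross_model(seed = 5, n_background_variants = 200, n_transcripts = 30)
  set.seed(m$seed)
  pools <- build_pools(m)
  ci <- pools$causal_index

  expect_true(all(pools$mut[ci, ] == 2L))          # mutants are hom-alt
  expect_true(all(pools$sib[ci, ] != 2L))          # siblings never hom-alt
  expect_true(all(pools$wt[ci, ] == 0L))           # WT strain lacks the allele

  truth <- pools$truth
  expect_identical(sum(truth$causal), 1L)
  expect_identical(truth$founder_genotype[ci], "het")
  expect_equal(truth$expected_mut_alt_fraction[ci], 1)
  expect_equal(truth$expected_sib_alt_fraction[ci], 1 / 3)
  expect_equal(truth$expected_wt_alt_fraction[ci], 0)
})

test_that("without heterozygosity the background does not segregate", {
  m <- cross_model(seed = 9, n_background_variants = 300,
                   residual_het_rate = 0, enu_het_rate = 0,
                   n_transcripts = 30)
  set.seed(m$seed)
  pools <- build_pools(m)
  bg <- setdiff(seq_len(nrow(pools$mut)), pools$causal_index)
  # every background site is fixed within each pool
  expect_true(all(apply(pools$mut[bg, ], 1, function(x) length(unique(x))) == 1))
  expect_true(all(apply(pools$sib[bg, ], 1, function(x) length(unique(x))) == 1))
  expect_true(all(pools$wt[bg, ] == 0L))
})

test_that("noiseless sequencing reproduces pool dosages exactly and in expectation", {
  # fixed hom-alt sites with no sequencing error: all reads are alt
  m <- cross_model(seed = 3, n_embryos_per_pool = 20, seq_error_rate = 0,
                   n_background_variants = 0, n_transcripts = 5)
  s <- 2000L
  g_fixed <- matrix(2L, nrow = s, ncol = 20)
  g_sib <- matrix(rep(c(rep(0L, 10), rep(1L, 10)), each = s), nrow = s)
  pools <- structure(list(model = m, mut = g_fixed, sib = g_sib,
                          wt = matrix(0L, s, 20), sites = NULL),
                     class = "pool_set")
  set.seed(11)
  tab <- sequence_pools(pools, m)
  covered <- tab$mut_ref + tab$mut_alt > 0
  expect_true(all(tab$mut_ref[covered] == 0L))
  expect_true(all(tab$wt_alt == 0L))
  # 10 hom-ref + 10 het embryos carry alt dosage 10/40 = 0.25
  sib_frac <- sum(tab$sib_alt) / sum(tab$sib_ref + tab$sib_alt)
  se <- sqrt(0.25 * 0.75 / sum(tab$sib_ref + tab$sib_alt))
  expect_lt(abs(sib_frac - 0.25), 3 * se)
})

test_that("causal variant carries the designed signature when noiseless", {
  for (seed in 1:5) {
    sim <- simulate_cross(cross_model(seed = seed, seq_error_rate = 0,
                                      n_background_variants = 20,
                                      n_transcripts = 10))
    causal <- sim$variants[sim$truth$causal, ]
    expect_identical(causal$mut_ref, 0L)
    expect_identical(causal$wt_alt, 0L)
  }
})

test_that("sibling-pool causal alt fraction converges to one third", {
  # many small crosses, one causal site each
  set.seed(77)
  n_sites <- 1000L
  m <- cross_model(seed = 77, n_background_variants = 0, n_transcripts = 2)
  fracs <- vapply(seq_len(n_sites), function(i) {
    pools <- build_pools(m)
    mean(pools$sib[pools$causal_index, ]) / 2
  }, numeric(1))
  # per-pool dosage variance under 1/3 hom-ref : 2/3 het is 1/18 per embryo
  se <- sqrt(1 / 18 / m$n_embryos_per_pool / n_sites)
  expect_lt(abs(mean(fracs) - 1 / 3), 3 * se)
})

test_that("equal model and seed reproduce byte-identical outputs", {
  m <- cross_model(seed = 123, n_background_variants = 80, n_transcripts = 15)
  sim1 <- simulate_cross(m)
  sim2 <- simulate_cross(m)
  expect_identical(sim1$variants, sim2$variants)
  expect_identical(sim1$transcripts, sim2$transcripts)

  d1 <- tempfile("sim_a_"); d2 <- tempfile("sim_b_")
  write_cross_sim(sim1, d1)
  write_cross_sim(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("model validation rejects impossible parameters", {
  expect_error(cross_model(seed = 1, n_embryos_per_pool = 0),
               class = "poolscreen_config_error")
  expect_error(cross_model(seed = 1, seq_error_rate = 1.5),
               class = "poolscreen_config_error")
  expect_error(cross_model(seed = 1, depth_mean = 0),
               class = "poolscreen_config_error")
  expect_error(cross_model(seed = 1, residual_het_rate = 0.6,
                           enu_het_rate = 0.6),
               class = "poolscreen_config_error")
  expect_error(cross_model(), class = "poolscreen_config_error")
})

test_that("planted causal allele is a coding missense variant", {
  sim <- simulate_cross(cross_model(seed = 31, n_background_variants = 40,
                                    n_transcripts = 10))
  causal <- sim$variants[sim$truth$causal, ]
  call <- call_consequences(causal, sim$transcripts)
  expect_identical(call$consequence_class, "missense")
  expect_identical(causal$ref, "C")
  expect_identical(causal$alt, "T")
})
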