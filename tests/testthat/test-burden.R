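test_that("binomial upper tail handles edges exactly and matches the oracle", {
  expect_identical(binomial_tail(0, 10, 0.3), 1)
  expect_identical(binomial_tail(11, 10, 0.3), 0)
  # frozen oracle value: 1 - P(0) - P(1) for Bin(10, 0.1)
  expect_equal(binomial_tail(2, 10, 0.1), 0.2639011, tolerance = 1e-6)
  expect_equal(binomial_tail(2, 10, 0.1), binom_tail_oracle(2, 10, 0.1),
               tolerance = 1e-12)
  expect_error(binomial_tail(2, 10, 1.5), "\\[0, 1\\]")

  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(1:500, 1)
      k <- sample(0:(n + 1), 1)
      p <- runif(1)
      expect_equal(binomial_tail(k, n, p), binom_tail_oracle(k, n, p),
                   tolerance = 1e-10)
    }
  })
})

test_that("binomial tail is monotone in k and in p", {
  ks <- 0:50
  tails_k <- binomial_tail(ks, 50, 0.2)
  expect_true(all(diff(tails_k) <= 0))
  ps <- seq(0, 1, by = 0.05)
  tails_p <- vapply(ps, function(p) binomial_tail(10, 50, p), numeric(1))
  expect_true(all(diff(tails_p) >= 0))
})

test_that("carrier counting is binary per individual", {
  samples <- toy_samples(sprintf("S%d", 1:10))
  v <- dplyr::bind_rows(
    toy_variant(sample_id = "S1", pos = 150L),
    toy_variant(sample_id = "S1", pos = 160L),  # second hit, same carrier
    toy_variant(sample_id = "S3", pos = 170L),
    toy_variant(sample_id = "S7", pos = 180L)
  )
  ds <- cohort_dataset(toy_panel(), samples, v)
  counts <- count_carriers(ds, "overabundance")
  expect_equal(dplyr::filter(counts, gene == "GENEA")$carriers, 3L)
  expect_equal(dplyr::filter(counts, gene == "GENEX")$carriers, 0L)
  expect_error(count_carriers(ds, "overabundance", genes = "NOPE"),
               "not in panel")
  # carrier-burden rule needs the control cohort
  ctrl <- cohort_dataset(toy_panel(), toy_samples("C1", role = "control"))
  cb <- count_carriers(ds, "carrier_burden", controls = ctrl)
  expect_equal(dplyr::filter(cb, gene == "GENEA")$carriers, 3L)
})

test_that("carrier burden applies Bonferroni with a cap and flags degeneracy", {
  r0 <- carrier_burden_test(0, 271, 0.002, G = 112)
  expect_equal(r0$raw_p, 1)
  expect_equal(r0$corrected_p, 1)
  expect_false(r0$significant)

  r <- carrier_burden_test(3, 271, 1e-5, G = 112)
  expect_equal(r$corrected_p, min(1, r$raw_p * 112))
  expect_true(r$corrected_p >= r$raw_p)
  expect_equal(carrier_burden_test(3, 271, 1e-5, G = 1)$corrected_p,
               carrier_burden_test(3, 271, 1e-5, G = 1)$raw_p)

  # published ERLIN1 inputs, checked against the pmf-summation oracle (the
  # published corrected value itself is not reproducible from these inputs)
  er <- carrier_burden_test(3, 271, 0.0002, G = 112)
  expect_equal(er$raw_p, binom_tail_oracle(3, 271, 0.0002), tolerance = 1e-12)
  expect_equal(er$corrected_p, min(1, binom_tail_oracle(3, 271, 0.0002) * 112))

  dg <- carrier_burden_test(2, 271, 0, G = 112)
  expect_true(dg$degenerate)
  expect_equal(dg$raw_p, 0)
  expect_error(carrier_burden_test(1, 10, 0.1, G = 0), "G")
})

test_that("overabundance test implements the small-p two-tailed method", {
  # observed at the mode -> p = 1
  md <- overabundance_test(1, 10, 10, 100)   # phat 0.1, mode 1
  expect_equal(md$raw_p, 1)
  # frozen enumeration oracle for k=5, n=10, phat=0.1
  ov <- overabundance_test(5, 10, 10, 100)
  expect_equal(ov$raw_p, two_tailed_oracle(5, 10, 0.1), tolerance = 1e-12)
  expect_equal(ov$raw_p, 0.001634937, tolerance = 1e-6)
  # agreement with the independent implementation in stats::binom.test
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(5:300, 1)
      k <- sample(0:n, 1)
      m <- sample(1:50, 1)
      nc <- sample(100:600, 1)
      got <- overabundance_test(k, n, m, nc)$raw_p
      ref <- stats::binom.test(k, n, p = m / nc)$p.value
      expect_equal(got, ref, tolerance = 1e-9)
    }
  })
  # zero cases and zero control carriers without pseudo-count: the observed
  # outcome is the only possible one
  cfg_np <- threshold_config(ctrl_pseudo_count = FALSE)
  expect_equal(overabundance_test(0, 10, 0, 100, cfg_np)$raw_p, 1)
  # pseudo-count fallback engages when control count is zero
  ps <- overabundance_test(3, 271, 0, 503)
  expect_equal(ps$p0, 0.5 / 503)
  expect_error(overabundance_test(1, 10, 0, 0), "positive")
  expect_error(overabundance_test(11, 10, 1, 100), "exceed")
})

test_that("overabundance test is symmetric around one half", {
  a <- overabundance_test(3, 10, 50, 100)$raw_p
  b <- overabundance_test(7, 10, 50, 100)$raw_p
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("burden analysis over a simulated pair behaves sensibly", {
  cfg <- simulation_config(n_cases = 60, n_controls = 80,
                           gene_models = tibble::tibble(
                             gene = load_synthetic_panel()$genes$gene,
                             control_carrier_rate = 0.05,
                             case_enrichment = 1
                           ))
  sim <- simulate_cohort(cfg, seed = 21)
  res <- run_burden_analysis(sim$cases, sim$controls)
  expect_setequal(unique(res$test), c("carrier_burden", "overabundance"))
  # sorted by corrected p then gene
  expect_true(all(diff(res$corrected_p) >= 0 |
                    diff(as.integer(factor(res$gene))) != 0))
  expect_true(all(res$corrected_p >= res$raw_p - 1e-15))
  # tidy/glance interfaces
  td <- tidy(res)
  expect_true(all(c("estimate", "p.value", "adj.p.value") %in% names(td)))
  expect_equal(nrow(glance(res)), 2)

  # control-only variants: all case counts 0, all raw p 1 for carrier burden
  sim0 <- simulate_cohort(
    simulation_config(n_cases = 30, n_controls = 50,
                      gene_models = tibble::tibble(
                        gene = load_synthetic_panel()$genes$gene,
                        control_carrier_rate = 0.08, case_enrichment = 0
                      )),
    seed = 5
  )
  res0 <- run_burden_analysis(sim0$cases, sim0$controls)
  cb0 <- dplyr::filter(res0, test == "carrier_burden")
  expect_true(all(cb0$k_case == 0))
  expect_true(all(cb0$raw_p == 1))
})

test_that("enrichment shifts carrier-burden p-values downward", {
  genes <- load_synthetic_panel()$genes$gene
  # scaled-down control cohort: the rarity cut-off scales with it, since a
  # singleton among 150 controls already exceeds MAF 0.001
  cfg <- threshold_config(burden_maf_max = 5e-3)
  null_cfg <- simulation_config(
    n_cases = 120, n_controls = 150,
    gene_models = tibble::tibble(gene = genes, control_carrier_rate = 0.02,
                                 case_enrichment = 1)
  )
  enr_cfg <- simulation_config(
    n_cases = 120, n_controls = 150,
    gene_models = tibble::tibble(gene = genes, control_carrier_rate = 0.02,
                                 case_enrichment = 10)
  )
  sim_n <- simulate_cohort(null_cfg, seed = 3)
  sim_e <- simulate_cohort(enr_cfg, seed = 3)
  p_null <- run_burden_analysis(sim_n$cases, sim_n$controls, cfg)
  p_enr <- run_burden_analysis(sim_e$cases, sim_e$controls, cfg)
  med <- function(r) median(dplyr::filter(r, test == "carrier_burden")$raw_p)
  expect_lt(med(p_enr), med(p_null))
})
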