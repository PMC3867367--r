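test_that("the whole simulation is a pure function of the seed", {
  a <- simulate_study(small_sim_config(seed = 9))
  b <- simulate_study(small_sim_config(seed = 9))
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$models, b$models)
  expect_identical(a$truth, b$truth)
  expect_identical(a$counts, b$counts)
  c <- simulate_study(small_sim_config(seed = 10))
  expect_false(identical(a$counts, c$counts))
})

test_that("zero densities plant nothing", {
  s <- simulate_study(small_sim_config(seed = 2, wt_snp_per_bp = 0,
                                       ems_rate = 0))
  expect_equal(nrow(s$truth), 0L)
})

test_that("wild-type planting follows the configured site density", {
  withr::with_seed(1, NULL)
  L <- 2300L; d <- 0.02
  n_planted <- vapply(1:12, function(s) {
    cfg <- sim_config(seed = s,
                      amplicons = tibble::tibble(id = "a", length = L),
                      wt_snp_per_bp = d, ems_rate = 0)
    ref <- simulate_reference(cfg)
    pop <- simulate_population(cfg, ref)
    nrow(pop$variants)
  }, numeric(1))
  ## planted count per run ~ Binomial(L, d); the mean of 12 runs sits
  ## within 3 sigma of L * d
  se <- sqrt(L * d * (1 - d) / 12)
  expect_lt(abs(mean(n_planted) - L * d), 3 * se)
})

test_that("every EMS variant is a reference-strand transition carried at
           2 copies per carrier, shared by the sibling group", {
  s <- simulate_study(small_sim_config(seed = 5, ems_rate = 5e-4))
  ems <- dplyr::filter(s$truth, origin == "ems")
  expect_gt(nrow(ems), 0)
  expect_true(all((ems$ref == "G" & ems$alt == "A") |
                  (ems$ref == "C" & ems$alt == "T")))
  pt <- dplyr::filter(s$pool_truth, origin == "ems", carrier_copies > 0)
  expect_true(all(pt$carrier_copies == 2 * pt$n_carriers))
  ## carriers never exceed the sibling cap, and the expected frequency
  ## is the exact pool-model ratio of its carrier copies
  expect_true(all(pt$n_carriers <= 3))
  for (i in seq_len(nrow(pt))) {
    dsg <- s$designs[s$designs$label == pt$pool[i], ]
    expect_equal(pt$expected_freq[i],
                 expected_allele_frequency(dsg,
                                           pt$carrier_copies[i])$frequency)
  }
})

test_that("a three-sibling family reaches 6 copies in its pool", {
  s <- simulate_study(small_sim_config(seed = 6, ems_rate = 2e-3))
  pt <- dplyr::filter(s$pool_truth, origin == "ems", carrier_copies > 0,
                      pool == "M109")
  expect_true(any(pt$n_carriers == 3))
  six <- dplyr::filter(pt, n_carriers == 3)
  expect_true(all(six$expected_freq == 6 / 436))
})

test_that("error-free counts contain only planted alleles", {
  cfg <- small_sim_config(seed = 8, error_rate = 0, depth_sdlog = 0)
  s <- simulate_study(cfg)
  counts <- dplyr::filter(s$counts, pool == "C109")
  m <- as.matrix(counts[, c("A", "C", "G", "T")])
  nonref <- rowSums(m) - m[cbind(seq_len(nrow(m)),
                                 match(counts$ref, c("A", "C", "G", "T")))]
  planted <- dplyr::filter(s$pool_truth, pool == "C109",
                           carrier_copies > 0)
  is_planted <- paste(counts$amplicon, counts$pos) %in%
    paste(planted$amplicon, planted$pos)
  expect_true(all(nonref[!is_planted] == 0))
  ## flat multiplier means exactly the configured mean depth everywhere
  expect_true(all(rowSums(m) == 10000))
})

test_that("observed alt counts match the binomial error-flow oracle", {
  ## one variant at known pool frequency f, depth n: the alt count is
  ## Binomial(n, f(1-e) + (1-f)e/3); check the realised draw lies within
  ## 4 sigma of that mean at a handful of seeds
  e <- 0.001
  for (s in 1:4) {
    cfg <- small_sim_config(seed = s, error_rate = e, depth_sdlog = 0,
                            wt_snp_per_bp = 5e-3, ems_rate = 0)
    st <- simulate_study(cfg)
    pt <- dplyr::filter(st$pool_truth, pool == "M754", carrier_copies > 0)
    cc <- dplyr::filter(st$counts, pool == "M754")
    for (i in seq_len(min(nrow(pt), 10))) {
      row <- cc[cc$amplicon == pt$amplicon[i] & cc$pos == pt$pos[i], ]
      n <- sum(row[, c("A", "C", "G", "T")])
      p <- pt$expected_freq[i] * (1 - e) +
        (1 - pt$expected_freq[i]) * e / 3
      got <- row[[pt$alt[i]]]
      expect_lt(abs(got - n * p), 4 * sqrt(n * p * (1 - p)) + 1)
    }
  }
})

test_that("background noise converges to the error rate with depth", {
  cfg <- sim_config(seed = 3,
                    amplicons = tibble::tibble(id = "a", length = 4000L),
                    wt_snp_per_bp = 0, ems_rate = 0, error_rate = 0.002,
                    depth_sdlog = 0,
                    designs = pool_design("P", 10),
                    mean_depth = c(P = 50000))
  s <- simulate_study(cfg)
  m <- as.matrix(s$counts[, c("A", "C", "G", "T")])
  nonref <- 1 - m[cbind(seq_len(nrow(m)),
                        match(s$counts$ref, c("A", "C", "G", "T")))] /
    rowSums(m)
  expect_lt(abs(mean(nonref) - 0.002), 2e-4)
})

test_that("simulated references are reproducible and well-formed", {
  cfg <- small_sim_config(seed = 12)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(names(r1$sequences), c("gA", "gB"))
  expect_equal(unname(nchar(r1$sequences)), c(1500L, 800L))
  ## exon structure is valid by construction
  expect_silent(gene_models(r1$models, r1$sequences))
})
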