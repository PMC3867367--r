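mk_call <- function(pos, ref, alt, pool, frequency, amplicon = "a") {
  tibble::tibble(amplicon = amplicon, pos = as.integer(pos), ref = ref,
                 alt = alt, alt_count = round(frequency * 10000),
                 coverage = 10000L, frequency = frequency, pool = pool)
}

test_that("membership and Venn regions enumerate the 3-set diagram", {
  ## pools P1 = {x, y}, P2 = {y, z}, P3 = {z}
  calls <- dplyr::bind_rows(
    mk_call(c(1, 2), "G", "A", "P1", 0.01),
    mk_call(c(2, 3), "G", "A", "P2", 0.01),
    mk_call(3, "G", "A", "P3", 0.01))
  mem <- compare_pools(calls)
  expect_equal(nrow(mem), 3L)
  vc <- venn_counts(mem)
  expected <- c("P1" = 1L, "P2" = 0L, "P3" = 0L,
                "P1&P2" = 1L, "P1&P3" = 0L, "P2&P3" = 1L,
                "P1&P2&P3" = 0L)
  expect_identical(setNames(vc$n, vc$region), expected)
  expect_equal(sum(vc$n), nrow(mem))        # conservation
})

test_that("identical pools populate only the full intersection", {
  one <- mk_call(c(1, 5, 9), c("G", "C", "A"), c("A", "T", "G"), "P1",
                 c(0.01, 0.02, 0.3))
  calls <- dplyr::bind_rows(one,
                            dplyr::mutate(one, pool = "P2"),
                            dplyr::mutate(one, pool = "P3"))
  vc <- venn_counts(compare_pools(calls))
  expect_equal(vc$n[vc$region == "P1&P2&P3"], 3L)
  expect_equal(sum(vc$n), 3L)
})

test_that("an empty pool contributes an empty unique region", {
  calls <- dplyr::bind_rows(mk_call(1, "G", "A", "P1", 0.01),
                            mk_call(1, "G", "A", "P2", 0.01))
  mem <- compare_pools(calls)
  vc <- venn_counts(mem, labels = c("P1", "P2", "P3"))
  expect_equal(vc$n[vc$region == "P3"], 0L)
  expect_equal(sum(vc$n), 1L)
})

test_that("different alt alleles at one site are different SNPs", {
  calls <- dplyr::bind_rows(mk_call(7, "G", "A", "P1", 0.01),
                            mk_call(7, "G", "T", "P2", 0.01))
  mem <- compare_pools(calls)
  expect_equal(nrow(mem), 2L)
  expect_identical(sort(mem$pools), c("P1", "P2"))
})

test_that("duplicate SNP keys within one pool are rejected", {
  calls <- dplyr::bind_rows(mk_call(1, "G", "A", "P1", 0.01),
                            mk_call(1, "G", "A", "P1", 0.02))
  expect_error(compare_pools(calls), class = "tillpool_input_error")
})

designs3 <- dplyr::bind_rows(
  pool_design("C109", 109, is_mutant = FALSE),
  pool_design("M109", 109, is_mutant = TRUE),
  pool_design("M754", 754, is_mutant = TRUE))

classify1 <- function(calls, ...) {
  classify_ems(compare_pools(calls), designs3, ...)
}

test_that("EMS candidates need mutant-only, transition and window", {
  ## in-window transition unique to M109: passes
  ok <- classify1(mk_call(1, "G", "A", "M109", 0.009))
  expect_true(ok$passes)
  expect_identical(ok$reasons, "")

  ## transversion fails on signature alone
  tv <- classify1(mk_call(1, "G", "C", "M109", 0.009))
  expect_false(tv$passes)
  expect_match(tv$reasons, "transition-signature")

  ## shared with the control pool is wild-type polymorphism
  shared <- classify1(dplyr::bind_rows(
    mk_call(1, "G", "A", "C109", 0.009),
    mk_call(1, "G", "A", "M109", 0.009)))
  expect_false(shared$passes)
  expect_match(shared$reasons, "control-shared")

  ## window containment is inclusive at both exact endpoints
  lo <- classify1(mk_call(1, "C", "T", "M109", 2 / 436))
  hi <- classify1(mk_call(1, "C", "T", "M109", 6 / 436))
  out <- classify1(mk_call(1, "C", "T", "M109", 0.016))
  expect_true(lo$passes)
  expect_true(hi$passes)
  expect_false(out$passes)
  expect_match(out$reasons, "frequency-window")

  ## the M754 window is its own, lower band
  m754_in <- classify1(mk_call(1, "G", "A", "M754", 0.001))
  m754_out <- classify1(mk_call(1, "G", "A", "M754", 0.009))
  expect_true(m754_in$passes)
  expect_false(m754_out$passes)
})

test_that("the strict unique-to switch narrows candidacy to one pool", {
  both <- dplyr::bind_rows(mk_call(1, "G", "A", "M109", 0.009),
                           mk_call(1, "G", "A", "M754", 0.001))
  default <- classify1(both)
  strict <- classify1(both, unique_to = "M109")
  expect_true(default$passes)
  expect_false(strict$passes)
})

test_that("unknown pool labels are rejected", {
  calls <- mk_call(1, "G", "A", "Mystery", 0.009)
  expect_error(classify_ems(compare_pools(calls), designs3),
               class = "tillpool_input_error")
})

test_that("no control-pool SNP is ever classified induced", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- 30
      calls <- tibble::tibble(
        amplicon = "a", pos = sample(1:500, n), ref = "G", alt = "A",
        alt_count = 90L, coverage = 10000L,
        frequency = runif(n, 0.001, 0.02),
        pool = sample(c("C109", "M109", "M754"), n, replace = TRUE))
      calls <- dplyr::distinct(calls, pool, pos, .keep_all = TRUE)
      cls <- classify_ems(compare_pools(calls), designs3)
      in_control <- grepl("C109", cls$pools)
      expect_false(any(cls$passes & in_control))
    }
  })
})

test_that("the wildtype/induced partition is disjoint and exhaustive", {
  calls <- dplyr::bind_rows(
    mk_call(1:6, "G", "A", "M109", 0.009),                  # 6 candidates
    mk_call(7:10, "C", "G", "M109", 0.009),                 # transversions
    mk_call(c(3, 11), "G", "A", "C109", 0.009))             # 3 shared/control
  part <- partition_variants(classify1(calls))
  tab <- table(part$class)
  expect_equal(unname(tab[["induced"]]), 5L)   # SNP 3 shared with control
  expect_equal(unname(tab[["wildtype"]]), 6L)
  expect_equal(sum(tab), nrow(part))
  expect_error(partition_variants(compare_pools(calls)),
               class = "tillpool_input_error")
})
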