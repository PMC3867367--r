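## One hand-built amplicon: 5' intron, a single exon, 3' intron.
## Exon (phase 0, + strand): ATG GGG TGG TAC TAA -> M G W Y *
hand_model <- function(strand = "+", phase = 0L) {
  tibble::tibble(amplicon = "h", exon_start = 10L, exon_end = 25L,
                 strand = strand, phase = phase)
}
hand_seq <- c(h = paste0("ACGTACGTAC", "ATGGGGTGGTACTAA", "GTACGTACGT"))

mk_snp <- function(pos, ref, alt, amplicon = "h") {
  tibble::tibble(amplicon = amplicon, pos = as.integer(pos),
                 ref = ref, alt = alt)
}

test_that("codon effects follow the standard genetic code", {
  ## TGG codon (pos 16-18): G->A at the third base gives TGA, a stop
  stop_snp <- annotate_snps(mk_snp(18, "G", "A"), hand_model(), hand_seq)
  expect_identical(stop_snp$effect, "stop_gained")
  expect_identical(stop_snp$ref_codon, "TGG")
  expect_identical(stop_snp$alt_codon, "TGA")
  expect_identical(stop_snp$ref_aa, "W")
  expect_identical(stop_snp$alt_aa, "*")
  expect_equal(stop_snp$codon_pos, 3L)

  ## GGG codon (pos 13-15): G->A at the third base is synonymous Gly
  syn <- annotate_snps(mk_snp(15, "G", "A"), hand_model(), hand_seq)
  expect_identical(syn$effect, "synonymous")
  expect_identical(syn$alt_codon, "GGA")

  ## GGG -> CGG at the first base: Gly -> Arg, nonsynonymous
  nonsyn <- annotate_snps(mk_snp(13, "G", "C"), hand_model(), hand_seq)
  expect_identical(nonsyn$effect, "nonsynonymous")
  expect_identical(nonsyn$alt_aa, "R")

  ## intronic SNP gets no codon fields
  intr <- annotate_snps(mk_snp(3, "T", "A"), hand_model(), hand_seq)
  expect_identical(intr$region, "intronic")
  expect_identical(intr$effect, "not_applicable")
  expect_true(is.na(intr$ref_codon))
})

test_that("minus-strand models are reverse-complemented before codons", {
  ## On the minus strand the exon reads TTAGTACCACCCCAT: its first codon
  ## is TTA (Leu). The genomic T at pos 24 is the first coding base.
  snp <- annotate_snps(mk_snp(24, "A", "T"), hand_model(strand = "-"),
                       hand_seq)
  expect_identical(snp$region, "exonic")
  expect_identical(snp$ref_codon, "TTA")
  expect_equal(snp$codon_pos, 1L)
  expect_identical(snp$alt_codon, "ATA")   # alt T complements to A
  expect_identical(snp$effect, "nonsynonymous")
})

test_that("phase shifts the reading frame and flags partial codons", {
  ## with phase 1 the first exon base is the tail of an upstream codon
  snp <- suppressWarnings(
    annotate_snps(mk_snp(10, "A", "G"), hand_model(phase = 1L), hand_seq))
  expect_identical(snp$region, "exonic")
  expect_identical(snp$effect, "not_applicable")
  ## and the frame moves: pos 11-13 now form the first complete codon
  expect_warning(
    shifted <- annotate_snps(mk_snp(c(10, 11), c("A", "T"), c("G", "A")),
                             hand_model(phase = 1L), hand_seq),
    "partial codon")
  expect_identical(shifted$ref_codon[2], "TGG")
  expect_equal(shifted$codon_pos[2], 1L)
})

test_that("a SNP whose ref disagrees with the model sequence errors", {
  expect_error(annotate_snps(mk_snp(13, "C", "A"), hand_model(), hand_seq),
               class = "tillpool_consistency_error")
  expect_error(annotate_snps(mk_snp(999, "G", "A"), hand_model(), hand_seq),
               class = "tillpool_input_error")
})

test_that("malformed gene models are rejected", {
  m <- hand_model(); m$exon_end <- 5L
  expect_error(gene_models(m), class = "tillpool_format_error")
  overlap <- dplyr::bind_rows(hand_model(),
                              tibble::tibble(amplicon = "h",
                                             exon_start = 20L,
                                             exon_end = 30L,
                                             strand = "+", phase = 0L))
  expect_error(gene_models(overlap), class = "tillpool_format_error")
  beyond <- hand_model(); beyond$exon_end <- 99L
  expect_error(gene_models(beyond, hand_seq),
               class = "tillpool_format_error")
  badphase <- hand_model(); badphase$phase <- 3L
  expect_error(gene_models(badphase), class = "tillpool_format_error")
})

test_that("effect summary partitions the annotated set", {
  ## planted: 2 stop + 3 other nonsynonymous + 4 synonymous + 5 intronic
  ann <- tibble::tibble(
    region = c(rep("exonic", 9), rep("intronic", 5)),
    effect = c(rep("stop_gained", 2), rep("nonsynonymous", 3),
               rep("synonymous", 4), rep("not_applicable", 5)))
  s <- effect_summary(ann)
  expect_equal(s$nonsynonymous, 5L)   # stops counted within nonsynonymous
  expect_equal(s$stop_gained, 2L)
  expect_equal(s$synonymous, 4L)
  expect_equal(s$intronic, 5L)
  expect_equal(s$total, 14L)
  expect_equal(s$nonsynonymous + s$synonymous + s$intronic +
                 s$not_applicable, s$total)
  empty <- effect_summary(ann[0, ])
  expect_equal(empty$total, 0L)
})

test_that("annotation is order-independent and matches the CDS oracle", {
  withr::with_seed(41, {
    ref <- simulate_reference(sim_config(
      seed = 41, amplicons = tibble::tibble(id = c("x", "y"),
                                            length = c(1200L, 700L))))
    snps <- list()
    for (i in 1:120) {
      amp <- sample(names(ref$sequences), 1)
      L <- nchar(ref$sequences[[amp]])
      pos <- sample(0:(L - 1), 1)
      rb <- substr(ref$sequences[[amp]], pos + 1, pos + 1)
      snps[[i]] <- mk_snp(pos, rb, sample(setdiff(c("A", "C", "G", "T"),
                                                  rb), 1), amplicon = amp)
    }
    snps <- dplyr::distinct(dplyr::bind_rows(snps))
    ann <- suppressWarnings(
      annotate_snps(snps, ref$models, ref$sequences))
    shuffled <- suppressWarnings(
      annotate_snps(snps[sample(nrow(snps)), ], ref$models,
                    ref$sequences))
    expect_identical(
      dplyr::arrange(ann, amplicon, pos, alt),
      dplyr::arrange(shuffled, amplicon, pos, alt))
    for (i in seq_len(nrow(ann))) {
      want <- oracle_effect(ref$models, ref$sequences, ann$amplicon[i],
                            ann$pos[i], ann$ref[i], ann$alt[i])
      got <- if (ann$region[i] == "intronic") "intronic" else ann$effect[i]
      expect_identical(got, want)
    }
  })
})
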