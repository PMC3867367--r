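#' Validate a table of gene models
#'
#' A gene model places the coding structure on an amplicon: ordered,
#' non-overlapping exon intervals in 0-based half-open amplicon
#' coordinates, a strand, and the phase (0/1/2) of the first coding base
#' in transcription order. Amplicons are typically partial gene
#' sequences, so the concatenated exons need not start or end on a codon
#' boundary; leading (`phase`) and trailing partial codons are flagged at
#' annotation time rather than guessed at.
#'
#' @param models Tibble with columns `amplicon`, `exon_start`, `exon_end`,
#'   `strand` (`"+"`/`"-"`), `phase` (constant within an amplicon).
#' @param reference Optional named sequences; when given, exon bounds are
#'   checked against each amplicon's length.
#' @return The validated tibble, exons sorted within amplicon.
#' @export
gene_models <- function(models, reference = NULL) {
  needed <- c("amplicon", "exon_start", "exon_end", "strand", "phase")
  missing <- setdiff(needed, names(models))
  if (length(missing))
    abort(paste0("Gene-model table is missing: ",
                 paste(missing, collapse = ", ")),
          class = "tillpool_format_error")
  models <- arrange(models, .data$amplicon, .data$exon_start)
  if (!all(models$strand %in% c("+", "-")))
    abort("strand must be '+' or '-'.", class = "tillpool_format_error")
  if (!all(models$phase %in% 0:2))
    abort("phase must be 0, 1 or 2.", class = "tillpool_format_error")
  by_amp <- split(models, models$amplicon)
  for (m in by_amp) {
    if (length(unique(m$strand)) > 1L || length(unique(m$phase)) > 1L)
      abort(paste0("strand/phase must be constant within amplicon ",
                   m$amplicon[1]), class = "tillpool_format_error")
    if (any(m$exon_start < 0) || any(m$exon_end <= m$exon_start))
      abort("Exon intervals must satisfy 0 <= start < end.",
            class = "tillpool_format_error")
    if (nrow(m) > 1L && any(m$exon_start[-1] < m$exon_end[-nrow(m)]))
      abort(paste0("Exons overlap in amplicon ", m$amplicon[1]),
            class = "tillpool_format_error")
    if (!is.null(reference)) {
      seqs <- as_sequences(reference)
      if (!m$amplicon[1] %in% names(seqs))
        abort(paste0("No sequence for amplicon ", m$amplicon[1]),
              class = "tillpool_input_error")
      if (max(m$exon_end) > nchar(seqs[[m$amplicon[1]]]))
        abort(paste0("Exon beyond sequence end in ", m$amplicon[1]),
              class = "tillpool_format_error")
    }
  }
  models
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Coding map of one amplicon: genomic positions in transcription order,
## the CDS string read on the coding strand, and the usable codon span.
coding_map <- function(model_rows, sequence) {
  strand <- model_rows$strand[1]
  phase <- model_rows$phase[1]
  gpos <- unlist(purrr::map2(model_rows$exon_start, model_rows$exon_end,
                             function(s, e) seq.int(s, e - 1L)))
  bases <- strsplit(sequence, "")[[1]][gpos + 1L]
  if (strand == "-") {
    gpos <- rev(gpos)
    bases <- unname(COMPLEMENT[rev(bases)])
  }
  n_cod <- (length(gpos) - phase) %/% 3L
  list(gpos = gpos, bases = bases, phase = phase, strand = strand,
       n_codons = max(n_cod, 0L))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate SNP calls with putative functional effects
#'
#' Assigns each SNP a region (exonic/intronic) and, for exonic SNPs, a
#' codon-level effect under the standard genetic code: `synonymous`,
#' `nonsynonymous`, or `stop_gained` (reference codon is not a stop, the
#' alternate is). Minus-strand models are reverse-complemented before
#' codon assembly. SNPs falling in a leading or trailing partial codon of
#' a partially sequenced coding region are flagged `not_applicable` with
#' a warning, since their frame cannot be established from the amplicon
#' alone. Effects are computed against the single reference haplotype on
#' the premise that the homeologous copies are potentially functional and
#' share the polymorphism.
#'
#' @param calls [call_snps()] output (or any tibble with `amplicon`,
#'   `pos`, `ref`, `alt`).
#' @param models [gene_models()] table.
#' @param reference Named amplicon sequences.
#' @return `calls` with added `region` (`exonic`/`intronic`), `effect`
#'   (`synonymous`/`nonsynonymous`/`stop_gained`/`not_applicable`),
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `codon_pos` (1-based
#'   position within the codon; `NA` outside complete codons).
#' @export
annotate_snps <- function(calls, models, reference) {
  reference <- as_sequences(reference)
  models <- gene_models(models, reference)
  maps <- purrr::map(split(models, models$amplicon), function(m)
    coding_map(m, reference[[m$amplicon[1]]]))

  n <- nrow(calls)
  region <- rep("intronic", n)
  effect <- rep("not_applicable", n)
  ref_codon <- alt_codon <- ref_aa <- alt_aa <- rep(NA_character_, n)
  codon_pos <- rep(NA_integer_, n)
  partial <- FALSE

  for (i in seq_len(n)) {
    amp <- calls$amplicon[i]
    seq <- reference[[amp]]
    if (is.null(seq))
      abort(paste0("No sequence for amplicon ", amp),
            class = "tillpool_input_error")
    p <- calls$pos[i]
    if (p < 0 || p >= nchar(seq))
      abort("SNP position outside amplicon.", class = "tillpool_input_error")
    if (substr(seq, p + 1L, p + 1L) != calls$ref[i])
      abort(sprintf("SNP ref '%s' at %s:%d does not match the reference.",
                    calls$ref[i], amp, p),
            class = "tillpool_consistency_error")
    cm <- maps[[amp]]
    if (is.null(cm)) next  # no gene model: treated as non-coding
    t_idx <- match(p, cm$gpos)
    if (is.na(t_idx)) next
    region[i] <- "exonic"
    off <- t_idx - cm$phase
    cod <- if (off >= 1L) (off - 1L) %/% 3L + 1L else 0L
    if (cod < 1L || cod > cm$n_codons) { partial <- TRUE; next }
    within <- (off - 1L) %% 3L + 1L
    span <- cm$phase + (cod - 1L) * 3L + 1:3
    rc <- cm$bases[span]
    ac <- rc
    alt_on_coding <- if (cm$strand == "-") unname(COMPLEMENT[calls$alt[i]])
                     else calls$alt[i]
    ac[within] <- alt_on_coding
    ref_codon[i] <- paste(rc, collapse = "")
    alt_codon[i] <- paste(ac, collapse = "")
    ref_aa[i] <- translate_codon(ref_codon[i])
    alt_aa[i] <- translate_codon(alt_codon[i])
    codon_pos[i] <- within
    effect[i] <- if (alt_aa[i] == ref_aa[i]) "synonymous"
      else if (alt_aa[i] == "*" && ref_aa[i] != "*") "stop_gained"
      else "nonsynonymous"
  }
  if (partial)
    warn(paste("Some exonic SNPs fall in a leading/trailing partial codon;",
               "annotated as not_applicable."))
  calls %>%
    mutate(region = region, effect = effect,
           ref_codon = ref_codon, alt_codon = alt_codon,
           ref_aa = ref_aa, alt_aa = alt_aa, codon_pos = codon_pos)
}

#' Tally SNPs by predicted functional effect
#'
#' Counts the annotation categories the way such screens report them:
#' `nonsynonymous` includes premature stop codons, which are also counted
#' separately as `stop_gained`; `synonymous`, `intronic` and
#' `not_applicable` complete the partition, so
#' `nonsynonymous + synonymous + intronic + not_applicable = total`.
#'
#' @param annotations [annotate_snps()] output.
#' @return One-row tibble: `nonsynonymous`, `stop_gained`, `synonymous`,
#'   `intronic`, `not_applicable`, `total`.
#' @export
effect_summary <- function(annotations) {
  eff <- annotations$effect
  reg <- annotations$region
  tibble(
    nonsynonymous = sum(eff %in% c("nonsynonymous", "stop_gained")),
    stop_gained = sum(eff == "stop_gained"),
    synonymous = sum(eff == "synonymous"),
    intronic = sum(reg == "intronic"),
    not_applicable = sum(reg == "exonic" & eff == "not_applicable"),
    total = length(eff)
  )
}
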