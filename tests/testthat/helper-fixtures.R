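## Shared fixtures: everything is built in code, nothing read from disk.

toy_counts <- function() {
  tibble::tibble(
    amplicon = "amp1", pos = 0:3, ref = c("A", "G", "G", "C"),
    A = c(1000L, 0L, 100L, 2L), C = c(0L, 0L, 0L, 992L),
    G = c(0L, 994L, 299L, 3L), T = c(0L, 6L, 0L, 3L), N = 0L)
}

random_counts <- function(n_sites = 50, depth = 1000) {
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  cm <- t(vapply(seq_len(n_sites), function(i) {
    p <- c(A = 0.001, C = 0.001, G = 0.001, T = 0.001)
    p[ref[i]] <- 1 - sum(p[names(p) != ref[i]])
    as.integer(rmultinom(1, depth, p))
  }, integer(4)))
  tibble::tibble(amplicon = "r", pos = seq_len(n_sites) - 1L, ref = ref,
                 A = cm[, 1], C = cm[, 2], G = cm[, 3], T = cm[, 4],
                 N = 0L)
}

## A small, fast synthetic screen: same pool structure as the full
## study, short amplicons and moderate depth.
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    amplicons = tibble::tibble(id = c("gA", "gB"),
                               length = c(1500L, 800L)),
    mean_depth = c(C109 = 10000, M109 = 10000, M754 = 10000),
    ...)
}

## Independent effect oracle: rebuild the complete CDS in transcription
## order, substitute, translate both proteins with Biostrings and diff.
oracle_effect <- function(models, sequences, amplicon, pos, ref, alt) {
  m <- models[models$amplicon == amplicon, ]
  seq <- strsplit(sequences[[amplicon]], "")[[1]]
  stopifnot(seq[pos + 1] == ref)
  gpos <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                     m$exon_start, m$exon_end))
  if (!(pos %in% gpos)) return("intronic")
  alt_seq <- seq
  alt_seq[pos + 1] <- alt
  get_cds <- function(bases) {
    cds <- bases[gpos + 1]
    if (m$strand[1] == "-")
      cds <- rev(chartr("ACGT", "TGCA", cds))
    cds <- cds[-seq_len(m$phase[1])]
    cds[seq_len(3 * (length(cds) %/% 3))]
  }
  cds_ref <- get_cds(seq)
  cds_alt <- get_cds(alt_seq)
  if (identical(cds_ref, cds_alt)) return("not_applicable")  # partial codon
  p_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(cds_ref, collapse = "")),
    if.fuzzy.codon = "X"))
  p_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(cds_alt, collapse = "")),
    if.fuzzy.codon = "X"))
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  aa_alt <- strsplit(p_alt, "")[[1]][d]
  aa_ref <- strsplit(p_ref, "")[[1]][d]
  if (aa_alt == "*" && aa_ref != "*") "stop_gained" else "nonsynonymous"
}
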