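#' Call SNPs from a pooled base-count table
#'
#' A SNP call is a (site, alternate base) pair whose coverage meets the
#' minimum depth (inclusive, default 400x) and whose alternate-allele
#' frequency strictly exceeds the error-derived threshold (default 0.5%).
#' Several alternate alleles at one site yield several calls. The
#' reference allele always comes from the supplied reference sequence,
#' never from the pool majority, so high-frequency variants are not
#' silently re-referenced.
#'
#' @param counts Count table (see [site_frequencies()]); a `ref` column
#'   is used if present and checked against `reference` when both exist.
#' @param reference Optional named character vector (or
#'   `Biostrings::DNAStringSet`) of amplicon sequences; lengths must match
#'   the count table.
#' @param min_coverage Inclusive depth floor (default 400).
#' @param min_frequency Strict frequency threshold (default 0.005).
#' @param pool Pool label attached to the calls; defaults to a `pool`
#'   column in `counts` if present.
#' @return Tibble of calls sorted by (amplicon, pos, alt): `amplicon`,
#'   `pos` (0-based), `ref`, `alt`, `alt_count`, `coverage`, `frequency`,
#'   `pool`, satisfying `frequency == alt_count / coverage` exactly.
#' @examples
#' counts <- tibble::tibble(amplicon = "amp1", pos = 0:1, ref = c("A", "G"),
#'                          A = c(1000L, 0L), C = 0L, G = c(0L, 994L),
#'                          T = c(0L, 6L), N = 0L)
#' call_snps(counts, min_coverage = 400, pool = "M109")
#' @export
call_snps <- function(counts, reference = NULL, min_coverage = 400,
                      min_frequency = 0.005, pool = NULL) {
  validate_counts(counts)
  counts <- attach_reference(counts, reference)
  if (is.null(pool)) {
    pool <- if ("pool" %in% names(counts)) counts$pool else NA_character_
  }
  counts$pool <- pool
  if (!all(counts$ref %in% BASES))
    abort("Reference bases must be A/C/G/T.", class = "tillpool_input_error")

  long <- counts %>%
    mutate(coverage = .data$A + .data$C + .data$G + .data$T) %>%
    select(all_of(c("amplicon", "pos", "ref", "pool", "coverage", BASES))) %>%
    tidyr::pivot_longer(all_of(BASES), names_to = "alt",
                        values_to = "alt_count") %>%
    filter(.data$alt != .data$ref,
           .data$coverage >= min_coverage,
           .data$alt_count / .data$coverage > min_frequency) %>%
    mutate(frequency = .data$alt_count / .data$coverage) %>%
    select(all_of(c("amplicon", "pos", "ref", "alt", "alt_count",
                    "coverage", "frequency", "pool"))) %>%
    arrange(.data$amplicon, .data$pos, .data$alt)
  long
}

attach_reference <- function(counts, reference) {
  if (!is.null(reference)) {
    reference <- as_sequences(reference)
    ref_col <- character(nrow(counts))
    for (amp in unique(counts$amplicon)) {
      if (!amp %in% names(reference))
        abort(paste0("No reference sequence for amplicon ", amp),
              class = "tillpool_input_error")
      idx <- which(counts$amplicon == amp)
      seq <- strsplit(reference[[amp]], "")[[1]]
      if (length(idx) != length(seq))
        abort(paste0("Reference/count-table length mismatch for ", amp),
              class = "tillpool_input_error")
      ref_col[idx] <- seq[counts$pos[idx] + 1L]
    }
    if ("ref" %in% names(counts) && !all(counts$ref == ref_col))
      abort("`ref` column disagrees with the supplied reference.",
            class = "tillpool_input_error")
    counts$ref <- ref_col
  }
  if (!"ref" %in% names(counts))
    abort("Provide a `ref` column or a reference sequence set.",
          class = "tillpool_input_error")
  counts
}

as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x) || is.null(names(x)))
    abort("Reference must be a named character vector or DNAStringSet.",
          class = "tillpool_input_error")
  toupper(x)
}

#' Summarise background noise against a frequency threshold
#'
#' For the sites declared non-variant, computes per amplicon the
#' distribution of the maximum non-reference base frequency and the
#' fraction of sites whose noise exceeds the calling threshold. Used to
#' verify, on simulated error-only data, that a threshold (0.5% by
#' default) sits far above the sequencing-noise floor: at per-base error
#' e and depth n the exceedance probability is the binomial tail
#' `P(Bin(n, e) > n * threshold)`.
#'
#' @param stats Output of [site_frequencies()] with a `ref` column.
#' @param threshold Frequency threshold to test (default 0.005).
#' @param exclude Optional tibble of known variant sites (`amplicon`,
#'   `pos`) to drop before summarising.
#' @return Per-amplicon tibble: `n_sites`, `mean_noise`, `max_noise`,
#'   `n_above`, `frac_above`; zero rows (with a warning) when no
#'   non-variant site has coverage. The threshold is stored in
#'   `attr(, "threshold")`.
#' @export
error_threshold_report <- function(stats, threshold = 0.005, exclude = NULL) {
  if (!"ref" %in% names(stats))
    abort("`stats` needs a `ref` column.", class = "tillpool_input_error")
  if (!"f_A" %in% names(stats)) stats <- site_frequencies(stats)
  if (!is.null(exclude) && nrow(exclude)) {
    stats <- dplyr::anti_join(stats, exclude[, c("amplicon", "pos")],
                              by = c("amplicon", "pos"))
  }
  stats <- stats %>% filter(!.data$no_data)
  if (!nrow(stats)) {
    warn("No covered non-variant sites; noise summary is empty.")
    out <- tibble(amplicon = character(), n_sites = integer(),
                  mean_noise = double(), max_noise = double(),
                  n_above = integer(), frac_above = double())
    attr(out, "threshold") <- threshold
    return(out)
  }
  fm <- as.matrix(stats[, paste0("f_", BASES)])
  ref_idx <- match(stats$ref, BASES)
  fm[cbind(seq_len(nrow(fm)), ref_idx)] <- NA_real_
  stats$noise <- apply(fm, 1L, max, na.rm = TRUE)
  out <- stats %>%
    group_by(.data$amplicon) %>%
    summarise(n_sites = n(),
              mean_noise = mean(.data$noise),
              max_noise = max(.data$noise),
              n_above = sum(.data$noise > threshold),
              frac_above = mean(.data$noise > threshold))
  attr(out, "threshold") <- threshold
  out
}
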