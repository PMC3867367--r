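BASES <- c("A", "C", "G", "T")

validate_counts <- function(counts) {
  needed <- c("amplicon", "pos", BASES, "N")
  missing <- setdiff(needed, names(counts))
  if (length(missing))
    abort(paste0("Count table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tillpool_format_error")
  cm <- as.matrix(counts[, c(BASES, "N")])
  if (any(is.na(cm)) || any(cm < 0) || any(cm != floor(cm)))
    abort("Base counts must be non-negative integers.",
          class = "tillpool_format_error")
  bad <- counts %>%
    group_by(across(dplyr::any_of(c("amplicon", "pool")))) %>%
    summarise(ok = identical(sort(.data$pos), seq(0L, n() - 1L)),
              .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad))
    abort(paste0("Positions must be contiguous 0..L-1 within amplicon(s): ",
                 paste(bad$amplicon, collapse = ", ")),
          class = "tillpool_format_error")
  invisible(counts)
}

#' Per-site coverage and base frequencies
#'
#' Converts a per-pool base-count table into per-site coverage and base
#' frequencies. Coverage is `A + C + G + T`; ambiguous `N` calls carry no
#' allele information and are excluded from both coverage and frequency
#' denominators. Zero-coverage sites are kept and flagged (`no_data`),
#' with `NA` frequencies, rather than dropped.
#'
#' @param counts Tibble with columns `amplicon`, `pos` (0-based,
#'   contiguous per amplicon), `A`, `C`, `G`, `T`, `N`, and optionally
#'   `ref` and `pool` (carried through).
#' @return The input tibble with added columns `coverage`, `f_A`, `f_C`,
#'   `f_G`, `f_T` and logical `no_data`.
#' @examples
#' counts <- tibble::tibble(amplicon = "amp1", pos = 0:1, ref = c("A", "G"),
#'                          A = c(1000L, 0L), C = 0L, G = c(0L, 994L),
#'                          T = c(0L, 6L), N = 0L)
#' site_frequencies(counts)
#' @export
site_frequencies <- function(counts) {
  validate_counts(counts)
  counts %>%
    mutate(coverage = .data$A + .data$C + .data$G + .data$T,
           no_data = .data$coverage == 0L,
           f_A = ifelse(.data$no_data, NA_real_, .data$A / .data$coverage),
           f_C = ifelse(.data$no_data, NA_real_, .data$C / .data$coverage),
           f_G = ifelse(.data$no_data, NA_real_, .data$G / .data$coverage),
           f_T = ifelse(.data$no_data, NA_real_, .data$T / .data$coverage))
}

#' Shenkin information-content variability of a site
#'
#' The per-position variability score of Shenkin et al. (1991):
#' `S = k * 2^H`, where `H = -sum(p_b * log2(p_b))` is the Shannon entropy
#' of the base-frequency distribution (terms with `p_b = 0` contribute
#' nothing). `S` ranges from `k` at a fully conserved site to `k * 4` at a
#' uniform site for the four-letter nucleotide alphabet. The scale constant
#' `k` (default 6, Shenkin's convention) affects presentation only — no
#' threshold in the pipeline depends on it.
#'
#' @param freq Numeric vector (or matrix with one row per site) of
#'   non-negative base frequencies summing to 1.
#' @param k Positive scale constant (default 6).
#' @param tol Tolerance on `sum(freq) == 1` (default 1e-9).
#' @return Numeric vector of S values (one per site).
#' @examples
#' shenkin_variability(c(1, 0, 0, 0))           # 6: fully conserved
#' shenkin_variability(rep(0.25, 4))            # 24: maximal variability
#' @export
shenkin_variability <- function(freq, k = 6, tol = 1e-9) {
  if (!is.matrix(freq)) freq <- matrix(freq, nrow = 1L)
  if (any(is.na(freq)) || any(freq < 0))
    abort("Frequencies must be non-negative and non-missing.",
          class = "tillpool_domain_error")
  if (any(abs(rowSums(freq) - 1) > tol))
    abort("Frequencies must sum to 1 at each site.",
          class = "tillpool_domain_error")
  if (k <= 0) abort("`k` must be positive.", class = "tillpool_domain_error")
  plogp <- freq * log2(freq)
  plogp[freq == 0] <- 0
  h <- -rowSums(plogp)
  as.numeric(k * 2^h)
}

#' Per-site statistics: coverage, frequencies and Shenkin S
#'
#' Runs [site_frequencies()] and appends the Shenkin variability score
#' `shenkin_s` ([shenkin_variability()]) at every covered site.
#'
#' @inheritParams site_frequencies
#' @param k Scale constant for the Shenkin score.
#' @return Tibble of per-site statistics (`shenkin_s` is `NA` where
#'   coverage is zero).
#' @export
site_stats <- function(counts, k = 6) {
  stats <- site_frequencies(counts)
  fm <- as.matrix(stats[, paste0("f_", BASES)])
  s <- rep(NA_real_, nrow(stats))
  ok <- !stats$no_data
  if (any(ok)) s[ok] <- shenkin_variability(fm[ok, , drop = FALSE], k = k)
  stats$shenkin_s <- s
  stats
}

#' Minimum-coverage mask
#'
#' Flags the sites of a count table that meet the minimum coverage
#' requirement for rare-allele calling. The comparison is inclusive:
#' a site at exactly `min_coverage` passes.
#'
#' @inheritParams site_frequencies
#' @param min_coverage Minimum read depth (default 400, roughly ten times
#'   the effective size of a 109-individual tetraploid pool).
#' @return The table with added `coverage` and logical `pass_coverage`.
#' @export
coverage_mask <- function(counts, min_coverage = 400) {
  if (min_coverage < 1)
    abort("`min_coverage` must be >= 1.", class = "tillpool_domain_error")
  validate_counts(counts)
  counts %>%
    mutate(coverage = .data$A + .data$C + .data$G + .data$T,
           pass_coverage = .data$coverage >= min_coverage)
}
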