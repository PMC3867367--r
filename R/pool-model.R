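#' Describe one sequenced equimolar pool
#'
#' A pool design records the sampling structure behind one deeply sequenced
#' amplicon pool: how many individuals were pooled, how many allele copies
#' each contributes (4 for a tetraploid treated as two diploid homeologous
#' subgenomes, 2 for a diploid), how many sibling M2 plants per M1 family
#' may share an induced mutation, and whether the pool is mutagenised or a
#' control. Every frequency threshold downstream derives from these counts.
#'
#' @param label Pool identifier, e.g. `"C109"`, `"M109"`, `"M754"`.
#' @param n_individuals Number of individuals pooled (>= 1).
#' @param copies_per_individual Allele copies contributed per individual;
#'   must be a positive even integer (default 4, tetraploid).
#' @param max_siblings Maximum number of siblings from one mutagenised
#'   family included in the pool (default 3).
#' @param is_mutant `TRUE` for a mutagenised pool, `FALSE` for a control.
#'
#' @return A one-row tibble of class `pool_design` with the fields above
#'   plus `total_copies = n_individuals * copies_per_individual`. Rows for
#'   several pools can be combined with [dplyr::bind_rows()].
#'
#' @examples
#' pool_design("M109", 109, is_mutant = TRUE)
#' @export
pool_design <- function(label, n_individuals, copies_per_individual = 4,
                        max_siblings = 3, is_mutant = FALSE) {
  stopifnot(is.character(label), length(label) == 1L)
  n_individuals <- as.integer(n_individuals)
  copies_per_individual <- as.integer(copies_per_individual)
  max_siblings <- as.integer(max_siblings)
  if (is.na(n_individuals) || n_individuals < 1L)
    abort("`n_individuals` must be >= 1.", class = "tillpool_domain_error")
  if (is.na(copies_per_individual) || copies_per_individual < 2L ||
      copies_per_individual %% 2L != 0L)
    abort("`copies_per_individual` must be a positive even integer.",
          class = "tillpool_domain_error")
  if (is.na(max_siblings) || max_siblings < 1L)
    abort("`max_siblings` must be >= 1.", class = "tillpool_domain_error")
  out <- tibble(
    label = label,
    n_individuals = n_individuals,
    copies_per_individual = copies_per_individual,
    total_copies = n_individuals * copies_per_individual,
    max_siblings = max_siblings,
    is_mutant = isTRUE(is_mutant)
  )
  class(out) <- c("pool_design", class(out))
  out
}

#' The three pool designs of a typical deep-pooled TILLING screen
#'
#' Convenience constructor for the default study structure: a control pool
#' and a mutant pool of 109 tetraploid individuals each, plus a mutant
#' screening pool of 754, all with up to 3 siblings per family.
#'
#' @return A three-row `pool_design` tibble (labels `C109`, `M109`, `M754`).
#' @export
default_pool_designs <- function() {
  bind_rows(
    pool_design("C109", 109, is_mutant = FALSE),
    pool_design("M109", 109, is_mutant = TRUE),
    pool_design("M754", 754, is_mutant = TRUE)
  )
}

pick_design <- function(designs, label) {
  row <- designs[designs$label == label, , drop = FALSE]
  if (nrow(row) != 1L)
    abort(paste0("Unknown or duplicated pool label: ", label),
          class = "tillpool_input_error")
  row
}

#' Expected allele frequency of a variant in an equimolar pool
#'
#' In an equimolar pool every allele copy contributes equally, so a variant
#' carried by `copies_carrying` of the pool's `total_copies` allele copies
#' is expected at frequency `copies_carrying / total_copies`. The ratio of
#' two integers is held exactly (numerator and denominator are carried
#' through to the percent label), and [render_percent()] reproduces the
#' conventional printed form: a single homozygous-in-one-subgenome carrier
#' among 109 tetraploids is 2/436, rendered "0.46%".
#'
#' @param design A one-row [pool_design()] tibble.
#' @param copies_carrying Integer vector; allele copies carrying the
#'   variant, each in `[0, total_copies]`.
#' @param digits Decimal places for the percent label (default 2,
#'   round-half-up).
#'
#' @return A tibble with one row per element of `copies_carrying`:
#'   `label`, `copies_carrying`, `total_copies`, `frequency` (double),
#'   `percent` (character label such as `"0.46%"`).
#'
#' @examples
#' m109 <- pool_design("M109", 109, is_mutant = TRUE)
#' expected_allele_frequency(m109, c(2, 6))
#' @export
expected_allele_frequency <- function(design, copies_carrying, digits = 2) {
  stopifnot(inherits(design, "pool_design"), nrow(design) == 1L)
  copies_carrying <- as.integer(copies_carrying)
  total <- design$total_copies
  if (any(is.na(copies_carrying)) || any(copies_carrying < 0L) ||
      any(copies_carrying > total))
    abort("`copies_carrying` must lie in [0, total_copies].",
          class = "tillpool_domain_error")
  tibble(
    label = design$label,
    copies_carrying = copies_carrying,
    total_copies = total,
    frequency = copies_carrying / total,
    percent = render_percent(copies_carrying, total, digits = digits)
  )
}

#' Render an exact copy-count ratio as a rounded percentage
#'
#' Computes `100 * numerator / denominator` and rounds half-up to `digits`
#' decimal places using integer arithmetic only, so ties and printed values
#' never depend on binary floating point. This matches how pool allele
#' frequencies are conventionally reported (e.g. 2/436 -> "0.46%").
#'
#' @param numerator,denominator Non-negative integer vector / positive
#'   integer scalar (recycled).
#' @param digits Decimal places (default 2).
#' @param suffix Appended unit, default `"%"`; use `""` for a bare number.
#' @return Character vector of labels.
#' @examples
#' render_percent(c(2, 6), 436)      # "0.46%" "1.38%"
#' render_percent(1, 192)            # "0.52%"
#' @export
render_percent <- function(numerator, denominator, digits = 2, suffix = "%") {
  numerator <- as.numeric(numerator)
  denominator <- as.numeric(denominator)
  if (any(denominator <= 0)) abort("denominator must be positive.",
                                   class = "tillpool_domain_error")
  if (any(numerator < 0)) abort("numerator must be non-negative.",
                                class = "tillpool_domain_error")
  scale <- 10^digits
  scaled <- numerator * 100 * scale
  q <- scaled %/% denominator
  r <- scaled %% denominator
  q <- q + as.numeric(2 * r >= denominator)  # round half up, exactly
  whole <- q %/% scale
  frac <- q %% scale
  if (digits == 0) return(paste0(whole, suffix))
  paste0(whole, ".", formatC(frac, width = digits, flag = "0"), suffix)
}

#' Predicted pool-frequency window for an EMS-induced mutation
#'
#' An EMS-induced G/C->A/T transition arising in one M1 plant is assumed
#' homozygous within a single subgenome, so each pooled carrier contributes
#' `copies_per_carrier` (default 2) allele copies. Because up to
#' `max_individuals` siblings sharing the founder mutation may enter the
#' pool, the expected pool frequency spans a window from the one-carrier to
#' the max-carrier value: 2/436 to 6/436 ("0.46%" to "1.38%") for a pool of
#' 109 tetraploids with up to 3 siblings.
#'
#' @param design A one-row [pool_design()] tibble.
#' @param min_individuals,max_individuals Range of pooled carriers sharing
#'   the mutation (defaults 1 and `design$max_siblings`).
#' @param copies_per_carrier Allele copies contributed per carrier
#'   (default 2: homozygous in one of two diploid subgenomes).
#' @param digits Decimal places for the percent labels.
#' @return A one-row tibble: `label`, `lo`, `hi` (fractions),
#'   `lo_percent`, `hi_percent` (labels), `min_copies`, `max_copies`,
#'   `total_copies`.
#' @examples
#' ems_frequency_window(pool_design("M754", 754, is_mutant = TRUE))
#' @export
ems_frequency_window <- function(design, min_individuals = 1,
                                 max_individuals = design$max_siblings,
                                 copies_per_carrier = 2, digits = 2) {
  stopifnot(inherits(design, "pool_design"), nrow(design) == 1L)
  min_individuals <- as.integer(min_individuals)
  max_individuals <- as.integer(max_individuals)
  copies_per_carrier <- as.integer(copies_per_carrier)
  if (min_individuals > max_individuals)
    abort("`min_individuals` must be <= `max_individuals`.",
          class = "tillpool_domain_error")
  if (copies_per_carrier > design$copies_per_individual)
    abort("`copies_per_carrier` cannot exceed `copies_per_individual`.",
          class = "tillpool_domain_error")
  w_lo <- expected_allele_frequency(
    design, min_individuals * copies_per_carrier, digits = digits)
  w_hi <- expected_allele_frequency(
    design, max_individuals * copies_per_carrier, digits = digits)
  tibble(
    label = design$label,
    lo = w_lo$frequency, hi = w_hi$frequency,
    lo_percent = w_lo$percent, hi_percent = w_hi$percent,
    min_copies = w_lo$copies_carrying, max_copies = w_hi$copies_carrying,
    total_copies = design$total_copies
  )
}
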