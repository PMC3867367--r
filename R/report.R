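#' Variants per megabase under an explicit denominator convention
#'
#' Computes `1e6 * n_variants / screened_bases`. Published per-Mb
#' densities from pooled screens are sensitive to what counts as
#' "screened": the amplicon length alone, or the amplicon length times
#' the number of individuals (and possibly subgenomes) screened. The
#' convention is therefore a mandatory label on the result, never an
#' implicit choice.
#'
#' @param n_variants Variant count (>= 0).
#' @param screened_bases Denominator in bases (> 0).
#' @param convention Character label describing the denominator, e.g.
#'   `"amplicon_bp"` or `"amplicon_bp_x_individuals"`.
#' @return One-row tibble: `n_variants`, `screened_bases`, `per_mb`
#'   (one decimal), `convention`.
#' @examples
#' snp_density(229, 16.0e6, "amplicon_bp_x_individuals")
#' @export
snp_density <- function(n_variants, screened_bases, convention) {
  if (screened_bases <= 0)
    abort("`screened_bases` must be positive.",
          class = "tillpool_domain_error")
  if (n_variants < 0)
    abort("`n_variants` must be non-negative.",
          class = "tillpool_domain_error")
  tibble(n_variants = as.integer(n_variants),
         screened_bases = screened_bases,
         per_mb = round(1e6 * n_variants / screened_bases, 1),
         convention = convention)
}

#' Aggregate the pipeline outputs into one consistent study summary
#'
#' Collects per-gene and per-pool SNP counts, the Venn region sizes, the
#' wild-type/induced partition, the effect tally and the density
#' estimates, and refuses to emit a summary whose internal conservation
#' checks fail (Venn regions must sum to the distinct-SNP total, the
#' partition and the effect categories must each sum to the total).
#'
#' @param calls Combined [call_snps()] output across pools.
#' @param classified [partition_variants()] output.
#' @param annotations [annotate_snps()] output for the distinct SNPs.
#' @param designs The `pool_design` table.
#' @param amplicon_lengths Named amplicon lengths (bp).
#' @param params Named list of threshold parameters to record (e.g.
#'   `min_coverage`, `min_frequency`).
#' @return An object of class `study_summary` with components
#'   `per_gene`, `per_pool`, `venn`, `partition`, `effects`,
#'   `densities`, `params`; it has [tidy()], [glance()], [autoplot()]
#'   and print methods.
#' @export
build_summary <- function(calls, classified, annotations, designs,
                          amplicon_lengths, params = list()) {
  total <- nrow(classified)
  venn <- venn_counts(classified,
                      labels = attr(classified, "pool_labels") %||%
                        designs$label[designs$label %in% calls$pool])
  if (sum(venn$n) != total)
    abort("Venn regions do not sum to the distinct SNP total.",
          class = "tillpool_consistency_error")
  part <- count(classified, .data$class, .drop = FALSE)
  if (sum(part$n) != total)
    abort("wildtype + induced != total SNPs.",
          class = "tillpool_consistency_error")
  eff <- effect_summary(annotations)
  if (eff$total != nrow(annotations) ||
      eff$nonsynonymous + eff$synonymous + eff$intronic +
        eff$not_applicable != eff$total)
    abort("Effect categories do not partition the annotated SNPs.",
          class = "tillpool_consistency_error")

  n_induced <- part$n[part$class == "induced"]
  n_wildtype <- part$n[part$class == "wildtype"]
  amp_bp <- sum(amplicon_lengths)
  n_screened <- sum(designs$n_individuals)
  densities <- bind_rows(
    snp_density(n_wildtype, amp_bp, "wildtype per amplicon bp"),
    snp_density(n_wildtype, amp_bp * n_screened,
                "wildtype per amplicon bp x individuals screened"),
    snp_density(n_induced, amp_bp, "induced per amplicon bp"),
    snp_density(n_induced, amp_bp * n_screened,
                "induced per amplicon bp x individuals screened"))

  structure(list(
    per_gene = count(classified, .data$amplicon, name = "n_snps"),
    per_pool = count(calls, .data$pool, name = "n_calls"),
    venn = venn,
    partition = tibble(class = as.character(part$class), n = part$n,
                       total = total),
    effects = eff,
    densities = densities,
    params = params
  ), class = "study_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_summary <- function(x, ...) {
  cat("Pooled-amplicon SNP discovery summary\n")
  cat("  distinct SNPs:", x$partition$total[1],
      sprintf("(%d wild-type, %d putatively EMS-induced)\n",
              x$partition$n[x$partition$class == "wildtype"],
              x$partition$n[x$partition$class == "induced"]))
  cat("  per gene:", paste(sprintf("%s=%d", x$per_gene$amplicon,
                                   x$per_gene$n_snps), collapse = ", "),
      "\n")
  cat("  effects:", sprintf(
    "%d nonsynonymous (of which %d stop-gained), %d synonymous, %d intronic\n",
    x$effects$nonsynonymous, x$effects$stop_gained, x$effects$synonymous,
    x$effects$intronic))
  cat("  densities:\n")
  for (i in seq_len(nrow(x$densities)))
    cat(sprintf("    %.1f /Mb  [%s]\n", x$densities$per_mb[i],
                x$densities$convention[i]))
  invisible(x)
}

#' Tidy the study summary into one long count table
#'
#' @param x A `study_summary`.
#' @param ... Unused.
#' @return Tibble `section`, `item`, `n`.
#' @export
tidy.study_summary <- function(x, ...) {
  bind_rows(
    tibble(section = "per_gene", item = x$per_gene$amplicon,
           n = as.numeric(x$per_gene$n_snps)),
    tibble(section = "per_pool", item = x$per_pool$pool,
           n = as.numeric(x$per_pool$n_calls)),
    tibble(section = "venn", item = x$venn$region, n = as.numeric(x$venn$n)),
    tibble(section = "partition", item = x$partition$class,
           n = as.numeric(x$partition$n)),
    tibble(section = "effects",
           item = c("nonsynonymous", "stop_gained", "synonymous",
                    "intronic", "not_applicable"),
           n = as.numeric(c(x$effects$nonsynonymous, x$effects$stop_gained,
                            x$effects$synonymous, x$effects$intronic,
                            x$effects$not_applicable))),
    tibble(section = "density", item = x$densities$convention,
           n = x$densities$per_mb)
  )
}

#' One-row overview of the study summary
#'
#' @inheritParams tidy.study_summary
#' @return One-row tibble: totals and headline counts.
#' @export
glance.study_summary <- function(x, ...) {
  tibble(
    total_snps = x$partition$total[1],
    wildtype = x$partition$n[x$partition$class == "wildtype"],
    induced = x$partition$n[x$partition$class == "induced"],
    nonsynonymous = x$effects$nonsynonymous,
    stop_gained = x$effects$stop_gained,
    synonymous = x$effects$synonymous,
    intronic = x$effects$intronic
  )
}

#' Serialise a study summary to JSON
#'
#' @param x A `study_summary`.
#' @param path Output file.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path, seed = NULL) {
  payload <- list(
    tool = paste0("tillpool ", as.character(packageVersion("tillpool"))),
    seed = seed,
    params = x$params,
    per_gene = x$per_gene, per_pool = x$per_pool, venn = x$venn,
    partition = x$partition, effects = x$effects, densities = x$densities)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
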