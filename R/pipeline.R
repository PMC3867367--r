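#' Read a pipeline configuration
#'
#' A single declarative YAML file drives the pipeline: the seed, the
#' thresholds, the pool designs, and either a `simulate` block (the
#' synthetic generator supplies every input) or a `paths` block naming a
#' reference FASTA, a gene-model TSV and one count TSV per pool.
#'
#' @param path YAML file, or a list already in the same shape.
#' @return A validated list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$thresholds <- utils::modifyList(
    list(min_coverage = 400, min_frequency = 0.005),
    cfg$thresholds %||% list())
  if (is.null(cfg$pools))
    abort("Config must declare `pools`.", class = "tillpool_config_error")
  cfg$designs <- bind_rows(purrr::map(cfg$pools, function(p)
    pool_design(p$label, p$n_individuals,
                p$copies_per_individual %||% 4,
                p$max_siblings %||% 3,
                isTRUE(p$is_mutant))))
  structure(cfg, class = "pipeline_config")
}

sim_config_from_pipeline <- function(cfg) {
  sb <- cfg$simulate %||% list()
  args <- list(seed = cfg$seed, designs = cfg$designs)
  if (!is.null(sb$amplicons))
    args$amplicons <- bind_rows(purrr::map(sb$amplicons, as_tibble))
  if (!is.null(sb$mean_depth)) args$mean_depth <- unlist(sb$mean_depth)
  for (nm in c("exon_fraction", "wt_snp_per_bp", "wt_freq_lo", "wt_freq_hi",
               "residual_het", "ems_rate", "depth_sdlog", "error_rate"))
    if (!is.null(sb[[nm]])) args[[nm]] <- sb[[nm]]
  do.call(sim_config, args)
}

#' Run the whole discovery pipeline
#'
#' Chains every stage: obtain inputs (simulate, or load from the
#' configured paths), per-site statistics, SNP calling per pool,
#' cross-pool comparison, EMS classification, effect annotation and the
#' study summary. All stage outputs are written under `out_dir` with a
#' provenance header (tool version and seed), and the summary is
#' returned.
#'
#' @param config A YAML path, list, or `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return The `study_summary`, invisibly; stage outputs on disk.
#' @export
run_pipeline <- function(config, out_dir = "tillpool_out") {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  if (!is.null(cfg$simulate)) {
    study <- simulate_study(sim_config_from_pipeline(cfg))
    sequences <- study$sequences
    models <- study$models
    counts <- study$counts
    write_fasta(sequences, file.path(out_dir, "reference.fasta"))
    write_gene_models(models, file.path(out_dir, "gene_models.tsv"))
    write_truth(study$truth, file.path(out_dir, "truth.tsv"), seed)
    write_truth(study$pool_truth, file.path(out_dir, "pool_truth.tsv"),
                seed)
    for (lb in unique(counts$pool))
      write_counts(counts[counts$pool == lb, ],
                   file.path(out_dir, paste0("counts_", lb, ".tsv")), seed)
  } else {
    if (is.null(cfg$paths))
      abort("Config needs a `simulate` or a `paths` block.",
            class = "tillpool_config_error")
    sequences <- read_fasta(cfg$paths$reference)
    models <- read_gene_models(cfg$paths$gene_models, sequences)
    counts <- bind_rows(purrr::imap(cfg$paths$counts, function(p, lb)
      mutate(read_counts(p), pool = lb)))
  }

  stats <- site_stats(counts)
  readr::write_tsv(stats, file.path(out_dir, "site_stats.tsv"))

  calls <- counts %>%
    dplyr::group_split(.data$pool) %>%
    purrr::map(function(tb)
      call_snps(tb, sequences,
                min_coverage = cfg$thresholds$min_coverage,
                min_frequency = cfg$thresholds$min_frequency,
                pool = tb$pool[1])) %>%
    bind_rows()
  readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))

  membership <- compare_pools(calls)
  classified <- classify_ems(membership, cfg$designs) %>%
    partition_variants()
  readr::write_tsv(classified, file.path(out_dir, "ems_classification.tsv"))

  annotations <- annotate_snps(
    distinct(calls, .data$amplicon, .data$pos, .data$ref, .data$alt),
    models, sequences)
  readr::write_tsv(annotations, file.path(out_dir, "annotations.tsv"))

  write_vcf(calls %>% arrange(.data$amplicon, .data$pos, .data$alt),
            file.path(out_dir, "calls.vcf"), annotations = annotations,
            contig_lengths = nchar(sequences), seed = seed)

  summary <- build_summary(
    calls, classified, annotations, cfg$designs,
    amplicon_lengths = nchar(sequences),
    params = c(cfg$thresholds, seed = seed))
  write_summary_json(summary, file.path(out_dir, "summary.json"),
                     seed = seed)
  invisible(summary)
}
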