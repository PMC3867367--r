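tool_header <- function(seed = NULL) {
  paste0("# tillpool ", as.character(packageVersion("tillpool")),
         if (!is.null(seed)) paste0(" seed=", seed))
}

#' Read amplicon sequences from FASTA
#'
#' Sequences are upper-cased; duplicate ids, empty records and RNA
#' (`U`) are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs))
    abort("FASTA contains no records.", class = "tillpool_format_error")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    abort("Duplicate FASTA ids.", class = "tillpool_format_error")
  out <- toupper(setNames(as.character(seqs), ids))
  if (any(nchar(out) == 0L))
    abort("Empty FASTA record.", class = "tillpool_format_error")
  if (any(grepl("U", out, fixed = TRUE)))
    abort("RNA (U) not accepted.", class = "tillpool_format_error")
  out
}

#' Write amplicon sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read / write a per-site base-count table
#'
#' TSV with columns `amplicon`, `pos` (0-based, contiguous per
#' amplicon), `ref`, `A`, `C`, `G`, `T`, `N` and optionally `pool`.
#' Lines starting with `#` (the provenance header) are skipped on read.
#'
#' @param path File path.
#' @return A validated count tibble.
#' @export
read_counts <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  for (cl in intersect(c("pos", "A", "C", "G", "T", "N"), names(tb)))
    tb[[cl]] <- as.integer(tb[[cl]])
  if ("pool" %in% names(tb)) tb$pool <- as.character(tb$pool)
  validate_counts(tb)
  tb
}

#' @rdname read_counts
#' @param counts Count tibble.
#' @param seed Optional seed recorded in the header line.
#' @export
write_counts <- function(counts, path, seed = NULL) {
  validate_counts(counts)
  writeLines(tool_header(seed), path)
  readr::write_tsv(counts, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write gene models as BED-like TSV
#'
#' Columns `amplicon`, `exon_start`, `exon_end` (0-based half-open),
#' `strand`, `phase`.
#'
#' @param path File path.
#' @param reference Optional sequences for bounds checking.
#' @return Validated [gene_models()] tibble.
#' @export
read_gene_models <- function(path, reference = NULL) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          amplicon = "c", strand = "c",
                          .default = readr::col_integer()))
  gene_models(tb, reference)
}

#' @rdname read_gene_models
#' @param models Gene-model tibble.
#' @export
write_gene_models <- function(models, path) {
  writeLines(tool_header(), path)
  readr::write_tsv(models, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write SNP calls as minimal VCF 4.2
#'
#' One data line per call, `POS` 1-based (internal coordinates are
#' 0-based half-open; the conversion happens only here), INFO fields
#' `DP` (coverage), `AC` (alt count), `AF` (frequency), `POOL`, and
#' `EFF` when annotations are supplied.
#'
#' @param calls Sorted [call_snps()] output.
#' @param path Output file.
#' @param annotations Optional [annotate_snps()] output to merge as
#'   `EFF`.
#' @param contig_lengths Optional named amplicon lengths for `##contig`
#'   header lines.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, annotations = NULL,
                      contig_lengths = NULL, seed = NULL) {
  o <- order(calls$amplicon, calls$pos, calls$alt)
  if (!identical(o, seq_len(nrow(calls))) && nrow(calls) > 0L)
    abort("Calls must be sorted by (amplicon, pos, alt).",
          class = "tillpool_input_error")
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=tillpool-",
           as.character(packageVersion("tillpool")),
           if (!is.null(seed)) paste0(";seed=", seed)),
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt read count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele frequency\">",
    "##INFO=<ID=POOL,Number=1,Type=String,Description=\"Pool label\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Predicted effect\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  eff <- NULL
  if (!is.null(annotations)) {
    key <- paste(calls$amplicon, calls$pos, calls$ref, calls$alt)
    akey <- paste(annotations$amplicon, annotations$pos, annotations$ref,
                  annotations$alt)
    m <- match(key, akey)
    eff <- ifelse(is.na(m), NA_character_,
                  ifelse(annotations$region[m] == "intronic", "intronic",
                         annotations$effect[m]))
  }
  lines <- character(nrow(calls))
  if (nrow(calls)) {
    info <- sprintf("DP=%d;AC=%d;AF=%s;POOL=%s",
                    calls$coverage, calls$alt_count,
                    format(calls$frequency, digits = 6, scientific = FALSE,
                           trim = TRUE),
                    calls$pool)
    if (!is.null(eff))
      info <- ifelse(is.na(eff), info, paste0(info, ";EFF=", eff))
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                     calls$amplicon, calls$pos + 1L, calls$ref, calls$alt,
                     info)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write the simulator's planted-variant ledger
#'
#' @param truth The `truth` or `pool_truth` tibble of a
#'   [simulate_study()] result.
#' @param path Output file.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NULL) {
  writeLines(tool_header(seed), path)
  readr::write_tsv(truth, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
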