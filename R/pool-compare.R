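#' Cross-pool membership of SNP calls
#'
#' Collates the calls of several pools into one row per distinct SNP
#' (identity is the full (amplicon, pos, ref, alt) key — different
#' alternate alleles at one site are different mutations), recording which
#' pools each SNP was called in and its frequency in each.
#'
#' @param calls A tibble of [call_snps()] output rows from all pools (the
#'   `pool` column distinguishes them), or a named list of per-pool call
#'   tibbles.
#' @return Membership tibble: `amplicon`, `pos`, `ref`, `alt`, `pools`
#'   (member labels joined with `"&"`), `n_pools`, and one `freq_<label>`
#'   column per pool (`NA` where absent). Pool labels seen in the input
#'   are kept in `attr(, "pool_labels")`.
#' @export
compare_pools <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- purrr::imap(calls, function(x, nm) {
      if (!nrow(x)) return(x)
      mutate(x, pool = nm)
    })
    calls <- bind_rows(calls)
  }
  if (!nrow(calls))
    abort("No calls to compare.", class = "tillpool_input_error")
  if (anyNA(calls$pool))
    abort("Every call needs a pool label.", class = "tillpool_input_error")
  dup <- calls %>%
    count(.data$pool, .data$amplicon, .data$pos, .data$ref, .data$alt) %>%
    filter(.data$n > 1L)
  if (nrow(dup))
    abort("Duplicate SNP keys within one pool.",
          class = "tillpool_input_error")
  labels <- sort(unique(calls$pool))
  wide <- calls %>%
    select(all_of(c("amplicon", "pos", "ref", "alt", "pool", "frequency"))) %>%
    tidyr::pivot_wider(names_from = "pool", values_from = "frequency",
                       names_prefix = "freq_")
  freq_cols <- paste0("freq_", labels)
  for (cl in setdiff(freq_cols, names(wide))) wide[[cl]] <- NA_real_
  present <- !is.na(as.matrix(wide[, freq_cols]))
  wide$pools <- apply(present, 1L, function(p)
    paste(labels[p], collapse = "&"))
  wide$n_pools <- rowSums(present)
  out <- wide %>%
    select(all_of(c("amplicon", "pos", "ref", "alt", "pools", "n_pools",
                    freq_cols))) %>%
    arrange(.data$amplicon, .data$pos, .data$alt)
  attr(out, "pool_labels") <- labels
  out
}

#' Sizes of every region of the pool Venn diagram
#'
#' Counts the distinct SNPs falling in each region of the k-set Venn
#' diagram over the pools (7 regions for the usual three pools). Region
#' sizes are non-negative and sum to the number of distinct SNPs.
#'
#' @param membership Output of [compare_pools()].
#' @param labels Pool labels defining the diagram; defaults to the labels
#'   seen by [compare_pools()].
#' @return Tibble `region` (labels joined with `"&"`), `n`, ordered by
#'   region size (singletons first).
#' @export
venn_counts <- function(membership, labels = attr(membership, "pool_labels")) {
  if (is.null(labels))
    abort("Pool labels are needed (pass `labels`).",
          class = "tillpool_input_error")
  k <- length(labels)
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, function(x) paste(x, collapse = "&"))),
    use.names = FALSE)
  found <- table(membership$pools)
  tibble(region = subsets,
         n = as.integer(ifelse(subsets %in% names(found),
                               found[subsets], 0L)))
}

ems_transition <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Classify SNPs as putatively EMS-induced
#'
#' A SNP is a putative EMS-induced mutation when all three criteria hold:
#' it was called in no control pool; it is the EMS transition signature on
#' the reference strand as written (`G->A` or `C->T`, the two
#' strand-complementary renderings of O6-ethylguanine mispairing); and in
#' every mutant pool where it was called, its frequency lies inside that
#' pool's predicted window (inclusive at both ends; see
#' [ems_frequency_window()]). Non-passing SNPs carry machine-readable
#' `reasons`.
#'
#' @param membership Output of [compare_pools()].
#' @param designs `pool_design` tibble covering every pool label.
#' @param min_individuals,copies_per_carrier Window parameters passed to
#'   [ems_frequency_window()] (the upper carrier count is each design's
#'   `max_siblings`).
#' @param unique_to Optional single pool label: additionally require the
#'   SNP to be called in that pool only (e.g. `"M109"` for the strict
#'   discovery-pool reading).
#' @return The membership tibble with added columns `mutant_only`,
#'   `is_transition`, `in_window`, `passes`, `reasons`.
#' @export
classify_ems <- function(membership, designs, min_individuals = 1,
                         copies_per_carrier = 2, unique_to = NULL) {
  labels <- attr(membership, "pool_labels")
  if (is.null(labels))
    labels <- sub("^freq_", "", grep("^freq_", names(membership),
                                     value = TRUE))
  unknown <- setdiff(labels, designs$label)
  if (length(unknown))
    abort(paste0("Unknown pool label(s): ", paste(unknown, collapse = ", ")),
          class = "tillpool_input_error")
  designs_used <- designs[designs$label %in% labels, , drop = FALSE]
  control_labels <- designs_used$label[!designs_used$is_mutant]
  mutant_labels <- designs_used$label[designs_used$is_mutant]
  windows <- purrr::map(setNames(mutant_labels, mutant_labels), function(lb) {
    d <- pick_design(designs, lb)
    ems_frequency_window(d, min_individuals = min_individuals,
                         max_individuals = d$max_siblings,
                         copies_per_carrier = copies_per_carrier)
  })

  member_sets <- strsplit(membership$pools, "&", fixed = TRUE)
  mutant_only <- map_lgl(member_sets, function(p)
    length(p) > 0 && !any(p %in% control_labels))
  if (!is.null(unique_to)) {
    mutant_only <- mutant_only & map_lgl(member_sets, identical, y = unique_to)
  }
  is_transition <- ems_transition(membership$ref, membership$alt)
  in_window <- map_lgl(seq_along(member_sets), function(i) {
    mpools <- intersect(member_sets[[i]], mutant_labels)
    if (!length(mpools)) return(FALSE)
    all(map_lgl(mpools, function(lb) {
      f <- membership[[paste0("freq_", lb)]][i]
      w <- windows[[lb]]
      f >= w$lo && f <= w$hi
    }))
  })
  passes <- mutant_only & is_transition & in_window
  reasons <- pmap(list(mutant_only, is_transition, in_window),
                  function(m, t, w) {
                    r <- character()
                    if (!m) r <- c(r, "control-shared")
                    if (!t) r <- c(r, "transition-signature")
                    if (!w) r <- c(r, "frequency-window")
                    r
                  })
  out <- membership %>%
    mutate(mutant_only = mutant_only, is_transition = is_transition,
           in_window = in_window, passes = passes,
           reasons = map_chr(reasons, paste, collapse = ";"))
  attr(out, "pool_labels") <- labels
  attr(out, "windows") <- bind_rows(windows)
  out
}

#' Partition SNPs into wild-type and putatively induced sets
#'
#' Splits the classified SNPs into the putatively EMS-induced set (those
#' passing [classify_ems()]) and the wild-type (natural variation)
#' remainder. The two sets are disjoint and their union is every distinct
#' SNP.
#'
#' @param ems Output of [classify_ems()].
#' @return The input with an added factor column
#'   `class` (`"induced"` / `"wildtype"`).
#' @export
partition_variants <- function(ems) {
  if (!"passes" %in% names(ems))
    abort("Run classify_ems() first.", class = "tillpool_input_error")
  mutate(ems, class = factor(ifelse(.data$passes, "induced", "wildtype"),
                             levels = c("wildtype", "induced")))
}
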