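#' Configuration for the synthetic pooled-amplicon study
#'
#' Bundles every knob of the generator. The defaults reproduce the
#' structure of a deep-pooled tetraploid TILLING screen: four amplicons
#' totalling 16.4 kb, pools of 109 control, 109 mutant and 754 mutant
#' individuals (4 allele copies each, up to 3 siblings per M1 family),
#' mean depths of 27118x / 32289x / 10171x with heavy-tailed per-site
#' non-uniformity, and a 0.1% per-base sequencing error spread uniformly
#' over the three wrong bases.
#'
#' @param seed Integer seed; the whole simulation is a pure function of
#'   the config, so a fixed seed gives identical outputs.
#' @param amplicons Tibble `id`, `length` (bp). Default four amplicons
#'   shaped like the usual shattering/starch targets (7800, 4800, 3400,
#'   400 bp).
#' @param exon_fraction Approximate coding fraction of each amplicon
#'   (default 0.38, i.e. roughly 60% intronic sequence).
#' @param wt_snp_per_bp Probability that an amplicon site segregates in
#'   the base population (default 0.0143, about 14 segregating sites per
#'   kb of amplicon).
#' @param wt_freq_lo,wt_freq_hi Range of the uniform population
#'   allele-frequency model for wild-type variants (default 0.02-0.5).
#' @param residual_het Residual heterozygosity of the predominantly
#'   selfing base population (default 0.05: an individual's second allele
#'   copy within the variant's subgenome is redrawn with this
#'   probability instead of duplicating the first).
#' @param ems_rate Per-G/C-site probability that an M1 family founder
#'   carries an induced transition (default 1.7e-5), homozygous within
#'   one random subgenome and shared by all pooled siblings.
#' @param designs `pool_design` tibble (default [default_pool_designs()]).
#' @param mean_depth Named mean depths per pool label (defaults
#'   C109 = 27118, M109 = 32289, M754 = 10171).
#' @param depth_sdlog Log-sd of the lognormal per-site coverage
#'   multiplier (mean 1; default 0.5). `0` gives flat coverage.
#' @param error_rate Per-base miscall probability (default 0.001).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       amplicons = tibble(
                         id = c("sh4", "qsh1", "waxy", "isa"),
                         length = c(7800L, 4800L, 3400L, 400L)),
                       exon_fraction = 0.38,
                       wt_snp_per_bp = 0.0143,
                       wt_freq_lo = 0.02, wt_freq_hi = 0.5,
                       residual_het = 0.05,
                       ems_rate = 1.7e-5,
                       designs = default_pool_designs(),
                       mean_depth = c(C109 = 27118, M109 = 32289,
                                      M754 = 10171),
                       depth_sdlog = 0.5,
                       error_rate = 0.001) {
  stopifnot(all(c("id", "length") %in% names(amplicons)),
            all(amplicons$length >= 1L),
            !anyDuplicated(amplicons$id))
  for (p in c(wt_snp_per_bp, ems_rate, error_rate, residual_het))
    if (p < 0 || p > 1)
      abort("Rates must lie in [0, 1].", class = "tillpool_config_error")
  if (!all(designs$label %in% names(mean_depth)))
    abort("`mean_depth` must name every pool label.",
          class = "tillpool_config_error")
  structure(list(
    seed = as.integer(seed), amplicons = amplicons,
    exon_fraction = exon_fraction, wt_snp_per_bp = wt_snp_per_bp,
    wt_freq_lo = wt_freq_lo, wt_freq_hi = wt_freq_hi,
    residual_het = residual_het, ems_rate = ems_rate,
    designs = designs, mean_depth = mean_depth,
    depth_sdlog = depth_sdlog, error_rate = error_rate
  ), class = "sim_config")
}

#' Simulate reference amplicons and gene models
#'
#' Draws uniform-random A/C/G/T sequences of the configured lengths and
#' lays an exon/intron structure over each: exons of 80-300 bp separated
#' by introns sized to hit the configured coding fraction, with a random
#' strand and phase per amplicon.
#'
#' @param config A [sim_config()].
#' @return List: `sequences` (named character) and `models`
#'   ([gene_models()] tibble).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  sequences <- setNames(
    map_chr(config$amplicons$length, function(L)
      paste(sample(BASES, L, replace = TRUE), collapse = "")),
    config$amplicons$id)
  models <- purrr::map2(config$amplicons$id, config$amplicons$length,
                        function(id, L) random_gene_model(id, L, config))
  models <- bind_rows(models)
  list(sequences = sequences, models = gene_models(models, sequences))
}

random_gene_model <- function(id, L, config) {
  strand <- sample(c("+", "-"), 1L)
  phase <- sample(0:2, 1L)
  exon_mean <- 180
  gap_mean <- exon_mean * (1 - config$exon_fraction) / config$exon_fraction
  starts <- integer(); ends <- integer()
  pos <- round(runif(1, 0, gap_mean / 2))
  while (pos < L - 10L) {
    len <- round(runif(1, 80, 300))
    e <- min(pos + len, L)
    starts <- c(starts, pos); ends <- c(ends, e)
    pos <- e + round(runif(1, 0.5 * gap_mean, 1.5 * gap_mean))
  }
  if (!length(starts)) { starts <- 0L; ends <- min(L, 120L) }
  tibble(amplicon = id, exon_start = as.integer(starts),
         exon_end = as.integer(ends), strand = strand, phase = phase)
}

#' Simulate the base population and its wild-type variation
#'
#' Creates the individuals of every configured pool (mutant pools are
#' organised into M1 families contributing 1 to `max_siblings` M2
#' siblings each) and plants segregating wild-type variants: each
#' amplicon site becomes a variant with probability `wt_snp_per_bp`,
#' receives a random non-reference allele on a random subgenome and a
#' population allele frequency from the configured uniform model, and
#' each individual's two allele copies within that subgenome are drawn
#' nearly identically (selfing) with residual heterozygosity.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return List: `individuals` (tibble `id`, `pool`, `family`,
#'   `sibling`), `variants` (wild-type truth rows) and `copies`
#'   (variants x individuals integer matrix of allele copies carried).
#' @export
simulate_population <- function(config, reference) {
  set.seed(config$seed + 1L)
  individuals <- assemble_individuals(config$designs)
  seqs <- reference$sequences

  rows <- list(); copies <- list()
  for (amp in names(seqs)) {
    L <- nchar(seqs[[amp]])
    is_var <- which(runif(L) < config$wt_snp_per_bp)
    if (!length(is_var)) next
    refb <- strsplit(seqs[[amp]], "")[[1]][is_var]
    alt <- map_chr(refb, function(r) sample(setdiff(BASES, r), 1L))
    f <- runif(length(is_var), config$wt_freq_lo, config$wt_freq_hi)
    rows[[amp]] <- tibble(
      amplicon = amp, pos = is_var - 1L, ref = refb, alt = alt,
      origin = "wildtype", subgenome = sample(1:2, length(is_var), TRUE),
      pop_freq = f, family = NA_integer_)
  }
  variants <- bind_rows(c(list(empty_truth()), rows))
  n_ind <- nrow(individuals)
  cp <- matrix(0L, nrow(variants), n_ind)
  for (v in seq_len(nrow(variants))) {
    a1 <- rbinom(n_ind, 1L, variants$pop_freq[v])
    redraw <- runif(n_ind) < config$residual_het
    a2 <- ifelse(redraw, rbinom(n_ind, 1L, variants$pop_freq[v]), a1)
    cp[v, ] <- a1 + a2
  }
  list(individuals = individuals, variants = variants, copies = cp)
}

assemble_individuals <- function(designs) {
  out <- list(); fam_id <- 0L
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    if (!d$is_mutant) {
      out[[d$label]] <- tibble(pool = d$label,
                               family = NA_integer_,
                               sibling = 1L,
                               n = seq_len(d$n_individuals))
    } else {
      fams <- integer(); sibs <- integer()
      while (length(fams) < d$n_individuals) {
        fam_id <- fam_id + 1L
        k <- sample(seq_len(d$max_siblings), 1L)
        k <- min(k, d$n_individuals - length(fams))
        fams <- c(fams, rep(fam_id, k)); sibs <- c(sibs, seq_len(k))
      }
      out[[d$label]] <- tibble(pool = d$label, family = fams,
                               sibling = sibs,
                               n = seq_len(d$n_individuals))
    }
  }
  ind <- bind_rows(out)
  ind$id <- seq_len(nrow(ind))
  ind[, c("id", "pool", "family", "sibling")]
}

empty_truth <- function() {
  tibble(amplicon = character(), pos = integer(), ref = character(),
         alt = character(), origin = character(), subgenome = integer(),
         pop_freq = double(), family = integer())
}

#' Plant EMS-induced mutations in the mutant families
#'
#' For each M1 family founder, every G or C reference site mutates with
#' probability `ems_rate` to the transition allele (G->A or C->T on the
#' reference strand as written), homozygous within one randomly chosen
#' subgenome; every pooled sibling of the family inherits the founder's
#' mutations, so a mutation is carried by 1 to `max_siblings` pooled
#' individuals at 2 allele copies each.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param population Output of [simulate_population()].
#' @return The population list with EMS rows appended to `variants` and
#'   `copies`.
#' @export
simulate_ems <- function(config, reference, population) {
  set.seed(config$seed + 2L)
  ind <- population$individuals
  mutant_pools <- config$designs$label[config$designs$is_mutant]
  fam_tbl <- ind %>%
    filter(.data$pool %in% mutant_pools) %>%
    group_by(.data$family) %>%
    summarise(members = list(.data$id))
  seqs <- reference$sequences
  gc_sites <- purrr::map(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    tibble(pos = which(b %in% c("G", "C")) - 1L,
           ref = b[b %in% c("G", "C")])
  })

  rows <- list(); carrier <- list()
  for (fi in seq_len(nrow(fam_tbl))) {
    for (amp in names(seqs)) {
      gc <- gc_sites[[amp]]
      hit <- which(runif(nrow(gc)) < config$ems_rate)
      for (h in hit) {
        rows[[length(rows) + 1L]] <- tibble(
          amplicon = amp, pos = gc$pos[h], ref = gc$ref[h],
          alt = ifelse(gc$ref[h] == "G", "A", "T"),
          origin = "ems", subgenome = sample(1:2, 1L),
          pop_freq = NA_real_, family = fam_tbl$family[fi])
        carrier[[length(carrier) + 1L]] <- fam_tbl$members[[fi]]
      }
    }
  }
  if (length(rows)) {
    ems_variants <- bind_rows(rows)
    cp <- matrix(0L, nrow(ems_variants), nrow(ind))
    for (v in seq_along(carrier)) cp[v, carrier[[v]]] <- 2L
    population$variants <- bind_rows(population$variants, ems_variants)
    population$copies <- rbind(population$copies, cp)
  }
  population
}

## Vectorised multinomial via successive conditional binomials.
rmultinom_rows <- function(size, prob) {
  n <- length(size)
  out <- matrix(0L, n, ncol(prob))
  remaining <- size
  ptail <- rep(1, n)
  for (j in seq_len(ncol(prob) - 1L)) {
    pj <- prob[, j] / ptail
    pj[ptail <= 0] <- 0
    pj <- pmin(pmax(pj, 0), 1)
    out[, j] <- rbinom(n, remaining, pj)
    remaining <- remaining - out[, j]
    ptail <- ptail - prob[, j]
  }
  out[, ncol(prob)] <- remaining
  out
}

#' Simulate per-pool base-count tables
#'
#' For each pool, each site's true allele mixture is the copy-weighted
#' average over the pooled individuals; read depth is the pool's mean
#' depth times a lognormal per-site multiplier (mean 1); base counts are
#' multinomial over the mixture after pushing each base through the
#' uniform error channel (a drawn base is miscalled with probability
#' `error_rate`, uniformly to the other three bases).
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param population Output of [simulate_ems()] (or
#'   [simulate_population()] for an error-only run).
#' @return List: `counts` (one count tibble with a `pool` column) and
#'   `pool_truth` (per variant per pool: carrier copies, carrier count
#'   and exact expected frequency).
#' @export
simulate_counts <- function(config, reference, population) {
  set.seed(config$seed + 3L)
  seqs <- reference$sequences
  ind <- population$individuals
  variants <- population$variants
  e <- config$error_rate

  counts <- list(); truths <- list()
  for (i in seq_len(nrow(config$designs))) {
    d <- config$designs[i, ]
    members <- ind$id[ind$pool == d$label]
    total_copies <- d$n_individuals * d$copies_per_individual
    pool_copies <- if (nrow(variants))
      as.integer(rowSums(population$copies[, members, drop = FALSE]))
      else integer()
    if (nrow(variants)) {
      truths[[d$label]] <- variants %>%
        select(all_of(c("amplicon", "pos", "ref", "alt", "origin"))) %>%
        mutate(pool = d$label, carrier_copies = pool_copies,
               n_carriers = if (nrow(variants))
                 as.integer(rowSums(population$copies[, members,
                                                      drop = FALSE] > 0L))
                 else integer(),
               expected_freq = pool_copies / total_copies)
    }
    for (amp in names(seqs)) {
      L <- nchar(seqs[[amp]])
      refb <- strsplit(seqs[[amp]], "")[[1]]
      prob <- matrix(0, L, 4L, dimnames = list(NULL, BASES))
      prob[cbind(seq_len(L), match(refb, BASES))] <- 1
      vs <- which(variants$amplicon == amp & pool_copies > 0L)
      for (v in vs) {
        f <- pool_copies[v] / total_copies
        p <- variants$pos[v] + 1L
        prob[p, variants$ref[v]] <- prob[p, variants$ref[v]] - f
        prob[p, variants$alt[v]] <- prob[p, variants$alt[v]] + f
      }
      ## uniform error channel
      q <- prob * (1 - e) + (1 - prob) * (e / 3)
      mult <- if (config$depth_sdlog > 0)
        rlnorm(L, -config$depth_sdlog^2 / 2, config$depth_sdlog)
        else rep(1, L)
      depth <- pmax(as.integer(round(config$mean_depth[[d$label]] * mult)),
                    1L)
      cm <- rmultinom_rows(depth, q)
      counts[[paste(d$label, amp)]] <- tibble(
        amplicon = amp, pos = seq_len(L) - 1L, ref = refb,
        A = cm[, 1], C = cm[, 2], G = cm[, 3], T = cm[, 4],
        N = 0L, pool = d$label)
    }
  }
  list(counts = bind_rows(counts), pool_truth = bind_rows(truths))
}

#' Run the full synthetic study
#'
#' Chains [simulate_reference()], [simulate_population()],
#' [simulate_ems()] and [simulate_counts()] under the config's seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: `config`, `sequences`, `models`,
#'   `designs`, `individuals`, `truth` (planted-variant ledger),
#'   `pool_truth` and `counts`.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(seed = 7))
#' dplyr::count(study$truth, origin)
#' }
#' @export
simulate_study <- function(config = sim_config()) {
  reference <- simulate_reference(config)
  population <- simulate_population(config, reference)
  population <- simulate_ems(config, reference, population)
  observed <- simulate_counts(config, reference, population)
  structure(list(
    config = config, sequences = reference$sequences,
    models = reference$models, designs = config$designs,
    individuals = population$individuals,
    truth = population$variants,
    pool_truth = observed$pool_truth,
    counts = observed$counts
  ), class = "sim_study")
}
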