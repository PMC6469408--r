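# Synthetic-data generators.  Each generator reproduces the statistical
# structure the downstream analysis assumes (group means on the delta-Cq
# scale, planted substitution clusters, overdispersed offspring counts) so
# that every pipeline stage is testable without external data.  All
# generators are deterministic given the scenario seed and restore the
# caller's RNG state on exit.

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  expr
}

#' Expression scenario for the Cq generator
#'
#' Defines per-gene, per-class target delta-Cq means and the replication
#' structure of a qRT-PCR assay with two reference genes.
#'
#' @param mean_dcq data.frame with columns `gene`, `sample_class`,
#'   `mean_dcq`: the target delta-Cq mean under the first reference gene.
#'   The second reference gene's mean is `mean_dcq + reference_offset` for
#'   every pair, so both references cover every (gene, class).
#' @param replicate_sd Gaussian noise SD added independently to each Cq
#'   value (cycles, > 0); the resulting delta-Cq SD is
#'   `sqrt(2) * replicate_sd`.
#' @param n_replicates biological replicates per (gene, class, reference),
#'   at least 2 (assays use at least three).
#' @param reference_offset additive delta-Cq shift of the second reference
#'   gene (cycles); positive means relative expression reads uniformly
#'   higher under it.
#' @param reference_genes length-2 character vector of reference labels.
#' @param baseline_cq mean Cq of the reference genes (cycles); affects only
#'   raw Cq values, never delta-Cq.
#' @param seed integer seed.
#' @return object of class `"expression_scenario"`.
#' @export
expression_scenario <- function(mean_dcq, replicate_sd = 0.3,
                                n_replicates = 5L, reference_offset = 1,
                                reference_genes = c("RpL32", "RpS18"),
                                baseline_cq = 20, seed = 1L) {
  stopifnot(is.data.frame(mean_dcq),
            all(c("gene", "sample_class", "mean_dcq") %in% names(mean_dcq)),
            replicate_sd > 0, n_replicates >= 2L,
            length(reference_genes) == 2L)
  if (anyDuplicated(mean_dcq[, c("gene", "sample_class")]))
    stop("duplicate (gene, sample_class) entries in mean_dcq")
  structure(list(mean_dcq = mean_dcq, replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 reference_offset = reference_offset,
                 reference_genes = reference_genes,
                 baseline_cq = baseline_cq, seed = as.integer(seed)),
            class = "expression_scenario")
}

#' Generate a raw Cq table from an expression scenario
#'
#' For each (gene, sample class, reference gene, replicate) a reference Cq
#' and a target Cq are drawn with independent Gaussian noise
#' (`sd = replicate_sd` on each) such that the expectation of
#' `cq_reference - cq_target` equals the scenario's delta-Cq mean for that
#' combination.
#'
#' @param scenario an [expression_scenario()].
#' @return data.frame of Cq records (columns `gene`, `sample_class`,
#'   `replicate`, `reference_gene`, `cq_reference`, `cq_target`), suitable
#'   for [compute_delta_cq()].
#' @export
generate_cq_table <- function(scenario) {
  stopifnot(inherits(scenario, "expression_scenario"))
  m <- scenario$mean_dcq
  refs <- scenario$reference_genes
  grid <- expand.grid(row = seq_len(nrow(m)),
                      reference_gene = refs,
                      replicate = seq_len(scenario$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu_dcq <- m$mean_dcq[grid$row] +
    ifelse(grid$reference_gene == refs[2L], scenario$reference_offset, 0)
  with_seed(scenario$seed, {
    cq_ref <- scenario$baseline_cq +
      stats::rnorm(nrow(grid), 0, scenario$replicate_sd)
    cq_tgt <- scenario$baseline_cq - mu_dcq +
      stats::rnorm(nrow(grid), 0, scenario$replicate_sd)
  })
  out <- data.frame(gene = m$gene[grid$row],
                    sample_class = m$sample_class[grid$row],
                    replicate = grid$replicate,
                    reference_gene = grid$reference_gene,
                    cq_reference = cq_ref,
                    cq_target = cq_tgt)
  out[order(out$gene, out$sample_class, out$reference_gene, out$replicate), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Sequence scenario for the aligned-pair generator
#'
#' @param fragment_start,fragment_end TSS-relative fragment bounds
#'   (`fragment_start < 0 < fragment_end`, no position 0).
#' @param background_rate per-site probability of a background fixed
#'   difference.
#' @param cluster_interval optional length-2 TSS interval inside the
#'   fragment where extra events are planted.
#' @param cluster_extra_events number of extra events planted uniformly
#'   (without replacement) inside `cluster_interval`.
#' @param indel_fraction fraction of planted differences generated as
#'   single-column deletions in species b rather than SNVs.
#' @param shared_polymorphism_rate probability that a planted difference
#'   is also segregating within species a (its species-b allele then
#'   appears in the generated strain reads).
#' @param n_strain_reads strain reads generated per difference site.
#' @param read_length strain read length (bases).
#' @param seed integer seed.
#' @return object of class `"sequence_scenario"`.
#' @export
sequence_scenario <- function(fragment_start = -1123L, fragment_end = 518L,
                              background_rate = 0.005,
                              cluster_interval = NULL,
                              cluster_extra_events = 0L,
                              indel_fraction = 0,
                              shared_polymorphism_rate = 0,
                              n_strain_reads = 3L, read_length = 100L,
                              seed = 1L) {
  stopifnot(fragment_start < 0L, fragment_end > 0L,
            background_rate >= 0, background_rate <= 1,
            shared_polymorphism_rate >= 0, shared_polymorphism_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            cluster_extra_events >= 0L)
  if (!is.null(cluster_interval)) {
    stopifnot(length(cluster_interval) == 2L)
    if (cluster_interval[1L] < fragment_start ||
        cluster_interval[2L] > fragment_end)
      stop("cluster_interval must lie within the fragment")
    w <- tss_to_index(cluster_interval[2L], fragment_start, fragment_end) -
      tss_to_index(cluster_interval[1L], fragment_start, fragment_end) + 1L
    if (cluster_extra_events > w)
      stop("cluster_extra_events exceeds the cluster interval length")
  } else if (cluster_extra_events > 0L) {
    stop("cluster_extra_events requires a cluster_interval")
  }
  structure(list(fragment_start = as.integer(fragment_start),
                 fragment_end = as.integer(fragment_end),
                 background_rate = background_rate,
                 cluster_interval = cluster_interval,
                 cluster_extra_events = as.integer(cluster_extra_events),
                 indel_fraction = indel_fraction,
                 shared_polymorphism_rate = shared_polymorphism_rate,
                 n_strain_reads = as.integer(n_strain_reads),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sequence_scenario")
}

#' Generate an aligned interspecies sequence pair with planted differences
#'
#' Species a is a uniform random sequence; species b copies it and
#' receives differences at Bernoulli(`background_rate`) sites plus
#' `cluster_extra_events` sites drawn uniformly without replacement inside
#' the cluster interval.  Differences are SNVs, or single-column deletions
#' in species b with probability `indel_fraction`.  A fraction
#' `shared_polymorphism_rate` of difference sites is marked as shared
#' polymorphism: strain reads covering those sites carry the species-b
#' allele.  The true planted event list is returned for recovery testing.
#'
#' @param scenario a [sequence_scenario()].
#' @param gene gene label for the fragment.
#' @return list with `fragment` (a [sequenced_fragment()]), `truth`
#'   (data.frame `tss_position`, `index`, `kind`, `allele_a`, `allele_b`,
#'   `shared`), `evidence` (per-site allele table covering read evidence)
#'   and `reads` (character vector of strain reads).
#' @export
generate_sequence_pair <- function(scenario, gene = "synthetic") {
  stopifnot(inherits(scenario, "sequence_scenario"))
  a0 <- scenario$fragment_start; b0 <- scenario$fragment_end
  N <- tss_span_length(a0, b0)
  with_seed(scenario$seed, {
    ref <- sample(c("A", "C", "G", "T"), N, replace = TRUE)
    bg <- which(stats::runif(N) < scenario$background_rate)
    extra <- integer()
    if (scenario$cluster_extra_events > 0L) {
      lo <- tss_to_index(scenario$cluster_interval[1L], a0, b0)
      hi <- tss_to_index(scenario$cluster_interval[2L], a0, b0)
      pool <- setdiff(lo:hi, bg)
      if (length(pool) < scenario$cluster_extra_events)
        stop("cluster interval saturated by background events")
      extra <- pool[sample.int(length(pool), scenario$cluster_extra_events)]
    }
    sites <- sort(unique(c(bg, extra)))
    kinds <- if (length(sites))
      ifelse(stats::runif(length(sites)) < scenario$indel_fraction,
             "deletion", "SNV") else character()
    # adjacent single-column deletions would merge into one alignment gap;
    # keep planted events 1:1 with called events by demoting the second
    if (length(sites) > 1L) {
      for (k in 2L:length(sites)) {
        if (kinds[k] == "deletion" && kinds[k - 1L] == "deletion" &&
            sites[k] == sites[k - 1L] + 1L)
          kinds[k] <- "SNV"
      }
    }
    alt <- vapply(seq_along(sites), function(k) {
      if (kinds[k] == "deletion") return("-")
      sample(setdiff(c("A", "C", "G", "T"), ref[sites[k]]), 1L)
    }, character(1L))
    shared <- if (length(sites))
      stats::runif(length(sites)) < scenario$shared_polymorphism_rate
    else logical()
    alt_row <- ref
    alt_row[sites] <- alt
    reads <- character()
    if (length(sites) && scenario$n_strain_reads > 0L) {
      L <- min(scenario$read_length, N)
      for (k in seq_along(sites)) {
        for (r in seq_len(scenario$n_strain_reads)) {
          starts <- max(1L, sites[k] - L + 1L):min(sites[k], N - L + 1L)
          start <- starts[sample.int(length(starts), 1L)]
          rd <- ref[start:(start + L - 1L)]
          if (shared[k]) {
            off <- sites[k] - start + 1L
            if (alt[k] == "-") rd <- rd[-off] else rd[off] <- alt[k]
          }
          reads <- c(reads, paste(rd, collapse = ""))
        }
      }
    }
  })
  fragment <- sequenced_fragment(gene, a0, b0,
                                 paste(ref, collapse = ""),
                                 paste(alt_row, collapse = ""))
  truth <- data.frame(
    tss_position = if (length(sites)) index_to_tss(sites, a0, b0) else integer(),
    index = sites,
    kind = kinds,
    allele_a = ref[sites],
    allele_b = alt,
    shared = shared)
  evidence <- if (length(sites)) {
    data.frame(tss_position = truth$tss_position,
               alleles = ifelse(shared,
                                paste(ref[sites], alt, sep = ","),
                                ref[sites]))
  } else {
    data.frame(tss_position = integer(), alleles = character())
  }
  list(fragment = fragment, truth = truth, evidence = evidence,
       reads = reads)
}

#' Fecundity scenario and count generator
#'
#' Offspring counts per replicate vial are negative-binomial with the
#' class mean and a quadratic overdispersion parameter
#' (`variance = mean + dispersion * mean^2`); `dispersion = 0` gives
#' Poisson counts, and a zero mean gives all-zero counts (a sterile
#' class).
#'
#' @param mean_offspring named numeric vector: expected offspring count
#'   per male class (>= 0).
#' @param n_vials replicate vials per class (>= 2; assays use six).
#' @param dispersion overdispersion parameter (>= 0).
#' @param seed integer seed.
#' @return object of class `"fecundity_scenario"`.
#' @export
fecundity_scenario <- function(mean_offspring, n_vials = 6L,
                               dispersion = 0.02, seed = 1L) {
  stopifnot(is.numeric(mean_offspring), all(mean_offspring >= 0),
            !is.null(names(mean_offspring)), n_vials >= 2L, dispersion >= 0)
  structure(list(mean_offspring = mean_offspring,
                 n_vials = as.integer(n_vials),
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "fecundity_scenario")
}

#' @rdname fecundity_scenario
#' @param scenario a `fecundity_scenario`.
#' @return `generate_fecundity()` returns a data.frame with columns
#'   `class`, `vial`, `offspring`.
#' @export
generate_fecundity <- function(scenario) {
  stopifnot(inherits(scenario, "fecundity_scenario"))
  mu <- scenario$mean_offspring
  nv <- scenario$n_vials
  with_seed(scenario$seed, {
    counts <- unlist(lapply(mu, function(m) {
      if (m == 0) return(rep(0L, nv))
      if (scenario$dispersion == 0) return(stats::rpois(nv, m))
      stats::rnbinom(nv, size = 1 / scenario$dispersion, mu = m)
    }))
  })
  data.frame(class = rep(names(mu), each = nv),
             vial = rep(seq_len(nv), times = length(mu)),
             offspring = as.integer(counts))
}
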