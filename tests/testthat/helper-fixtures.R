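# Shared fixtures, built in code.

# Expression scenario over the bundled per-gene class means, including a
# sterile-F1 class: for excluded genes the F1 mean is the mean of their
# misregulated fertile classes (those classes reach sterile-like levels);
# for retained genes the F1 mean is placed 2 cycles below the gene's lowest
# class mean, since the panel's genes are misregulated uniquely in sterile
# F1 males.
reference_scenario_means <- function() {
  means <- dps_expression()$means
  flags <- dps_comparison_flags()
  genes <- unique(means$gene)
  f1 <- vapply(genes, function(g) {
    mis <- flags$sample_class[flags$gene == g & flags$diff_from_both_parents]
    gm <- means$mean_dcq[means$gene == g]
    if (length(mis))
      mean(means$mean_dcq[means$gene == g & means$sample_class %in% mis])
    else min(gm) - 2
  }, numeric(1))
  rbind(means,
        data.frame(gene = genes, sample_class = "F1sterile", mean_dcq = f1))
}

# brute-force one-tailed T over all pairs (independent of the package's
# cummin shortcut)
brute_force_t <- function(event_indices, N, two_tailed = FALSE) {
  n <- length(event_indices)
  g <- seq_len(n) / n - event_indices / N
  best <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- if (two_tailed) abs(g[j] - g[i]) else g[j] - g[i]
      best <- max(best, d)
    }
  }
  best
}

# small aligned-fragment builder: plants the given species-b alleles at the
# given TSS positions on a fixed-seed random background
build_fragment <- function(gene = "syn", tss_start = -50L, tss_end = 30L,
                           snv_positions = integer(), snv_alleles = NULL,
                           features = NULL, seed = 11L) {
  n <- tss_span_length(tss_start, tss_end)
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  b <- a
  if (length(snv_positions)) {
    idx <- tss_to_index(snv_positions, tss_start, tss_end)
    for (k in seq_along(idx)) {
      b[idx[k]] <- if (is.null(snv_alleles))
        setdiff(c("A", "C", "G", "T"), a[idx[k]])[1L] else snv_alleles[k]
    }
  }
  sequenced_fragment(gene, tss_start, tss_end,
                     paste(a, collapse = ""), paste(b, collapse = ""),
                     features = features)
}

# GA22690 fixed-substitution positions and fragment bounds
ga22690_positions <- function() {
  subs <- dps_substitutions()
  subs$tss_position[subs$gene == "GA22690"]
}
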