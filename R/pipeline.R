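#' Full candidate screen: exclusion rule, Ovd targets, tissue priority
#'
#' Chains the genetic exclusion rule over fertile backcross/introgression
#' misregulation, the Ovd-modulation call (F8se vs F8se+), and the
#' tissue-expression prioritization into one classification.
#'
#' @param flags comparison flags as in [apply_exclusion_rule()] (default:
#'   the bundled reference flags).
#' @param se_comparison per-gene F8se vs F8se+ significance, see
#'   [identify_ovd_targets()].
#' @param tissue_profiles tissue delta-Cq table for the retained
#'   candidates, see [enrichment_table()].
#' @return object of class `"candidate_screen"`: list with `status`
#'   (per-gene classification data.frame including `ovd_target`),
#'   `retained` (gene vector), `ovd_targets`, `enrichment` (calls for the
#'   retained genes) and `prioritized` plus `dropped` from
#'   [prioritize_candidates()].
#' @export
candidate_screen <- function(flags = dps_comparison_flags(),
                             se_comparison = dps_se_comparison(),
                             tissue_profiles = dps_tissue_profiles()) {
  status <- apply_exclusion_rule(flags)
  ovd <- identify_ovd_targets(se_comparison)
  status$ovd_target <- status$gene %in% ovd
  retained <- status$gene[status$retained_candidate]
  calls <- enrichment_table(tissue_profiles)
  pri <- prioritize_candidates(intersect(retained, calls$gene), calls)
  structure(list(status = status, retained = sort(retained),
                 ovd_targets = ovd, enrichment = calls,
                 prioritized = pri$prioritized, dropped = pri$dropped),
            class = "candidate_screen")
}

#' @export
print.candidate_screen <- function(x, ...) {
  n <- nrow(x$status)
  cat(sprintf("Candidate screen over %d gene(s)\n", n))
  cat(sprintf("  excluded (misregulation not HMS-specific): %d\n",
              sum(x$status$excluded)))
  cat(sprintf("  retained candidates: %d  (%s)\n", length(x$retained),
              paste(x$retained, collapse = ", ")))
  cat(sprintf("  Ovd-modulated: %s\n", paste(x$ovd_targets, collapse = ", ")))
  cat(sprintf("  prioritized after tissue filters: %d  (%s)\n",
              length(x$prioritized), paste(x$prioritized, collapse = ", ")))
  if (nrow(x$dropped))
    cat(paste0("    dropped ", x$dropped$gene, ": ", x$dropped$reason,
               collapse = "\n"), "\n")
  invisible(x)
}
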