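# Genetic-logic classification of genes from backcross / introgression
# expression comparisons.  Fertile progeny classes: first-generation
# backcrosses from each parental female (BC1p, BC1b), the fourth-generation
# backcross (BC4), and the X-allele introgressions F8y, F8y+ and F8se.
# F8se+ males (carrying the introgressed sterility allele linked to Ovd)
# are sterile and never count toward fertile misregulation.

BC_CLASSES <- c("BC1p", "BC1b", "BC4")
IG_CLASSES <- c("F8y", "F8y+", "F8se", "F8se+")
FERTILE_CLASSES <- c("BC1p", "BC1b", "BC4", "F8y", "F8y+", "F8se")

#' Misregulated fertile classes per gene
#'
#' A gene x class pair is misregulated when the class's expression differs
#' significantly from BOTH parental species.  Only fertile backcross and
#' introgression classes are considered (F8se+ is sterile and excluded).
#'
#' @param flags data.frame with columns `gene`, `sample_class`,
#'   `diff_from_both_parents` (logical), covering every fertile BC/IG
#'   class of every gene.
#' @return list with elements `by_gene` (named list of misregulated fertile
#'   class vectors), `bc_genes` and `ig_genes` (genes misregulated in at
#'   least one fertile BC, resp. IG, class), and `by_class` (named list:
#'   class -> genes misregulated in it).
#' @export
flag_fertile_misregulation <- function(flags) {
  stopifnot(all(c("gene", "sample_class", "diff_from_both_parents") %in%
                  names(flags)))
  genes <- unique(as.character(flags$gene))
  for (g in genes) {
    have <- flags$sample_class[flags$gene == g]
    miss <- setdiff(FERTILE_CLASSES, have)
    if (length(miss))
      stop(sprintf("missing flag for gene '%s', class '%s'", g, miss[1L]))
  }
  sub <- flags[flags$sample_class %in% FERTILE_CLASSES &
                 flags$diff_from_both_parents, , drop = FALSE]
  by_gene <- lapply(genes, function(g)
    as.character(sub$sample_class[sub$gene == g]))
  names(by_gene) <- genes
  fert_bc <- intersect(FERTILE_CLASSES, BC_CLASSES)
  fert_ig <- intersect(FERTILE_CLASSES, IG_CLASSES)
  list(
    by_gene = by_gene,
    bc_genes = sort(genes[vapply(by_gene, function(x) any(x %in% fert_bc),
                                 logical(1L))]),
    ig_genes = sort(genes[vapply(by_gene, function(x) any(x %in% fert_ig),
                                 logical(1L))]),
    by_class = stats::setNames(lapply(FERTILE_CLASSES, function(cl)
      sort(unique(as.character(sub$gene[sub$sample_class == cl])))),
      FERTILE_CLASSES)
  )
}

#' Exclusion rule for candidate hybrid-male-sterility genes
#'
#' A gene is excluded as an HMS candidate when it is misregulated
#' (different from both parents) in at least one fertile class AND at
#' least one of those misregulated fertile classes is NOT significantly
#' different from sterile F1 males: fertile progeny then reach sterile-like
#' expression without being sterile, so the misregulation cannot be
#' directly tied to sterility.  A gene misregulated in fertile progeny
#' whose misregulated classes all differ from sterile F1 is retained by
#' the letter of the rule but annotated `"review"`.
#'
#' @param flags data.frame with columns `gene`, `sample_class`,
#'   `diff_from_both_parents`, `diff_from_sterile_f1` for every fertile
#'   BC/IG class of every gene.
#' @return data.frame (one row per gene, sorted by gene) with columns
#'   `gene`, `misregulated_in_fertile` (comma-joined classes), `excluded`,
#'   `exclusion_reason`, `retained_candidate`, `review`.
#' @export
apply_exclusion_rule <- function(flags) {
  stopifnot("diff_from_sterile_f1" %in% names(flags))
  mis <- flag_fertile_misregulation(flags)$by_gene
  rows <- lapply(sort(names(mis)), function(g) {
    cls <- mis[[g]]
    if (!length(cls)) {
      return(data.frame(gene = g, misregulated_in_fertile = "",
                        excluded = FALSE, exclusion_reason = "",
                        retained_candidate = TRUE, review = FALSE))
    }
    f1 <- vapply(cls, function(cl) {
      v <- flags$diff_from_sterile_f1[flags$gene == g &
                                        flags$sample_class == cl]
      if (!length(v) || is.na(v[1L]))
        stop(sprintf(
          "misregulated class '%s' of gene '%s' lacks a sterile-F1 comparison",
          cl, g))
      v[1L]
    }, logical(1L))
    matches_f1 <- cls[!f1]
    excl <- length(matches_f1) > 0L
    data.frame(
      gene = g,
      misregulated_in_fertile = paste(cls, collapse = ","),
      excluded = excl,
      exclusion_reason = if (excl)
        sprintf("misregulated in fertile class(es) %s at levels not different from sterile F1",
                paste(matches_f1, collapse = ",")) else "",
      retained_candidate = !excl,
      review = !excl)  # misregulated yet retained -> flag for review
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes modulated by the Ovd allele status
#'
#' Genes whose expression differs significantly between the sepia (F8se,
#' fertile, D. p. pseudoobscura Ovd allele) and non-sepia (F8se+, sterile,
#' D. p. bogotana allele) introgressions are likely targets of the
#' X-linked HMS gene Ovd.
#'
#' @param se_comparison named logical vector (or data.frame with columns
#'   `gene`, `significant`): per gene, is the F8se vs F8se+ comparison
#'   significant at q < 0.05?
#' @return sorted character vector of Ovd-target genes.
#' @export
identify_ovd_targets <- function(se_comparison) {
  if (is.data.frame(se_comparison)) {
    stopifnot(all(c("gene", "significant") %in% names(se_comparison)))
    se_comparison <- stats::setNames(se_comparison$significant,
                                     se_comparison$gene)
  }
  if (is.null(names(se_comparison)))
    stop("se_comparison must be named by gene")
  sort(names(se_comparison)[!is.na(se_comparison) & se_comparison])
}
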