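#' Testes vs accessory-gland enrichment call for one gene
#'
#' From mean delta-Cq per male reproductive tissue (testes T, accessory
#' glands AG, optionally seminal vesicles SV and ejaculatory bulb EB):
#'
#' * `ratio` = |dCq(T)| / |dCq(AG)|, rounded to 2 decimals.  Because
#'   delta-Cq is a log2-scale quantity this is a ratio of magnitudes, not a
#'   linear expression ratio; the linear-scale `fold_2dd = 2^(dCq(T) -
#'   dCq(AG))` is also returned for interpretability.
#' * `enriched_tissue` = `"T"` when dCq(T) > dCq(AG) (higher relative
#'   expression in testes), `"AG"` when lower, `"unclassified"` on a tie.
#' * `fold_change` = 1 / rounded ratio for testes-enriched genes, else the
#'   rounded ratio, rounded to 2 decimals (the reciprocal-of-rounded
#'   convention; the unrounded values are returned alongside).
#' * `low_expressed`: all available tissue delta-Cq < -10;
#'   `high_expressed`: all > -5.
#'
#' @param dcq_by_tissue named numeric vector of mean delta-Cq with names
#'   among `T`, `AG`, `SV`, `EB`; `T` and `AG` are required.
#' @param low_threshold,high_threshold delta-Cq cutoffs for the
#'   low/high-expression flags.
#' @return list with `ratio`, `ratio_unrounded`, `fold_change`,
#'   `fold_change_unrounded`, `fold_2dd`, `enriched_tissue`,
#'   `low_expressed`, `high_expressed`.
#' @examples
#' enrichment_call(c(T = -2.03, AG = -17.05))$ratio        # 0.12
#' enrichment_call(c(T = -12.48, AG = -1.99))$fold_change  # 6.27
#' @export
enrichment_call <- function(dcq_by_tissue, low_threshold = -10,
                            high_threshold = -5) {
  if (!all(c("T", "AG") %in% names(dcq_by_tissue)))
    stop("delta-Cq for tissues T and AG are required")
  t_val <- dcq_by_tissue[["T"]]
  ag <- dcq_by_tissue[["AG"]]
  if (!is.finite(t_val) || !is.finite(ag))
    stop("non-finite tissue delta-Cq")
  if (ag == 0) stop("dCq(AG) = 0: expression ratio undefined")
  ratio_un <- abs(t_val) / abs(ag)
  ratio <- round(ratio_un, 2)
  if (t_val == ag) {
    enriched <- "unclassified"
    fold <- fold_un <- 1
  } else if (t_val > ag) {
    enriched <- "T"
    fold <- round(1 / ratio, 2)
    fold_un <- 1 / ratio_un
  } else {
    enriched <- "AG"
    fold <- ratio
    fold_un <- ratio_un
  }
  list(ratio = ratio,
       ratio_unrounded = ratio_un,
       fold_change = fold,
       fold_change_unrounded = fold_un,
       fold_2dd = 2^(t_val - ag),
       enriched_tissue = enriched,
       low_expressed = all(dcq_by_tissue < low_threshold),
       high_expressed = all(dcq_by_tissue > high_threshold))
}

#' Enrichment calls for a table of tissue profiles
#'
#' @param profiles data.frame with columns `gene`, `tissue`, `mean_dcq`
#'   (long) or `gene`, `T`, `AG`, optionally `SV`, `EB` (wide).
#' @inheritParams enrichment_call
#' @return data.frame, one row per gene: `gene`, `ratio`, `fold_change`,
#'   `enriched_tissue`, `low_expressed`, `high_expressed`, plus the
#'   unrounded columns.
#' @export
enrichment_table <- function(profiles, low_threshold = -10,
                             high_threshold = -5) {
  if (all(c("tissue", "mean_dcq") %in% names(profiles))) {
    wide <- stats::reshape(
      profiles[, c("gene", "tissue", "mean_dcq")],
      idvar = "gene", timevar = "tissue", direction = "wide")
    names(wide) <- sub("^mean_dcq\\.", "", names(wide))
    profiles <- wide
  }
  stopifnot(all(c("gene", "T", "AG") %in% names(profiles)))
  tissues <- intersect(c("T", "SV", "AG", "EB"), names(profiles))
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    v <- unlist(profiles[i, tissues, drop = TRUE])
    v <- v[!is.na(v)]
    cl <- enrichment_call(v, low_threshold, high_threshold)
    data.frame(gene = profiles$gene[i],
               ratio = cl$ratio, fold_change = cl$fold_change,
               enriched_tissue = cl$enriched_tissue,
               low_expressed = cl$low_expressed,
               high_expressed = cl$high_expressed,
               ratio_unrounded = cl$ratio_unrounded,
               fold_change_unrounded = cl$fold_change_unrounded,
               fold_2dd = cl$fold_2dd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prioritize candidate genes by site and level of tissue expression
#'
#' Sperm-side candidacy filter: drops accessory-gland-enriched genes
#' (hybrid male sterility is a sperm-motility phenotype, so seminal-fluid
#' genes are deprioritized), genes very lowly expressed in all assayed
#' male reproductive tissues (delta-Cq < -10) and genes very highly
#' expressed everywhere (delta-Cq > -5, housekeeping-like).
#'
#' @param candidates character vector of candidate gene identifiers.
#' @param calls result of [enrichment_table()] covering every candidate.
#' @return list with `prioritized` (sorted genes kept) and `dropped`
#'   (data.frame gene/reason).
#' @export
prioritize_candidates <- function(candidates, calls) {
  miss <- setdiff(candidates, calls$gene)
  if (length(miss))
    stop("no enrichment call for candidate(s): ", paste(miss, collapse = ", "))
  calls <- calls[match(candidates, calls$gene), , drop = FALSE]
  reason <- character(length(candidates))
  reason[calls$enriched_tissue == "AG"] <- "accessory-gland enriched"
  reason[calls$enriched_tissue == "unclassified"] <-
    "tissue enrichment unclassified (tie)"
  reason[calls$low_expressed] <- "very low expression in all tissues"
  reason[calls$high_expressed] <- "very high expression in all tissues"
  keep <- reason == ""
  list(prioritized = sort(candidates[keep]),
       dropped = data.frame(gene = candidates[!keep],
                            reason = reason[!keep]))
}
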