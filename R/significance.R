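#' Two-way fixed-effects ANOVA of delta-Cq on gene and reference gene
#'
#' Tests for gene and reference-gene main effects and their interaction on
#' the delta-Cq scale.  With dual reference genes a pure additive reference
#' offset shows up as a reference main effect with no interaction.
#'
#' @param dcq data.frame with columns `gene`, `reference_gene`, `delta_cq`.
#' @return data.frame with one row per effect (`gene`, `reference_gene`,
#'   `gene:reference_gene`) and columns `effect`, `f_statistic`, `df_num`,
#'   `df_den`, `p_value`.
#' @export
two_way_anova <- function(dcq) {
  stopifnot(all(c("gene", "reference_gene", "delta_cq") %in% names(dcq)))
  cells <- table(dcq$gene, dcq$reference_gene)
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty cell: gene '%s' x reference '%s'",
                 rownames(cells)[idx[1L]], colnames(cells)[idx[2L]]))
  }
  if (nlevels(factor(dcq$gene)) < 2L || nlevels(factor(dcq$reference_gene)) < 2L)
    stop("both factors need at least two levels")
  if (stats::var(dcq$delta_cq) == 0) {
    a <- length(unique(dcq$gene)); b <- length(unique(dcq$reference_gene))
    return(data.frame(
      effect = c("gene", "reference_gene", "gene:reference_gene"),
      f_statistic = 0,
      df_num = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
      df_den = nrow(dcq) - a * b,
      p_value = 1))
  }
  fit <- stats::aov(delta_cq ~ gene * reference_gene,
                    data = transform(dcq, gene = factor(gene),
                                     reference_gene = factor(reference_gene)))
  tab <- summary(fit)[[1L]]
  eff <- trimws(rownames(tab))
  keep <- eff != "Residuals"
  df_den <- tab[eff == "Residuals", "Df"]
  f <- tab[keep, "F value"]
  p <- tab[keep, "Pr(>F)"]
  # degenerate all-equal data: SS = 0 everywhere -> F = 0, p = 1
  f[!is.finite(f)] <- 0
  p[!is.finite(p)] <- 1
  data.frame(effect = eff[keep],
             f_statistic = f,
             df_num = tab[keep, "Df"],
             df_den = df_den,
             p_value = p,
             row.names = NULL)
}

# center delta_cq within each reference gene, preserving the grand mean,
# so a pure additive reference offset drops out of downstream one-way fits
center_by_reference <- function(dcq) {
  gm <- mean(dcq$delta_cq)
  ref_means <- tapply(dcq$delta_cq, dcq$reference_gene, mean)
  dcq$delta_cq <- dcq$delta_cq - ref_means[as.character(dcq$reference_gene)] + gm
  dcq
}

#' One-way ANOVA of a gene's relative expression across sample classes
#'
#' Fixed-effects one-way ANOVA of delta-Cq across sample classes.  The two
#' reference genes are pooled by default after centering delta-Cq within
#' each reference gene (removing the additive reference offset);
#' `pool_references = FALSE` instead fits each reference gene separately
#' and returns one result per reference.
#'
#' @param dcq data.frame with columns `sample_class`, `reference_gene`,
#'   `delta_cq` (already restricted to one gene, or pass `gene` to subset).
#' @param gene optional gene identifier to subset `dcq$gene` on.
#' @param pool_references pool the reference genes after centering.
#' @return a list with `effect`, `f_statistic`, `df_num`, `df_den`,
#'   `p_value`, `mse`, `group_n`, `group_means` (or a list of such lists,
#'   one per reference gene, when `pool_references = FALSE`).
#' @export
anova_per_gene <- function(dcq, gene = NULL, pool_references = TRUE) {
  if (!is.null(gene)) dcq <- dcq[dcq$gene == gene, , drop = FALSE]
  stopifnot(all(c("sample_class", "delta_cq") %in% names(dcq)))
  if (!pool_references) {
    refs <- unique(as.character(dcq$reference_gene))
    out <- lapply(refs, function(r)
      one_way_fit(dcq[dcq$reference_gene == r, , drop = FALSE]))
    names(out) <- refs
    return(out)
  }
  if ("reference_gene" %in% names(dcq) &&
      length(unique(dcq$reference_gene)) > 1L)
    dcq <- center_by_reference(dcq)
  one_way_fit(dcq)
}

one_way_fit <- function(dcq) {
  cls <- factor(dcq$sample_class)
  if (nlevels(cls) < 2L) stop("at least two sample classes are required")
  n_by <- table(cls)
  if (any(n_by < 2L))
    stop(sprintf("class '%s' has fewer than 2 replicates",
                 names(n_by)[which(n_by < 2L)[1L]]))
  y <- dcq$delta_cq
  k <- nlevels(cls); N <- length(y)
  m <- tapply(y, cls, mean)
  ss_w <- sum((y - m[cls])^2)  # exact zero detection for degenerate layouts
  if (ss_w == 0) {
    ss_b <- sum(n_by * (m - mean(y))^2)
    f <- if (ss_b == 0) 0 else Inf
    p <- if (ss_b == 0) 1 else 0
    mse <- 0
  } else {
    fit <- stats::aov(delta_cq ~ cls,
                      data = data.frame(cls, delta_cq = y))
    tab <- summary(fit)[[1L]]
    f <- tab[1L, "F value"]; p <- tab[1L, "Pr(>F)"]
    mse <- tab[2L, "Mean Sq"]
  }
  list(effect = "sample_class",
       f_statistic = f,
       df_num = k - 1L,
       df_den = N - k,
       p_value = p,
       mse = mse,
       group_n = as.integer(n_by),
       group_means = m)
}

#' Scheffe post-hoc pairwise comparisons for a one-way layout
#'
#' For classes i and j the Scheffe statistic is
#' `S = (m_i - m_j)^2 / (MSE * (1/n_i + 1/n_j) * (k - 1))` and the p-value
#' is the upper tail of F(k-1, N-k) at S, protecting all pairwise contrasts
#' simultaneously.  With k = 2 this reduces to the ordinary two-sample
#' pooled-variance F test.
#'
#' @param dcq data.frame for one gene with columns `sample_class`,
#'   `delta_cq` (and `reference_gene` for pooling, see [anova_per_gene()]).
#' @param pool_references as in [anova_per_gene()] (pooled fit only).
#' @return symmetric matrix of pairwise p-values with unit diagonal,
#'   dimnames = sample classes.
#' @export
scheffe_pairwise <- function(dcq, pool_references = TRUE) {
  if (pool_references && "reference_gene" %in% names(dcq) &&
      length(unique(dcq$reference_gene)) > 1L)
    dcq <- center_by_reference(dcq)
  fit <- one_way_fit(dcq)
  m <- fit$group_means
  n <- fit$group_n
  k <- length(m)
  N <- sum(n)
  p <- matrix(1, k, k, dimnames = list(names(m), names(m)))
  if (fit$mse == 0) {
    warning("MSE is zero; p set to 0 for unequal means, 1 for equal")
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      p[i, j] <- p[j, i] <- if (m[i] == m[j]) 1 else 0
    return(p)
  }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- (m[i] - m[j])^2 / (fit$mse * (1 / n[i] + 1 / n[j]) * (k - 1))
      p[i, j] <- p[j, i] <- stats::pf(s, k - 1, N - k, lower.tail = FALSE)
    }
  }
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted q-values (monotone, order-preserving with the
#' input), via [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (NAs propagate).
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  px <- pvalues[!is.na(pvalues)]
  if (any(px < 0 | px > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Compact letter display
#'
#' Assigns letters to classes such that two classes share at least one
#' letter if and only if they are not significantly different, using the
#' insert-and-absorb algorithm: start from one group holding every class;
#' for each significant pair split every group containing both members
#' into two copies (one without each member); absorb groups contained in
#' another.  Letters are a, b, c, ... in first-use order.
#'
#' @param nonsig symmetric logical matrix over classes with `TRUE` on the
#'   diagonal; `nonsig[i, j]` is `TRUE` when i and j are NOT significantly
#'   different.
#' @return named character vector mapping each class to its letters.
#' @export
letter_display <- function(nonsig) {
  stopifnot(is.matrix(nonsig), is.logical(nonsig),
            nrow(nonsig) == ncol(nonsig))
  if (!isTRUE(all(nonsig == t(nonsig))))
    stop("nonsig matrix must be symmetric")
  if (!all(diag(nonsig)))
    stop("diagonal of nonsig must be TRUE")
  k <- nrow(nonsig)
  cls <- rownames(nonsig)
  if (is.null(cls)) cls <- as.character(seq_len(k))
  groups <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (nonsig[i, j]) next
      hit <- vapply(groups, function(g) i %in% g && j %in% g, logical(1L))
      if (!any(hit)) next
      split_new <- list()
      for (g in groups[hit]) {
        split_new <- c(split_new, list(setdiff(g, i)), list(setdiff(g, j)))
      }
      groups <- c(groups[!hit], split_new)
      groups <- groups[lengths(groups) > 0L]
      groups <- unique(lapply(groups, sort))
      # absorb any group that is a proper subset of another
      keep <- vapply(seq_along(groups), function(a) {
        !any(vapply(seq_along(groups), function(b)
          a != b && length(groups[[a]]) < length(groups[[b]]) &&
            all(groups[[a]] %in% groups[[b]]), logical(1L)))
      }, logical(1L))
      groups <- groups[keep]
    }
  }
  # deterministic ordering: by smallest member, then size
  ord <- order(vapply(groups, min, integer(1L)),
               -lengths(groups))
  groups <- groups[ord]
  letters_out <- rep("", k)
  for (gi in seq_along(groups)) {
    lab <- make_letter(gi)
    for (m in groups[[gi]])
      letters_out[m] <- paste0(letters_out[m], lab)
  }
  if (any(letters_out == ""))
    stop("internal error: class left without a letter")  # cannot happen: singletons survive
  stats::setNames(letters_out, cls)
}

make_letter <- function(i) {
  # a, b, ..., z, aa, ab, ... for pathological numbers of groups
  out <- ""
  i <- i - 1L
  repeat {
    out <- paste0(letters[i %% 26L + 1L], out)
    i <- i %/% 26L - 1L
    if (i < 0L) break
  }
  out
}

#' Per-gene significance report over sample classes
#'
#' Runs, for every gene in a delta-Cq table: the pooled one-way ANOVA
#' across sample classes, Scheffe pairwise comparisons, FDR correction of
#' the pairwise p-values (jointly across all genes by default, the
#' conservative reading of a single experiment-wide family; or per gene),
#' and the compact letter display at `q < alpha`.
#'
#' @param dcq data.frame with columns `gene`, `sample_class`,
#'   `reference_gene`, `delta_cq`.
#' @param alpha significance threshold on q-values (default 0.05).
#' @param fdr_scope `"joint"` (one family over all genes' pairwise tests)
#'   or `"per_gene"`.
#' @param pool_references as in [anova_per_gene()].
#' @return object of class `"significance_report"`: named list per gene,
#'   each with `anova`, `pairwise` (p matrix), `qvalues` (q matrix),
#'   `letters`, `group_means`; attributes `alpha` and `fdr_scope`.
#' @export
expression_significance <- function(dcq, alpha = 0.05,
                                    fdr_scope = c("joint", "per_gene"),
                                    pool_references = TRUE) {
  fdr_scope <- match.arg(fdr_scope)
  genes <- unique(as.character(dcq$gene))
  rep_list <- lapply(genes, function(g) {
    sub <- dcq[dcq$gene == g, , drop = FALSE]
    an <- anova_per_gene(sub, pool_references = pool_references)
    pw <- scheffe_pairwise(sub, pool_references = pool_references)
    list(anova = an, pairwise = pw, group_means = an$group_means)
  })
  names(rep_list) <- genes
  # FDR across the chosen family (upper triangles only, then mirrored back)
  tri_ps <- lapply(rep_list, function(r) r$pairwise[upper.tri(r$pairwise)])
  if (fdr_scope == "joint") {
    qs <- bh_fdr(unlist(tri_ps))
    splits <- rep(seq_along(tri_ps), times = lengths(tri_ps))
    tri_qs <- split(qs, splits)
  } else {
    tri_qs <- lapply(tri_ps, bh_fdr)
  }
  for (i in seq_along(rep_list)) {
    q <- rep_list[[i]]$pairwise
    q[upper.tri(q)] <- tri_qs[[i]]
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    diag(q) <- 1
    rep_list[[i]]$qvalues <- q
    rep_list[[i]]$letters <- letter_display(q >= alpha)
  }
  structure(rep_list, alpha = alpha, fdr_scope = fdr_scope,
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("Significance report for %d gene(s) (alpha = %g, FDR scope: %s)\n",
              length(x), attr(x, "alpha"), attr(x, "fdr_scope")))
  for (g in names(x)) {
    an <- x[[g]]$anova
    cat(sprintf("  %s: F(%d, %d) = %.2f, p = %.3g; groups: %s\n",
                g, an$df_num, an$df_den, an$f_statistic, an$p_value,
                paste(sprintf("%s=%s", names(x[[g]]$letters), x[[g]]$letters),
                      collapse = " ")))
  }
  invisible(x)
}

#' Class-comparison flags from a significance report
#'
#' Derives, for each gene and each fertile backcross/introgression class,
#' whether the class differs significantly (q < alpha) from BOTH parental
#' species and whether it differs from sterile F1 males — the inputs of the
#' candidate exclusion rule.
#'
#' @param report a [expression_significance()] result.
#' @param classes character vector of progeny classes to flag.
#' @param parents length-2 character vector of parental class labels.
#' @param sterile_f1 sterile F1 class label (flag is `NA` when that class
#'   is absent from the report).
#' @return data.frame with columns `gene`, `sample_class`,
#'   `diff_from_both_parents`, `diff_from_sterile_f1`.
#' @export
comparison_flags <- function(report,
                             classes = c("BC1p", "BC1b", "BC4",
                                         "F8y", "F8y+", "F8se", "F8se+"),
                             parents = c("Dpb", "Dpp"),
                             sterile_f1 = "F1sterile") {
  alpha <- attr(report, "alpha")
  rows <- list()
  for (g in names(report)) {
    q <- report[[g]]$qvalues
    have <- intersect(classes, rownames(q))
    for (cl in have) {
      both <- all(q[cl, parents] < alpha)
      f1 <- if (sterile_f1 %in% rownames(q)) q[cl, sterile_f1] < alpha else NA
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample_class = cl,
        diff_from_both_parents = both,
        diff_from_sterile_f1 = f1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
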