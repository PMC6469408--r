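#' Relative expression from raw Cq values
#'
#' Computes delta-Cq record by record as the reference-gene Cq minus the
#' target-gene Cq, so that a higher delta-Cq means higher relative
#' expression of the target.  No aggregation is performed.  Rows with a
#' non-finite Cq are dropped with a warning; the number dropped is attached
#' as attribute `"n_rejected"`.
#'
#' @param records data.frame of Cq records with columns `gene`,
#'   `sample_class`, `replicate`, `reference_gene`, `cq_reference`,
#'   `cq_target` (extra columns such as `tissue` are carried through).
#' @return data.frame with the same identifying columns plus `delta_cq`.
#' @examples
#' rec <- data.frame(gene = "g", sample_class = "Dpp", replicate = 1,
#'                   reference_gene = "RpL32",
#'                   cq_reference = 20, cq_target = 31.14)
#' compute_delta_cq(rec)$delta_cq  # -11.14
#' @export
compute_delta_cq <- function(records) {
  need <- c("gene", "sample_class", "replicate", "reference_gene",
            "cq_reference", "cq_target")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- is.finite(records$cq_reference) & is.finite(records$cq_target)
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    warning(sprintf("%d record(s) with non-finite Cq rejected", n_bad))
  out <- records[ok, , drop = FALSE]
  out$delta_cq <- out$cq_reference - out$cq_target
  out$cq_reference <- out$cq_target <- NULL
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_bad
  out
}

#' Amplification efficiency from a template dilution series
#'
#' Ordinary least squares of Cq on log10 relative input; the efficiency is
#' `10^(-1/slope) - 1`, so a perfect doubling per cycle
#' (slope -1/log10(2) = -3.32) gives efficiency 1.  The conventional
#' acceptance band (0.9-1.1) is reported via the `within_band` element but
#' never enforced.
#'
#' @param log10_input numeric vector of log10 relative template amounts.
#' @param cq numeric vector of threshold cycles, same length.
#' @return list with `slope`, `intercept`, `efficiency`, `r_squared`,
#'   `within_band`.
#' @export
primer_efficiency <- function(log10_input, cq) {
  stopifnot(length(log10_input) == length(cq))
  if (length(cq) < 3L)
    stop("at least 3 dilution points are required")
  if (stats::var(log10_input) == 0)
    stop("dilution inputs have zero variance")
  if (stats::var(cq) == 0)
    stop("degenerate dilution series: constant Cq, slope is zero")
  fit <- stats::lm(cq ~ log10_input)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope == 0)
    stop("degenerate dilution series: slope is zero or undefined")
  eff <- 10^(-1 / slope) - 1
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1L]),
       efficiency = eff,
       r_squared = 1 - sum(stats::resid(fit)^2) / sum((cq - mean(cq))^2),
       within_band = eff >= 0.9 && eff <= 1.1)
}

#' Mean and standard error of counts per class
#'
#' @param counts numeric vector of counts (e.g. offspring per vial).
#' @param class factor/character vector of class labels, same length.
#' @return data.frame with columns `class`, `n`, `mean`, `se` where
#'   `se = sd/sqrt(n)` with the n-1 sample standard deviation; a singleton
#'   class yields `se = 0` with a warning.
#' @export
summarize_counts <- function(counts, class) {
  stopifnot(length(counts) == length(class))
  if (!length(counts)) stop("no counts supplied")
  if (any(!is.finite(counts))) stop("non-finite counts")
  cls <- unique(as.character(class))
  out <- do.call(rbind, lapply(cls, function(cl) {
    x <- counts[class == cl]
    if (length(x) == 1L) {
      warning(sprintf("class '%s' has a single observation; SE set to 0", cl))
      se <- 0
    } else {
      se <- stats::sd(x) / sqrt(length(x))
    }
    data.frame(class = cl, n = length(x), mean = mean(x), se = se)
  }))
  rownames(out) <- NULL
  out
}
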