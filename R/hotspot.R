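#' G values of an event configuration
#'
#' For n point events at strictly increasing 1-based indices x_1 < ... < x_n
#' on a sequence of N positions, the i-th G value is the gap between the
#' event's relative rank among events and its relative position along the
#' sequence:
#'
#'   G_i = i/n - x_i/N
#'
#' A run of positive differences G_j - G_i (j > i) marks a stretch of
#' sequence accumulating events faster than the uniform expectation.
#'
#' @param event_indices sorted vector of distinct integers in 1..N.
#' @param N sequence length (number of positions).
#' @return numeric vector of n G values.
#' @export
g_values <- function(event_indices, N) {
  n <- length(event_indices)
  if (n == 0L) stop("no events in region")
  check_event_indices(event_indices, N)
  seq_len(n) / n - event_indices / N
}

check_event_indices <- function(event_indices, N) {
  stopifnot(length(N) == 1L, N >= 1)
  if (any(event_indices < 1 | event_indices > N))
    stop("event indices must lie in 1..N")
  if (any(diff(event_indices) <= 0))
    stop("event indices must be strictly increasing and distinct")
  invisible(TRUE)
}

#' Maximal differential accumulation statistic T
#'
#' T is the largest difference G_j - G_i over ordered event-rank pairs
#' i < j; the maximizing pair delimits the candidate hotspot.  The signed
#' (one-tailed, positive) convention is used: a super-dispersed
#' configuration can yield T <= 0 and is reported as-is.  With
#' `two_tailed = TRUE` the maximum of |G_j - G_i| is used instead.
#'
#' Ties are broken towards the smallest i, then smallest j.
#'
#' @param g numeric vector of G values in event-rank order (length >= 2).
#' @param two_tailed use max |deltaG| rather than max deltaG.
#' @return list with `t_statistic` and `best_pair` (integer ranks i < j).
#' @export
max_delta_g <- function(g, two_tailed = FALSE) {
  n <- length(g)
  if (n < 2L) stop("at least two events are required")
  dg <- outer(g, g, "-")            # dg[j, i] = g_j - g_i
  dg <- if (two_tailed) abs(dg) else dg
  dg[upper.tri(dg, diag = TRUE)] <- -Inf  # keep i < j only
  best <- which(dg == max(dg), arr.ind = TRUE)
  best <- best[order(best[, 2L], best[, 1L]), , drop = FALSE][1L, ]
  list(t_statistic = max(dg), best_pair = c(i = unname(best[2L]), j = unname(best[1L])))
}

# O(n) one-tailed T for simulation loops (no pair bookkeeping)
t_statistic_fast <- function(g) {
  n <- length(g)
  max(g[-1L] - cummin(g)[-n])
}

#' Monte Carlo null distribution of T
#'
#' Draws `n_sim` configurations of `n` event positions sampled uniformly
#' without replacement from 1..N, and returns the T statistic of each.
#' The draw is vectorised: positions are sampled with replacement, rows with
#' collisions are redrawn exactly, so the result is an exact uniform sample
#' of n-subsets.
#'
#' @param n number of events (2 <= n <= N).
#' @param N sequence length.
#' @param n_sim number of null replicates.
#' @param seed integer seed; the generator state is restored on exit.
#' @param two_tailed compute max |deltaG| per replicate instead of max deltaG.
#' @return numeric vector of `n_sim` null T values.
#' @export
monte_carlo_null <- function(n, N, n_sim = 100000L, seed = NULL, two_tailed = FALSE) {
  stopifnot(n >= 2L, n_sim >= 1L)
  if (n > N) stop("n must not exceed N")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  X <- matrix(sample.int(N, n_sim * n, replace = TRUE), nrow = n_sim)
  X <- row_sort(X)
  bad <- which(rowSums(X[, -1L, drop = FALSE] == X[, -n, drop = FALSE]) > 0L)
  while (length(bad)) {
    for (r in bad) X[r, ] <- sort(sample.int(N, n))
    bad <- integer(0)
  }
  # G matrix and running max of G_j - min_{i<j} G_i, column by column
  rank_over_n <- seq_len(n) / n
  G1 <- rank_over_n[1L] - X[, 1L] / N
  if (two_tailed) {
    run_min <- run_max <- G1
    best <- rep(-Inf, n_sim)
    for (j in 2L:n) {
      Gj <- rank_over_n[j] - X[, j] / N
      best <- pmax(best, Gj - run_min, run_max - Gj)
      run_min <- pmin(run_min, Gj)
      run_max <- pmax(run_max, Gj)
    }
  } else {
    run_min <- G1
    best <- rep(-Inf, n_sim)
    for (j in 2L:n) {
      Gj <- rank_over_n[j] - X[, j] / N
      best <- pmax(best, Gj - run_min)
      run_min <- pmin(run_min, Gj)
    }
  }
  best
}

# sort each row of an integer matrix with a single order() call
row_sort <- function(X) {
  n_row <- nrow(X)
  o <- order(rep(seq_len(n_row), times = ncol(X)), as.vector(X))
  matrix(as.vector(X)[o], nrow = n_row, byrow = TRUE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Exact null distribution of T by enumeration
#'
#' Enumerates all n-subsets of 1..N (testing oracle for the Monte Carlo
#' null; refuses to enumerate more than 10^6 configurations).
#'
#' @inheritParams monte_carlo_null
#' @return data.frame with columns `t` (distinct T values, ascending) and
#'   `probability`.
#' @export
exact_null_enumeration <- function(n, N, two_tailed = FALSE) {
  stopifnot(n >= 1L, n <= N)
  if (choose(N, n) > 1e6)
    stop("choose(N, n) exceeds 1e6; use monte_carlo_null() instead")
  stat <- if (two_tailed) {
    function(x) {
      g <- g_values(x, N)
      max(abs(outer(g, g, "-")))
    }
  } else {
    function(x) t_statistic_fast(g_values(x, N))
  }
  if (n == 1L) {
    tv <- rep(0, N)  # no pair; define T = 0 point mass (degenerate)
  } else {
    tv <- utils::combn(N, n, stat)
  }
  tab <- table(tv)
  out <- data.frame(
    t = as.numeric(names(tab)),
    probability = as.numeric(tab) / length(tv)
  )
  out[order(out$t), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Test for clustering of substitutions along a sequence
#'
#' Fits the empirical-CDF clustering test to a configuration of point
#' events (fixed interspecies substitutions) on a sequenced fragment: the
#' observed statistic T = max deltaG is compared against its Monte Carlo
#' null under uniform placement of n events on N positions (sampling
#' without replacement), giving a one-tailed p-value for a local
#' accumulation ("hotspot") of substitutions.
#'
#' Events may be supplied either as TSS-relative positions together with
#' the fragment bounds (`tss_interval`), or directly as 1-based indices via
#' `event_indices` and `N`.  Indels count as single point events at their
#' leftmost base.
#'
#' @param tss_positions TSS-relative event positions (no position 0).
#' @param tss_interval length-2 integer vector `c(tss_start, tss_end)`.
#' @param event_indices alternative input: sorted distinct indices in 1..N.
#' @param N sequence length (with `event_indices`).
#' @param n_sim Monte Carlo replicates for the null distribution.
#' @param seed integer seed for the null draw (stored in the result).
#' @param two_tailed use max |deltaG|; the default one-tailed positive
#'   convention looks for regions where deltaG is positive.
#' @param gene,region optional labels carried into the result.
#' @return An object of class `"hotspot_test"`: a list with the G values,
#'   `t_statistic`, the maximizing `best_pair` of event ranks, the hotspot
#'   interval (TSS positions when available), the inclusive event count of
#'   the hotspot, the one-tailed Monte Carlo `p_value`
#'   (add-one convention: (1 + #\{T* >= T\}) / (n_sim + 1)), the raw
#'   exceedance count, `n`, `N`, `n_sim` and `seed`.
#' @examples
#' ht <- hotspot_test(event_indices = c(5, 40, 42, 44, 47, 90), N = 100,
#'                    n_sim = 2000, seed = 1)
#' ht$t_statistic
#' @export
hotspot_test <- function(tss_positions = NULL, tss_interval = NULL,
                         event_indices = NULL, N = NULL,
                         n_sim = 100000L, seed = 1L, two_tailed = FALSE,
                         gene = NA_character_, region = NA_character_) {
  if (!is.null(tss_positions)) {
    stopifnot(!is.null(tss_interval), length(tss_interval) == 2L)
    tss_positions <- sort(unique(as.integer(tss_positions)))
    N <- tss_span_length(tss_interval[1L], tss_interval[2L])
    event_indices <- tss_to_index(tss_positions, tss_interval[1L], tss_interval[2L])
  } else {
    stopifnot(!is.null(event_indices), !is.null(N))
    event_indices <- sort(unique(as.integer(event_indices)))
  }
  n <- length(event_indices)
  if (n < 2L) stop("at least two events are required for the clustering test")
  g <- g_values(event_indices, N)
  mx <- max_delta_g(g, two_tailed = two_tailed)
  i <- mx$best_pair[["i"]]; j <- mx$best_pair[["j"]]
  null_t <- monte_carlo_null(n, N, n_sim = n_sim, seed = seed,
                             two_tailed = two_tailed)
  exceed <- sum(null_t >= mx$t_statistic)
  hotspot <- if (!is.null(tss_positions)) {
    c(tss_positions[i], tss_positions[j])
  } else {
    c(event_indices[i], event_indices[j])
  }
  structure(list(
    gene = gene, region = region,
    g_values = g,
    t_statistic = mx$t_statistic,
    best_pair = mx$best_pair,
    hotspot_interval = hotspot,
    events_in_hotspot = j - i + 1L,
    p_value = (1 + exceed) / (n_sim + 1),
    exceedance_count = exceed,
    n = n, N = N,
    event_indices = event_indices,
    tss_positions = tss_positions,
    n_sim = n_sim, seed = seed, two_tailed = two_tailed
  ), class = "hotspot_test")
}

#' @export
print.hotspot_test <- function(x, digits = 4, ...) {
  cat("\n\tEmpirical-CDF clustering test (G/deltaG/T, Monte Carlo null)\n\n")
  if (!is.na(x$gene) || !is.na(x$region))
    cat("data: ", paste(stats::na.omit(c(x$gene, x$region)), collapse = ", "), "\n")
  cat(sprintf("n = %d events on N = %d positions\n", x$n, x$N))
  cat(sprintf("T = %s (%s-tailed), hotspot = [%s, %s] spanning %d events\n",
              format(x$t_statistic, digits = digits),
              if (x$two_tailed) "two" else "one",
              x$hotspot_interval[1L], x$hotspot_interval[2L],
              x$events_in_hotspot))
  cat(sprintf("Monte Carlo p-value = %s  (%d of %d null T* >= T; seed %s)\n\n",
              format(x$p_value, digits = digits),
              x$exceedance_count, x$n_sim, format(x$seed)))
  invisible(x)
}

#' @method summary hotspot_test
#' @export
summary.hotspot_test <- function(object, ...) {
  pos <- if (is.null(object$tss_positions)) object$event_indices else object$tss_positions
  out <- data.frame(
    rank = seq_len(object$n),
    position = pos,
    index = object$event_indices,
    g = object$g_values
  )
  attr(out, "test") <- object
  class(out) <- c("summary.hotspot_test", "data.frame")
  out
}

#' @export
print.summary.hotspot_test <- function(x, ...) {
  print.hotspot_test(attr(x, "test"))
  print.data.frame(x)
  invisible(x)
}

#' Draw from the fitted null distribution of T
#'
#' `simulate()` on a `hotspot_test` object re-draws null replicates of the
#' T statistic under uniform placement of the object's n events on its N
#' positions.
#'
#' @param object a `hotspot_test` fit.
#' @param nsim replicates per draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return numeric vector of `nsim` null T values.
#' @method simulate hotspot_test
#' @export
simulate.hotspot_test <- function(object, nsim = object$n_sim, seed = NULL, ...) {
  monte_carlo_null(object$n, object$N, n_sim = nsim, seed = seed,
                   two_tailed = object$two_tailed)
}

#' Plot the empirical CDF of events against the uniform expectation
#'
#' Step plot of event rank i/n against relative position x_i/N with the
#' uniform diagonal; the maximizing deltaG pair is highlighted.  The
#' vertical gap between curve and diagonal at each event is its G value.
#'
#' @param x a `hotspot_test` object.
#' @param ... passed to [plot()].
#' @method plot hotspot_test
#' @export
plot.hotspot_test <- function(x, ...) {
  rel_pos <- x$event_indices / x$N
  rel_rank <- seq_len(x$n) / x$n
  plot(c(0, rel_pos, 1), c(0, rel_rank, 1), type = "s",
       xlab = "relative position x/N", ylab = "event rank i/n",
       main = sprintf("T = %.3f, p = %.4g", x$t_statistic, x$p_value), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  i <- x$best_pair[["i"]]; j <- x$best_pair[["j"]]
  graphics::points(rel_pos[c(i, j)], rel_rank[c(i, j)], pch = 19, col = "red3")
  graphics::segments(rel_pos[i], rel_rank[i], rel_pos[j], rel_rank[j],
                     col = "red3", lwd = 2)
  invisible(x)
}

#' Run the clustering test over a table of events, per gene and region
#'
#' Convenience driver reproducing the per-region analysis: for each gene it
#' tests the whole fragment and, optionally, each regulatory domain window
#' (promoter P = -200..+200, promoter-proximal PP = -500..-201,
#' promoter-distal PD = upstream of -500) that contains at least two
#' events.  p-values are BH-FDR corrected across all reported tests.
#'
#' @param events data.frame with columns `gene`, `tss_position`.
#' @param fragments data.frame with columns `gene`, `tss_start`, `tss_end`.
#' @param regions character vector among `"whole_fragment"`, `"P"`, `"PP"`,
#'   `"PD"`.
#' @param n_sim,seed,two_tailed passed to [hotspot_test()]; per-test seeds
#'   are derived deterministically from `seed`.
#' @param fdr apply BH correction across rows (column `q_value`).
#' @return data.frame, one row per (gene, region) tested.
#' @export
hotspot_scan <- function(events, fragments,
                         regions = c("whole_fragment", "PD", "PP", "P"),
                         n_sim = 100000L, seed = 1L, two_tailed = FALSE,
                         fdr = TRUE) {
  stopifnot(all(c("gene", "tss_position") %in% names(events)),
            all(c("gene", "tss_start", "tss_end") %in% names(fragments)))
  regions <- match.arg(regions, several.ok = TRUE)
  rows <- list()
  k <- 0L
  for (gi in seq_len(nrow(fragments))) {
    gene <- fragments$gene[gi]
    a <- fragments$tss_start[gi]; b <- fragments$tss_end[gi]
    pos <- sort(events$tss_position[events$gene == gene])
    for (reg in regions) {
      win <- switch(reg,
        whole_fragment = c(a, b),
        P  = c(max(a, -200L), min(b, 200L)),
        PP = c(max(a, -500L), min(b, -201L)),
        PD = c(a, min(b, -501L)))
      if (win[1L] >= win[2L] || win[1L] == 0L || win[2L] == 0L) next
      p_in <- pos[pos >= win[1L] & pos <= win[2L]]
      if (length(p_in) < 2L) next
      k <- k + 1L
      sub_seed <- (seed + 1000L * k) %% .Machine$integer.max
      ht <- hotspot_test(tss_positions = p_in, tss_interval = win,
                         n_sim = n_sim, seed = sub_seed,
                         two_tailed = two_tailed, gene = gene, region = reg)
      rows[[k]] <- data.frame(
        gene = gene, region = reg, n = ht$n, N = ht$N,
        t_statistic = ht$t_statistic,
        hotspot_start = ht$hotspot_interval[1L],
        hotspot_end = ht$hotspot_interval[2L],
        events_in_hotspot = ht$events_in_hotspot,
        p_value = ht$p_value, n_sim = n_sim, seed = sub_seed
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (fdr) out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
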