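#' Aligned interspecies sequenced fragment
#'
#' Container for a pair of aligned sequences around a gene's transcription
#' start site: species a is the reference frame (D. p. pseudoobscura in
#' the bundled data), species b the comparison species.  Coordinates are
#' TSS-relative (see [tss_to_index()]).
#'
#' @param gene gene identifier.
#' @param tss_start,tss_end TSS-relative fragment bounds.
#' @param seq_a,seq_b aligned sequences (equal length, characters in
#'   `A,C,G,T,-`; ambiguity codes tolerated but their columns are skipped
#'   when calling differences).
#' @param features optional data.frame with columns `feature_type` (one of
#'   `CDS`, `transcript`, `UTR5`, or `neighbor_gene:<name>`), `tss_start`,
#'   `tss_end`.
#' @return object of class `"sequenced_fragment"`.
#' @export
sequenced_fragment <- function(gene, tss_start, tss_end, seq_a, seq_b,
                               features = NULL) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length")
  n_ungapped <- nchar(gsub("-", "", seq_a))
  span <- tss_span_length(tss_start, tss_end)
  if (n_ungapped != span)
    stop(sprintf(
      "ungapped species-a length (%d) does not match TSS span %d..%d (%d positions)",
      n_ungapped, tss_start, tss_end, span))
  if (is.null(features))
    features <- data.frame(feature_type = character(), tss_start = integer(),
                           tss_end = integer())
  structure(list(gene = gene, tss_start = tss_start, tss_end = tss_end,
                 seq_a = seq_a, seq_b = seq_b, features = features,
                 N = span),
            class = "sequenced_fragment")
}

#' @export
print.sequenced_fragment <- function(x, ...) {
  cat(sprintf("Sequenced fragment %s: TSS %+d..%+d (%d positions, %d alignment columns, %d feature(s))\n",
              x$gene, x$tss_start, x$tss_end, x$N, nchar(x$seq_a),
              nrow(x$features)))
  invisible(x)
}

#' Call interspecies differences on an aligned fragment
#'
#' Walks the alignment columns on the species-a (reference) coordinate
#' frame: each mismatched non-gap column yields one SNV; a run of
#' consecutive gap columns in one species collapses to a single indel
#' event placed at the leftmost affected species-a base (insertions
#' relative to species a take the position of the preceding species-a
#' base).  Columns containing ambiguity codes are skipped with a warning.
#' The `fixed` status of every event is left `NA` until polymorphism
#' evidence is applied (see [filter_shared_polymorphisms()]).
#'
#' @param fragment a [sequenced_fragment()].
#' @return data.frame with columns `gene`, `tss_position`, `index`,
#'   `kind` (`SNV`, `deletion`, `insertion`), `allele_a`, `allele_b`,
#'   `domain`, `fixed` (NA).
#' @export
call_differences <- function(fragment) {
  stopifnot(inherits(fragment, "sequenced_fragment"))
  a <- strsplit(fragment$seq_a, "")[[1L]]
  b <- strsplit(fragment$seq_b, "")[[1L]]
  valid <- c("A", "C", "G", "T", "-")
  n_col <- length(a)
  events <- list()
  skipped <- 0L
  a_pos <- 0L  # ungapped species-a index of the last consumed base
  col <- 1L
  while (col <= n_col) {
    ca <- a[col]; cb <- b[col]
    if (!(ca %in% valid) || !(cb %in% valid)) {
      skipped <- skipped + 1L
      if (ca != "-") a_pos <- a_pos + 1L
      col <- col + 1L
      next
    }
    if (ca == "-" && cb == "-") { col <- col + 1L; next }
    if (cb == "-" && ca != "-") {         # deletion in species b
      start_pos <- a_pos + 1L
      del <- character()
      while (col <= n_col && b[col] == "-" && a[col] != "-" &&
             a[col] %in% valid) {
        a_pos <- a_pos + 1L
        del <- c(del, a[col])
        col <- col + 1L
      }
      events[[length(events) + 1L]] <- list(
        index = start_pos, kind = "deletion",
        allele_a = paste(del, collapse = ""), allele_b = "-")
      next
    }
    if (ca == "-" && cb != "-") {         # insertion in species b
      ins <- character()
      anchor <- max(a_pos, 1L)  # preceding species-a base (1 at fragment start)
      while (col <= n_col && a[col] == "-" && b[col] != "-" &&
             b[col] %in% valid) {
        ins <- c(ins, b[col])
        col <- col + 1L
      }
      events[[length(events) + 1L]] <- list(
        index = anchor, kind = "insertion",
        allele_a = "-", allele_b = paste(ins, collapse = ""))
      next
    }
    a_pos <- a_pos + 1L
    if (ca != cb)
      events[[length(events) + 1L]] <- list(
        index = a_pos, kind = "SNV", allele_a = ca, allele_b = cb)
    col <- col + 1L
  }
  if (skipped > 0L)
    warning(sprintf("%d alignment column(s) with ambiguity codes skipped",
                    skipped))
  if (!length(events)) {
    return(data.frame(gene = character(), tss_position = integer(),
                      index = integer(), kind = character(),
                      allele_a = character(), allele_b = character(),
                      domain = character(), fixed = logical()))
  }
  idx <- vapply(events, function(e) e$index, integer(1L))
  out <- data.frame(
    gene = fragment$gene,
    tss_position = index_to_tss(idx, fragment$tss_start, fragment$tss_end),
    index = idx,
    kind = vapply(events, function(e) e$kind, character(1L)),
    allele_a = vapply(events, function(e) e$allele_a, character(1L)),
    allele_b = vapply(events, function(e) e$allele_b, character(1L)),
    fixed = NA)
  out$domain <- vapply(out$tss_position, classify_domain,
                       character(1L), features = fragment$features)
  out[, c("gene", "tss_position", "index", "kind", "allele_a", "allele_b",
          "domain", "fixed")]
}

#' Regulatory-domain label of a TSS-relative position
#'
#' Feature annotations take precedence over the distance windows: a
#' position inside a CDS is `"CDS"` (reported `"CDS/P"` when it also falls
#' in the promoter window), inside a 5' UTR `"T(5'UTR)"`, inside the
#' transcript `"T"`, and inside an annotated neighboring gene that gene's
#' name.  Otherwise the promoter windows apply: `P` = -200..+200,
#' `PP` = -500..-201, `PD` = strictly upstream of -500 (-500 itself is
#' PP); unannotated positions downstream of +200 are `"other"`.
#'
#' @param tss_position a single TSS-relative position (not 0).
#' @param features feature data.frame as in [sequenced_fragment()].
#' @return character domain label.
#' @examples
#' classify_domain(-84)    # "P"
#' classify_domain(-348)   # "PP"
#' classify_domain(-1052)  # "PD"
#' @export
classify_domain <- function(tss_position, features = NULL) {
  stopifnot(length(tss_position) == 1L, tss_position != 0)
  in_promoter <- tss_position >= -200 && tss_position <= 200
  if (!is.null(features) && nrow(features)) {
    hit <- features[features$tss_start <= tss_position &
                      features$tss_end >= tss_position, , drop = FALSE]
    if (nrow(hit)) {
      types <- hit$feature_type
      if ("CDS" %in% types)
        return(if (in_promoter) "CDS/P" else "CDS")
      if ("UTR5" %in% types)
        return("T(5'UTR)")
      if ("transcript" %in% types)
        return(if (in_promoter) "T/P" else "T")
      nb <- grep("^neighbor_gene:", types, value = TRUE)
      if (length(nb))
        return(sub("^neighbor_gene:", "", nb[1L]))
    }
  }
  if (in_promoter) return("P")
  if (tss_position >= -500 && tss_position < -200) return("PP")
  if (tss_position < -500) return("PD")
  "other"
}

#' Resolve fixed vs shared-polymorphism status of called differences
#'
#' An apparent interspecies difference is a shared polymorphism (not
#' fixed) when the species-b allele also segregates among conspecific
#' strains of species a at that site.  Evidence is either a per-site
#' allele table or raw strain reads; a read only contributes evidence when
#' its global identity to its best-matching window of the species-a
#' fragment exceeds `min_identity` (the sequence-read screening contract;
#' default 90%).
#'
#' @param events result of [call_differences()].
#' @param evidence data.frame with columns `tss_position`, `alleles`
#'   (comma-separated allele strings observed among strains), or `NULL`
#'   for no polymorphism evidence (all events fixed).
#' @param reads optional character vector of strain read sequences; needs
#'   `fragment`.
#' @param fragment the [sequenced_fragment()] the events came from
#'   (required with `reads`).
#' @param min_identity minimum read identity for evidence (exclusive).
#' @return `events` with `fixed` resolved (`TRUE` unless the species-b
#'   allele is present in the evidence at that site).
#' @export
filter_shared_polymorphisms <- function(events, evidence = NULL,
                                        reads = NULL, fragment = NULL,
                                        min_identity = 0.9) {
  if (!is.null(reads)) {
    if (is.null(fragment))
      stop("fragment is required to place strain reads")
    read_ev <- reads_to_evidence(reads, fragment, min_identity)
    evidence <- merge_evidence(evidence, read_ev)
  }
  if (is.null(evidence) || !nrow(events)) {
    events$fixed <- rep(TRUE, nrow(events))
    return(events)
  }
  stopifnot(all(c("tss_position", "alleles") %in% names(evidence)))
  ev_alleles <- strsplit(as.character(evidence$alleles), ",")
  events$fixed <- vapply(seq_len(nrow(events)), function(i) {
    hit <- which(evidence$tss_position == events$tss_position[i])
    if (!length(hit)) return(TRUE)
    !(events$allele_b[i] %in% toupper(trimws(unlist(ev_alleles[hit]))))
  }, logical(1L))
  events
}

# align each read to its best window of the ungapped species-a sequence by
# global identity over all offsets; reads above the identity threshold
# contribute their bases as per-site allele evidence
reads_to_evidence <- function(reads, fragment, min_identity = 0.9) {
  ref <- strsplit(gsub("-", "", fragment$seq_a), "")[[1L]]
  n <- length(ref)
  site_alleles <- list()
  for (rd in reads) {
    r <- strsplit(toupper(rd), "")[[1L]]
    L <- length(r)
    if (L > n) next
    offsets <- seq_len(n - L + 1L)
    ident <- vapply(offsets, function(o) sum(ref[o:(o + L - 1L)] == r) / L,
                    numeric(1L))
    best <- which.max(ident)
    if (ident[best] <= min_identity) next
    for (k in seq_len(L)) {
      pos <- as.character(best + k - 1L)
      site_alleles[[pos]] <- union(site_alleles[[pos]], r[k])
    }
  }
  if (!length(site_alleles))
    return(data.frame(tss_position = integer(), alleles = character()))
  idx <- as.integer(names(site_alleles))
  data.frame(
    tss_position = index_to_tss(idx, fragment$tss_start, fragment$tss_end),
    alleles = vapply(site_alleles, paste, character(1L), collapse = ","))
}

merge_evidence <- function(a, b) {
  if (is.null(a) || !nrow(a)) return(b)
  if (is.null(b) || !nrow(b)) return(a)
  all_pos <- sort(unique(c(a$tss_position, b$tss_position)))
  data.frame(
    tss_position = all_pos,
    alleles = vapply(all_pos, function(p) {
      al <- c(unlist(strsplit(a$alleles[a$tss_position == p], ",")),
              unlist(strsplit(b$alleles[b$tss_position == p], ",")))
      paste(sort(unique(al)), collapse = ",")
    }, character(1L)))
}

#' Proportion of fixed substitutions along a fragment
#'
#' Number of fixed events (each indel counted once) divided by the number
#' of fragment positions.
#'
#' @param events event data.frame with `fixed` resolved; only
#'   `fixed = TRUE` rows are counted.
#' @param N fragment length in positions (or pass `fragment`).
#' @param fragment alternative to `N`: a [sequenced_fragment()].
#' @return list with `count`, `N`, `proportion` (unrounded) and
#'   `proportion_rounded` (3 decimals, as conventionally reported).
#' @export
substitution_proportion <- function(events, N = NULL, fragment = NULL) {
  if (is.null(N)) {
    stopifnot(!is.null(fragment))
    N <- fragment$N
  }
  stopifnot(N >= 1)
  cnt <- sum(events$fixed %in% TRUE)
  list(count = cnt, N = N, proportion = cnt / N,
       proportion_rounded = round(cnt / N, 3))
}

#' Map fixed substitutions for one fragment
#'
#' Convenience wrapper: calls differences, applies polymorphism evidence
#' and returns the table of fixed events with domains, plus the
#' substitution proportion.
#'
#' @inheritParams filter_shared_polymorphisms
#' @param fragment a [sequenced_fragment()].
#' @return list with `events` (all calls, `fixed` resolved),
#'   `fixed_events` (fixed only) and `proportion` (see
#'   [substitution_proportion()]).
#' @export
map_substitutions <- function(fragment, evidence = NULL, reads = NULL,
                              min_identity = 0.9) {
  ev <- call_differences(fragment)
  ev <- filter_shared_polymorphisms(ev, evidence = evidence, reads = reads,
                                    fragment = fragment,
                                    min_identity = min_identity)
  list(events = ev,
       fixed_events = ev[ev$fixed, , drop = FALSE],
       proportion = substitution_proportion(ev[ev$fixed, , drop = FALSE],
                                            N = fragment$N))
}
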