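# Plain-text readers/writers for the pipeline's external formats.

#' Read and write Cq record tables
#'
#' CSV with columns `gene,sample_class,replicate,reference_gene,
#' cq_reference,cq_target` (a `tissue` column is allowed and carried
#' through).
#'
#' @param path file path.
#' @return data.frame of Cq records.
#' @export
read_cq_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample_class", "replicate", "reference_gene",
            "cq_reference", "cq_target")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  out
}

#' @rdname read_cq_csv
#' @param records data.frame of Cq records.
#' @export
write_cq_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an aligned interspecies sequence pair from FASTA
#'
#' The FASTA file must hold exactly two aligned records (species a first);
#' gaps are `-`.  TSS bounds come from the arguments, or from headers of
#' the form `>name tss_start..tss_end`.
#'
#' @param path FASTA file path.
#' @param gene gene label (default: first record name).
#' @param tss_start,tss_end fragment bounds; parsed from the first header
#'   when omitted.
#' @param features optional feature data.frame (see
#'   [sequenced_fragment()]).
#' @return a [sequenced_fragment()].
#' @export
read_alignment_fasta <- function(path, gene = NULL, tss_start = NULL,
                                 tss_end = NULL, features = NULL) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    stop("expected exactly 2 aligned records in ", path)
  hdr <- names(recs)[1L]
  if (is.null(tss_start) || is.null(tss_end)) {
    m <- regmatches(hdr, regexec("(-?\\d+)\\.\\.(\\+?-?\\d+)", hdr))[[1L]]
    if (length(m) != 3L)
      stop("TSS bounds not given and not parseable from header: ", hdr)
    tss_start <- as.integer(m[2L]); tss_end <- as.integer(sub("^\\+", "", m[3L]))
  }
  if (is.null(gene)) gene <- sub("\\s.*$", "", hdr)
  sequenced_fragment(gene, tss_start, tss_end,
                     as.character(recs[[1L]]), as.character(recs[[2L]]),
                     features = features)
}

#' @rdname read_alignment_fasta
#' @param fragment a [sequenced_fragment()].
#' @param names_suffix length-2 character vector appended to the gene name
#'   in the two record headers.
#' @export
write_alignment_fasta <- function(fragment, path,
                                  names_suffix = c("species_a", "species_b")) {
  recs <- Biostrings::BStringSet(c(fragment$seq_a, fragment$seq_b))
  names(recs) <- sprintf("%s_%s %d..%+d", fragment$gene, names_suffix,
                         fragment$tss_start, fragment$tss_end)
  Biostrings::writeXStringSet(recs, path)
  invisible(path)
}

#' Read and write substitution-event tables (TSV)
#'
#' @param path file path.
#' @return data.frame with at least `gene`, `tss_position` (plus whatever
#'   further columns the file holds, e.g. `domain`, `allele_a`,
#'   `allele_b`, `fixed`).
#' @export
read_events_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "tss_position") %in% names(out)))
    stop("events TSV needs columns gene, tss_position")
  out
}

#' @rdname read_events_tsv
#' @param events event data.frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
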