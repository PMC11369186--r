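#' Construct a table of methylation reads
#'
#' The canonical in-memory representation of per-read CpG methylation calls:
#' a `data.frame` (class `methyl_reads`) with one row per sequenced fragment
#' and list-columns for the CpG offsets and states. This is the atomic unit
#' consumed by every downstream stage.
#'
#' Coordinates are 0-based; `cpg_offsets` index into `sequence` (0-based) at
#' the C of each CpG after plus-strand normalization; `cpg_states` are
#' integer 0 (unmethylated) / 1 (methylated).
#'
#' @param sample_id Character vector of sample identifiers.
#' @param chrom Character vector of chromosome labels.
#' @param start Integer vector, 0-based leftmost genomic position.
#' @param strand `"+"` or `"-"` per read (stored after normalization as `"+"`).
#' @param sequence DNA strings over `A,C,G,T,N`.
#' @param cpg_offsets List of strictly increasing integer vectors.
#' @param cpg_states List of 0/1 integer vectors, same lengths as offsets.
#' @param origin_label Optional `"tumor"`, `"normal"` or `"unknown"` ground
#'   truth (used by the simulator and parameter-recovery tests).
#' @param validate Check invariants (offsets point at CG, lengths match).
#' @return A `methyl_reads` data.frame.
#' @export
methyl_reads <- function(sample_id, chrom, start, strand, sequence,
                         cpg_offsets, cpg_states,
                         origin_label = "unknown", validate = TRUE) {
  n <- length(sequence)
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    strand = rep_len(as.character(strand), n),
    sequence = as.character(sequence),
    stringsAsFactors = FALSE
  )
  df$cpg_offsets <- lapply(cpg_offsets, as.integer)
  df$cpg_states <- lapply(cpg_states, as.integer)
  df$origin_label <- rep_len(as.character(origin_label), n)
  class(df) <- c("methyl_reads", "data.frame")
  if (validate) validate_reads(df)
  df
}

#' Validate a methyl_reads table
#'
#' Checks the per-read invariants: equal offset/state lengths, strictly
#' increasing offsets, states in \{0,1\}, and every offset pointing at a
#' `CG` dinucleotide in the read sequence.
#'
#' @param reads A `methyl_reads` data.frame.
#' @param where Optional character vector of row labels (e.g. file line
#'   numbers) used in error messages.
#' @return `reads`, invisibly, or a format error naming the first bad row.
#' @export
validate_reads <- function(reads, where = NULL) {
  if (nrow(reads) == 0L) return(invisible(reads))
  lab <- if (is.null(where)) paste("row", seq_len(nrow(reads))) else where
  if (!all(reads$strand %in% c("+", "-")))
    format_error("%s: strand must be '+' or '-'",
                 lab[which(!reads$strand %in% c("+", "-"))[1]])
  for (i in seq_len(nrow(reads))) {
    off <- reads$cpg_offsets[[i]]
    st <- reads$cpg_states[[i]]
    if (length(off) != length(st))
      format_error("%s: %d CpG offsets but %d states",
                   lab[i], length(off), length(st))
    if (length(off) == 0L) next
    if (any(diff(off) <= 0))
      format_error("%s: CpG offsets not strictly increasing", lab[i])
    if (!all(st %in% c(0L, 1L)))
      format_error("%s: CpG states must be 0/1 (U/M)", lab[i])
    seq_i <- reads$sequence[i]
    if (any(off < 0L) || any(off + 2L > nchar(seq_i)))
      format_error("%s: CpG offset outside read sequence", lab[i])
    dinuc <- substring(seq_i, off + 1L, off + 2L)
    bad <- dinuc != "CG"
    if (any(bad))
      format_error("%s: CpG offset %d is at '%s', not 'CG'",
                   lab[i], off[bad][1], dinuc[bad][1])
  }
  invisible(reads)
}

empty_reads <- function() {
  methyl_reads(character(0), character(0), integer(0), character(0),
               character(0), list(), list(), character(0), validate = FALSE)
}

rbind_reads <- function(lst) {
  lst <- lst[vapply(lst, nrow, 0L) > 0L]
  if (length(lst) == 0L) return(empty_reads())
  out <- do.call(rbind, lapply(lst, function(x) {
    class(x) <- "data.frame"
    x
  }))
  rownames(out) <- NULL
  class(out) <- c("methyl_reads", "data.frame")
  out
}
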