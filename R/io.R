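READ_TSV_COLS <- c("sample_id", "chrom", "start", "strand", "sequence",
                   "cpg_offsets", "cpg_states", "origin_label")

#' Write / read the read-record TSV
#'
#' The on-disk interchange format for per-read methylation calls: one row
#' per read with columns `sample_id, chrom, start, strand, sequence,
#' cpg_offsets, cpg_states, origin_label`. Offsets are comma-joined 0-based
#' integers; states are comma-joined `U`/`M`. Reads with no CpGs store an
#' empty field. Writing then reading is an exact round trip.
#'
#' @param reads A [methyl_reads()] table.
#' @param path File path.
#' @return `read_read_records()` returns a validated [methyl_reads()] table;
#'   minus-strand rows are normalized to the plus strand at ingest
#'   (sequence reverse-complemented, offsets remapped).
#' @export
write_read_records <- function(reads, path) {
  out <- data.frame(
    sample_id = reads$sample_id, chrom = reads$chrom, start = reads$start,
    strand = reads$strand, sequence = reads$sequence,
    cpg_offsets = join_ints(reads$cpg_offsets),
    cpg_states = join_states(reads$cpg_states),
    origin_label = reads$origin_label, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_records
#' @export
read_read_records <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "",
                    na.strings = NULL)
  missing_cols <- setdiff(READ_TSV_COLS, names(tab))
  if (length(missing_cols))
    format_error("read-record file missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) return(empty_reads())
  reads <- methyl_reads(
    sample_id = tab$sample_id, chrom = tab$chrom,
    start = as.integer(tab$start), strand = tab$strand,
    sequence = tab$sequence,
    cpg_offsets = split_ints(tab$cpg_offsets),
    cpg_states = split_states(tab$cpg_states),
    origin_label = tab$origin_label, validate = FALSE
  )
  reads <- normalize_strand(reads)
  # +1: header line occupies line 1 of the file
  validate_reads(reads, where = paste("line", seq_len(nrow(reads)) + 1L))
  reads
}

# Map minus-strand reads onto the plus strand: reverse-complement the
# sequence and reflect each CpG offset onto the plus-strand C. On the minus
# strand the read's "CG" at offset o corresponds to plus-strand offset
# len - 2 - o after reverse complementing.
normalize_strand <- function(reads) {
  neg <- which(reads$strand == "-")
  if (length(neg) == 0L) return(reads)
  for (i in neg) {
    len <- nchar(reads$sequence[i])
    reads$sequence[i] <- revcomp(reads$sequence[i])
    o <- reads$cpg_offsets[[i]]
    reads$cpg_offsets[[i]] <- rev(len - 2L - o)
    reads$cpg_states[[i]] <- rev(reads$cpg_states[[i]])
    reads$strand[i] <- "+"
  }
  reads
}

#' Read / write BED region files
#'
#' Standard 3+ column BED, 0-based half-open. An optional 4th column becomes
#' the region id (otherwise ids `region_1..n` are assigned); further columns
#' are preserved on write for DMR calls (see [write_dmr_bed()]).
#'
#' @param path File path.
#' @param regions Data frame with chrom, start, end, id.
#' @return `read_bed()` returns a data.frame (chrom, start, end, id).
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 3L)
    format_error("BED file must have at least 3 columns, found %d", ncol(tab))
  start <- suppressWarnings(as.integer(tab[[2]]))
  end <- suppressWarnings(as.integer(tab[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    format_error("line %d: non-integer BED coordinates", bad[1])
  bad <- which(start >= end)
  if (length(bad))
    format_error("line %d: start (%d) must be < end (%d)",
                 bad[1], start[bad[1]], end[bad[1]])
  data.frame(
    chrom = tab[[1]], start = start, end = end,
    id = if (ncol(tab) >= 4L) tab[[4]] else paste0("region_", seq_len(nrow(tab))),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  out <- data.frame(regions$chrom, regions$start, regions$end, regions$id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write region FASTA
#'
#' @param fasta Named character vector of sequences.
#' @param path File path.
#' @export
write_fasta <- function(fasta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(fasta)) {
    writeLines(paste0(">", nm), con)
    writeLines(fasta[[nm]], con)
  }
  invisible(path)
}

#' Read a Bismark-style CpG report
#'
#' Expects a cytosine/CpG report TSV with columns chrom, position (1-based),
#' strand, methylated count, unmethylated count (extra columns such as
#' context are ignored). Minus-strand records are collapsed onto the
#' plus-strand C of the CpG (position - 1) with counts summed.
#'
#' @param path File path.
#' @return Data frame (chrom, pos, meth, unmeth) with `pos` the 0-based
#'   plus-strand position of the C, unique per chromosome.
#' @export
read_cpg_report <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 5L)
    format_error("CpG report needs >= 5 columns (chrom, pos, strand, meth, unmeth), found %d",
                 ncol(tab))
  meth <- suppressWarnings(as.numeric(tab[[4]]))
  unmeth <- suppressWarnings(as.numeric(tab[[5]]))
  bad <- which(is.na(meth) | is.na(unmeth) | meth < 0 | unmeth < 0 |
                 meth != floor(meth) | unmeth != floor(unmeth))
  if (length(bad))
    format_error("line %d: counts must be non-negative integers", bad[1])
  if (!all(tab[[3]] %in% c("+", "-")))
    format_error("line %d: strand must be '+' or '-'",
                 which(!tab[[3]] %in% c("+", "-"))[1])
  pos1 <- as.integer(tab[[2]])
  # 1-based report -> 0-based; minus strand G collapses to the C one bp left
  pos0 <- ifelse(tab[[3]] == "+", pos1 - 1L, pos1 - 2L)
  agg <- aggregate(cbind(meth, unmeth) ~ chrom + pos,
                   data = data.frame(chrom = tab[[1]], pos = pos0,
                                     meth = meth, unmeth = unmeth),
                   FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  agg$meth <- as.integer(agg$meth)
  agg$unmeth <- as.integer(agg$unmeth)
  agg
}

#' Read / write a sample manifest
#'
#' TSV with columns `sample_id`, `group` (tumor_tissue, normal_tissue,
#' pca_urine, noncancer_urine), optional `grade` (HGS / LGS / none; HGS is
#' Gleason >= 4+3), optional `reads_path`, plus any numeric biomarker
#' columns.
#'
#' @param path File path.
#' @param manifest Data frame to write.
#' @return `read_manifest()` returns the validated data.frame.
#' @export
read_manifest <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
  validate_manifest(tab)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  if (!"sample_id" %in% names(manifest))
    format_error("manifest missing sample_id column")
  dup <- duplicated(manifest$sample_id)
  if (any(dup))
    format_error("duplicate sample_id '%s'", manifest$sample_id[dup][1])
  groups_ok <- c("tumor_tissue", "normal_tissue", "pca_urine",
                 "noncancer_urine")
  if ("group" %in% names(manifest)) {
    bad <- !manifest$group %in% groups_ok
    if (any(bad))
      format_error("unknown group '%s' (expected one of %s)",
                   manifest$group[bad][1], paste(groups_ok, collapse = ", "))
  }
  if ("grade" %in% names(manifest)) {
    bad <- !manifest$grade %in% c("HGS", "LGS", "none")
    if (any(bad))
      format_error("unknown grade '%s'", manifest$grade[bad][1])
  }
  manifest
}

#' Assign reads to regions
#'
#' A read belongs to a region iff at least one of its CpG positions (the C
#' of the CpG, 0-based) falls inside the region's half-open interval. A read
#' whose CpGs span two regions is assigned to each. Regions must be
#' non-overlapping; overlapping inputs are an error (merge them first).
#'
#' @param reads A [methyl_reads()] table.
#' @param regions Data frame with chrom, start, end, id.
#' @return Named list: region id -> integer vector of row indices into
#'   `reads`.
#' @export
assign_reads_to_regions <- function(reads, regions) {
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  if (length(gr) > 1L) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0L)
      param_error("regions overlap (e.g. '%s' and '%s'); merge first",
                  regions$id[S4Vectors::queryHits(hits)[1]],
                  regions$id[S4Vectors::subjectHits(hits)[1]])
  }
  out <- setNames(vector("list", nrow(regions)), regions$id)
  for (i in seq_along(out)) out[[i]] <- integer(0)
  if (nrow(reads) == 0L) return(out)
  n_cpg <- lengths(reads$cpg_offsets)
  if (all(n_cpg == 0L)) return(out)
  upos <- rep(reads$start, n_cpg) +
    unlist(reads$cpg_offsets, use.names = FALSE)
  cpg_gr <- GenomicRanges::GRanges(
    rep(reads$chrom, n_cpg),
    IRanges::IRanges(start = upos + 1L, width = 1L)
  )
  read_idx <- rep(seq_len(nrow(reads)), n_cpg)
  # suppress the benign seqlevel warning when reads and regions share no
  # chromosome at all (a legal no-overlap query)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(cpg_gr, gr))
  if (length(hits) == 0L) return(out)
  region_h <- S4Vectors::subjectHits(hits)
  read_h <- read_idx[S4Vectors::queryHits(hits)]
  keep_h <- !duplicated(region_h * (nrow(reads) + 1) + read_h)
  by_region <- split(read_h[keep_h],
                     factor(region_h[keep_h], levels = seq_len(nrow(regions))))
  out <- lapply(by_region, sort)
  names(out) <- regions$id
  out
}

#' Read aligned reads from a Bismark-style BAM/SAM file
#'
#' Optional ingest path: parses the Bismark `XM` methylation-call tag
#' (`z`/`Z` = un/methylated CpG) into the same [methyl_reads()] contract as
#' the TSV reader. Requires the `Rsamtools` package. The TSV path is the
#' reference implementation.
#'
#' @param path BAM (or SAM via `asBam`) file path.
#' @param sample_id Sample id to stamp on reads.
#' @param min_mapq Minimum mapping quality; no filtering by default.
#' @return A [methyl_reads()] table.
#' @export
read_bismark_bam <- function(path, sample_id = "bam", min_mapq = 0L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    config_error("read_bismark_bam requires the Rsamtools package")
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "seq", "mapq"),
    tag = "XM"
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- which(!is.na(b$pos) & (is.na(b$mapq) | b$mapq >= min_mapq))
  seqs <- as.character(b$seq)[keep]
  xm <- b$tag$XM[keep]
  strand <- as.character(b$strand)[keep]
  offs <- vector("list", length(keep))
  states <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    calls <- strsplit(xm[i], "", fixed = TRUE)[[1]]
    at <- which(calls %in% c("z", "Z"))
    st <- as.integer(calls[at] == "Z")
    o <- at - 1L
    # BAM sequences and XM tags are reference-oriented already; a
    # minus-strand bisulfite call sits on the G of the CpG, so shift to the
    # plus-strand C. Calls shifted off the read are dropped.
    if (strand[i] == "-") {
      o <- o - 1L
      st <- st[o >= 0L]
      o <- o[o >= 0L]
    }
    inb <- o + 2L <= nchar(seqs[i])
    o <- o[inb]; st <- st[inb]
    # restore the genomic CG under each call (bisulfite conversion turns
    # unmethylated C into T in the stored read sequence)
    for (j in seq_along(o)) substr(seqs[i], o[j] + 1L, o[j] + 2L) <- "CG"
    offs[[i]] <- o
    states[[i]] <- st
  }
  reads <- methyl_reads(
    sample_id = sample_id, chrom = as.character(b$rname)[keep],
    start = b$pos[keep] - 1L, strand = "+",
    sequence = seqs, cpg_offsets = offs, cpg_states = states,
    validate = FALSE
  )
  validate_reads(reads)
  reads
}
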