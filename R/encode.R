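#' Encode a read as a joint sequence + methylation matrix
#'
#' Produces the fixed-length numeric view the classifier consumes: an
#' `L x 5` matrix whose first four columns one-hot encode the base at each
#' position (A, C, G, T; N = all zeros) and whose fifth column carries the
#' methylation channel: +1 at the C of a methylated CpG, -1 at the C of an
#' unmethylated CpG, 0 elsewhere. Reads longer than `L` are trimmed from
#' the 3' end; shorter reads are zero-padded on the right; CpG offsets
#' falling outside the window are dropped.
#'
#' @param sequence DNA string.
#' @param cpg_offsets 0-based offsets of CpG Cs in `sequence`.
#' @param cpg_states 0/1 states matching `cpg_offsets`.
#' @param L Window length (default 66).
#' @return `L x 5` numeric matrix.
#' @export
encode_read <- function(sequence, cpg_offsets, cpg_states, L = 66L) {
  if (!is_count(L) || L < 1L) param_error("L must be a positive integer")
  m <- matrix(0, nrow = L, ncol = 5L)
  n <- min(nchar(sequence), L)
  if (n > 0L) {
    bases <- strsplit(substr(sequence, 1L, n), "", fixed = TRUE)[[1]]
    col <- match(bases, c("A", "C", "G", "T"))
    ok <- which(!is.na(col))
    m[cbind(ok, col[ok])] <- 1
  }
  keep <- cpg_offsets + 1L <= L   # the C itself must be inside the window
  if (any(keep))
    m[cpg_offsets[keep] + 1L, 5L] <-
      ifelse(cpg_states[keep] == 1L, 1, -1)
  m
}

#' Decode the sequence portion of an encoded read
#'
#' Inverse of the sequence channel of [encode_read()] over non-padded
#' positions (all-zero rows decode to `N`, trailing all-zero rows are
#' padding and dropped).
#'
#' @param m `L x 5` matrix from [encode_read()].
#' @return DNA string.
#' @export
decode_read <- function(m) {
  onehot <- m[, 1:4, drop = FALSE]
  filled <- rowSums(onehot != 0) > 0
  last <- if (any(filled)) max(which(filled)) else 0L
  if (last == 0L) return("")
  bases <- rep("N", last)
  idx <- apply(onehot[seq_len(last), , drop = FALSE], 1L, function(r) {
    w <- which(r == 1)
    if (length(w) == 1L) w else NA_integer_
  })
  bases[!is.na(idx)] <- c("A", "C", "G", "T")[idx[!is.na(idx)]]
  paste(bases, collapse = "")
}

# Encode many reads into an n x (L*5) matrix, position-major layout:
# element (pos, channel) of read i sits at column (pos-1)*5 + channel.
# This layout keeps each convolution window contiguous. Vectorized
# equivalent of stacking encode_read() over rows (property-tested).
encode_reads_matrix <- function(reads, L = 66L) {
  n <- nrow(reads)
  x <- matrix(0, n, L * 5L)
  if (n == 0L) return(x)
  padded <- vapply(reads$sequence, function(s) {
    if (nchar(s) >= L) substr(s, 1L, L)
    else paste0(s, strrep("N", L - nchar(s)))
  }, "", USE.NAMES = FALSE)
  chars <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
                  n, L, byrow = TRUE)
  col <- match(chars, c("A", "C", "G", "T"))       # n*L vector, col-major
  hit <- which(!is.na(col))
  ri <- ((hit - 1L) %% n) + 1L
  pos <- ((hit - 1L) %/% n) + 1L
  x[cbind(ri, (pos - 1L) * 5L + col[hit])] <- 1
  n_off <- lengths(reads$cpg_offsets)
  if (sum(n_off) > 0L) {
    ri <- rep(seq_len(n), n_off)
    off <- unlist(reads$cpg_offsets, use.names = FALSE)
    st <- unlist(reads$cpg_states, use.names = FALSE)
    keep <- off + 1L <= L
    x[cbind(ri[keep], off[keep] * 5L + 5L)] <- ifelse(st[keep] == 1L, 1, -1)
  }
  x
}

#' Build a labeled training set of encoded reads
#'
#' Positives are reads from `positive_group` samples inside the selected
#' regions whose alpha value lies on the region's aberrant side (hypo
#' regions: alpha <= `alpha_lo`; hyper regions: alpha >= `alpha_hi`) — not
#' every tumor-sample read carries the tumor pattern, so the signal lives
#' in the aberrant read subpopulation. Negatives are all alpha-qualifying
#' reads from `negative_groups` samples in the same regions. Classes are
#' balanced by downsampling the majority class under `seed`.
#'
#' @param reads A [methyl_reads()] table.
#' @param selected_regions Output of [select_top_n()] (needs `direction`).
#' @param manifest Manifest data.frame.
#' @param positive_group Group supplying positive (tumor-pattern) reads.
#' @param negative_groups Character vector of background groups.
#' @param alpha_lo,alpha_hi Read-level cutoffs (as in
#'   [region_statistics()]).
#' @param min_cpgs Minimum CpGs per read.
#' @param L Encoding window length.
#' @param seed Seed for the balancing downsample.
#' @return List: `x` (n x (L*5) matrix), `y` (0/1 labels), `L`, `meta`
#'   (read provenance), and `counts` (pre-balance class sizes).
#' @export
build_training_set <- function(reads, selected_regions, manifest,
                               positive_group,
                               negative_groups,
                               alpha_lo = 0.2, alpha_hi = 0.8,
                               min_cpgs = 3L, L = 66L, seed = 1L) {
  pos_ids <- samples_in_group(manifest, positive_group)
  neg_ids <- unique(unlist(lapply(negative_groups, samples_in_group,
                                  manifest = manifest)))
  assignment <- assign_reads_to_regions(reads, selected_regions)
  a <- compute_alpha(reads, min_cpgs)
  alpha_all <- rep(NA_real_, nrow(reads))
  alpha_all[a$read] <- a$alpha

  pos_idx <- integer(0)
  neg_idx <- integer(0)
  for (r in seq_along(assignment)) {
    idx <- assignment[[r]]
    idx <- idx[!is.na(alpha_all[idx])]
    if (length(idx) == 0L) next
    dir_r <- selected_regions$direction[
      selected_regions$id == names(assignment)[r]][1]
    aberrant <- if (identical(dir_r, "hyper"))
      alpha_all[idx] >= alpha_hi else alpha_all[idx] <= alpha_lo
    pos_idx <- c(pos_idx, idx[reads$sample_id[idx] %in% pos_ids & aberrant])
    neg_idx <- c(neg_idx, idx[reads$sample_id[idx] %in% neg_ids])
  }
  counts <- c(positive = length(pos_idx), negative = length(neg_idx))
  if (length(pos_idx) == 0L)
    config_error("no qualifying positive reads for group '%s'",
                 positive_group)
  if (length(neg_idx) == 0L)
    config_error("no qualifying negative reads for groups: %s",
                 paste(negative_groups, collapse = ", "))
  set.seed(seed)
  n_bal <- min(length(pos_idx), length(neg_idx))
  if (length(pos_idx) > n_bal)
    pos_idx <- sort(sample(pos_idx, n_bal))
  if (length(neg_idx) > n_bal)
    neg_idx <- sort(sample(neg_idx, n_bal))
  all_idx <- c(pos_idx, neg_idx)
  y <- c(rep(1L, length(pos_idx)), rep(0L, length(neg_idx)))
  list(
    x = encode_reads_matrix(reads[all_idx, , drop = FALSE], L),
    y = y, L = as.integer(L),
    meta = data.frame(read = all_idx,
                      sample_id = reads$sample_id[all_idx],
                      origin_label = reads$origin_label[all_idx],
                      label = y),
    counts = counts
  )
}
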