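#' Train the per-read tumor classifier
#'
#' Fits the convolutional read classifier (see [model_spec()]) by minibatch
#' Adam on binary cross-entropy, with a stratified held-out read split used
#' only for the training log. Deterministic under `spec$seed` in a single
#' R process.
#'
#' @param x Encoded read matrix from [build_training_set()].
#' @param y 0/1 labels.
#' @param spec A [model_spec()].
#' @param regions Optional region data.frame; its checksum is stored so a
#'   score-time region mismatch is detectable.
#' @return A `read_model` list: `params`, `spec`, `log` (per-epoch
#'   data.frame: epoch, train_loss, val_loss, val_auc), `val_auc`,
#'   `region_checksum`.
#' @export
train_read_classifier <- function(x, y, spec = model_spec(),
                                  regions = NULL) {
  if (length(unique(y)) < 2L)
    config_error("training set must contain both classes")
  if (ncol(x) != spec$L * 5L)
    param_error("x has %d columns; expected L*5 = %d", ncol(x), spec$L * 5L)
  set.seed(spec$seed)
  n <- nrow(x)
  # stratified held-out split
  val_idx <- unlist(lapply(c(0L, 1L), function(cl) {
    ids <- which(y == cl)
    sample(ids, max(1L, round(spec$val_fraction * length(ids))))
  }))
  tr_idx <- setdiff(seq_len(n), val_idx)
  xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]

  params <- nn_init(spec)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  set.seed(derive_seed(spec$seed, "train"))
  log <- vector("list", spec$epochs)
  t_step <- 0L
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(nrow(xt))
    losses <- c()
    for (i0 in seq(1L, nrow(xt), by = spec$batch_size)) {
      i1 <- min(i0 + spec$batch_size - 1L, nrow(xt))
      bi <- ord[i0:i1]
      fwd <- nn_forward(params, xt[bi, , drop = FALSE], spec, train = TRUE)
      loss <- bce_loss(fwd$phat, yt[bi])
      if (!is.finite(loss))
        rml_stop("rml_train_error",
                 "non-finite training loss at epoch %d (lr too high?)", ep)
      losses <- c(losses, loss)
      grads <- nn_backward(params, fwd$cache, fwd$phat, yt[bi], spec)
      t_step <- t_step + 1L
      upd <- nn_adam_step(params, grads, state, spec$lr, t_step)
      params <- upd$params
      state <- upd$state
    }
    pv <- nn_predict(params, xv, spec)
    log[[ep]] <- data.frame(
      epoch = ep, train_loss = mean(losses), val_loss = bce_loss(pv, yv),
      val_auc = mw_auc(pv[yv == 1L], pv[yv == 0L])
    )
  }
  log <- do.call(rbind, log)
  structure(list(
    params = params, spec = spec, log = log,
    val_auc = log$val_auc[nrow(log)],
    region_checksum = if (is.null(regions)) NA_character_
                      else region_checksum(regions)
  ), class = "read_model")
}

#' Score reads with a trained classifier
#'
#' One probability-of-tumor-origin score per qualifying read: the read must
#' be assigned to a selected region and cover at least `min_cpgs` CpGs.
#' Reads failing either filter are counted, never silently dropped.
#'
#' @param model A `read_model` from [train_read_classifier()].
#' @param reads A [methyl_reads()] table.
#' @param selected_regions Region data.frame the model was trained on.
#' @param min_cpgs Minimum CpGs per read.
#' @return Data frame (read, sample_id, origin_label, d) with attributes
#'   `skipped` (named counts) and, when empty, `reason`
#'   (`"no_informative_reads"`).
#' @export
score_reads <- function(model, reads, selected_regions, min_cpgs = 3L) {
  stopifnot(inherits(model, "read_model"))
  if (!is.na(model$region_checksum) &&
      model$region_checksum != region_checksum(selected_regions))
    config_error("region set does not match the one the model was trained on")
  assignment <- assign_reads_to_regions(reads, selected_regions)
  in_region <- sort(unique(unlist(assignment)))
  enough_cpg <- lengths(reads$cpg_states) >= min_cpgs
  qual <- in_region[enough_cpg[in_region]]
  skipped <- c(
    not_in_region = nrow(reads) - length(in_region),
    too_few_cpgs = length(in_region) - length(qual)
  )
  if (length(qual) == 0L) {
    out <- data.frame(read = integer(0), sample_id = character(0),
                      origin_label = character(0), d = numeric(0))
    attr(out, "skipped") <- skipped
    attr(out, "reason") <- "no_informative_reads"
    return(out)
  }
  # encode + predict in chunks to bound memory on large read sets
  d <- numeric(length(qual))
  chunk <- 20000L
  for (i0 in seq(1L, length(qual), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(qual))
    x <- encode_reads_matrix(reads[qual[i0:i1], , drop = FALSE],
                             model$spec$L)
    d[i0:i1] <- nn_predict(model$params, x, model$spec)
  }
  out <- data.frame(
    read = qual, sample_id = reads$sample_id[qual],
    origin_label = reads$origin_label[qual],
    d = d
  )
  attr(out, "skipped") <- skipped
  out
}

# Deterministic checksum of a region set (polynomial rolling hash over the
# coordinate/id strings).
region_checksum <- function(regions) {
  s <- paste(regions$chrom, regions$start, regions$end, regions$id,
             sep = ":", collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%d", as.integer(h))
}

#' Save / load a trained model
#'
#' The artifact is a directory of plain-text JSON: `weights.json` (full
#' precision), `spec.json`, and `meta.json` (region checksum, training
#' log), so artifacts survive text-only storage and diffs.
#'
#' @param model A `read_model`.
#' @param dir Artifact directory (created if absent).
#' @return `load_model()` returns the `read_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(lapply(model$params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = length(p), data = as.numeric(p))
  }), file.path(dir, "weights.json"), digits = NA, auto_unbox = FALSE)
  jsonlite::write_json(model$spec, file.path(dir, "spec.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(list(region_checksum = model$region_checksum,
                            val_auc = model$val_auc),
                       file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  write.table(model$log, file.path(dir, "training_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = TRUE)
  params <- lapply(w, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else if (identical(as.integer(p$dim), 1L)) p$data[1]
    else p$data
  })
  spec_l <- jsonlite::read_json(file.path(dir, "spec.json"),
                                simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  log <- read.table(file.path(dir, "training_log.tsv"), sep = "\t",
                    header = TRUE)
  structure(list(
    params = params, spec = do.call(model_spec, spec_l), log = log,
    val_auc = meta$val_auc,
    region_checksum = if (is.null(meta$region_checksum)) NA_character_
                      else meta$region_checksum
  ), class = "read_model")
}
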