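#' Simulation configuration
#'
#' Defaults describe the regime the package targets: a few hundred candidate
#' regions of a couple hundred bp each, urine-like mixtures whose tumor-read
#' fraction spans 0 to 0.3, and per-region coverage equivalents from 0.3X to
#' 30X. All downstream behaviour is a deterministic function of `seed`.
#'
#' @param n_regions Number of candidate regions.
#' @param region_length Region length in bp.
#' @param cpgs_per_region CpGs embedded per region.
#' @param read_length Read length in bp.
#' @param reads_per_region_per_X Reads per region at a 1X coverage
#'   equivalent (region_length / read_length, rounded up, by default).
#' @param p_meth_tumor,p_meth_normal Mean per-read methylation level of
#'   tumor / normal reads in *planted* (differential) regions. Defaults 0.1
#'   vs 0.9 give a strongly hypomethylated tumor signal.
#' @param p_meth_background Methylation level shared by both origins in
#'   non-planted regions.
#' @param frac_planted Fraction of regions carrying the tumor signal.
#' @param concordance_kappa Beta concentration controlling within-read
#'   methylation concordance (larger = more concordant reads).
#' @param flip_rate Uniform probability of reading an unmethylated CpG as
#'   methylated (bisulfite non-conversion stand-in). Default 0.
#' @param motif Optional DNA string embedded in tumor-derived reads so the
#'   sequence channel carries learnable signal; `NULL` (off) by default.
#' @param theta_grid Tumor fractions for simulated urine mixtures.
#' @param depth_X Coverage equivalent for urine samples.
#' @param seed Master seed; fixes the full output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 200L, region_length = 240L,
                       cpgs_per_region = 16L, read_length = 80L,
                       reads_per_region_per_X =
                         ceiling(region_length / read_length),
                       p_meth_tumor = 0.1, p_meth_normal = 0.9,
                       p_meth_background = 0.9, frac_planted = 0.5,
                       concordance_kappa = 5, flip_rate = 0,
                       motif = NULL,
                       theta_grid = c(0, 0.02, 0.05, 0.1, 0.2, 0.3),
                       depth_X = 3, seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    region_length = as.integer(region_length),
    cpgs_per_region = as.integer(cpgs_per_region),
    read_length = as.integer(read_length),
    reads_per_region_per_X = as.integer(reads_per_region_per_X),
    p_meth_tumor = p_meth_tumor, p_meth_normal = p_meth_normal,
    p_meth_background = p_meth_background, frac_planted = frac_planted,
    concordance_kappa = concordance_kappa, flip_rate = flip_rate,
    motif = motif, theta_grid = theta_grid, depth_X = depth_X,
    seed = as.integer(seed)
  )
  for (k in c("n_regions", "region_length", "cpgs_per_region",
              "read_length", "reads_per_region_per_X"))
    if (!is_count(cfg[[k]]) || cfg[[k]] < 1L)
      param_error("%s must be a positive count", k)
  for (k in c("p_meth_tumor", "p_meth_normal", "p_meth_background",
              "frac_planted", "flip_rate"))
    if (!is_prob(cfg[[k]])) param_error("%s must be in [0,1]", k)
  if (!is.numeric(cfg$concordance_kappa) || cfg$concordance_kappa <= 0)
    param_error("concordance_kappa must be > 0")
  if (any(cfg$theta_grid < 0 | cfg$theta_grid > 1))
    param_error("theta_grid values must be in [0,1]")
  # Each CG needs 2 bp and CpGs are planted at least 2 bp apart.
  if (cfg$region_length < 3L * cfg$cpgs_per_region + 2L)
    param_error("region_length %d too small to host %d CpGs",
                cfg$region_length, cfg$cpgs_per_region)
  class(cfg) <- "sim_config"
  cfg
}

# One region's sequence: CG exactly at the planted offsets, nowhere else.
# Sampling left to right and forbidding G after a C guarantees no stray CG.
sim_region_sequence <- function(region_length, offsets) {
  is_c <- logical(region_length)
  is_g <- logical(region_length)
  is_c[offsets + 1L] <- TRUE
  is_g[offsets + 2L] <- TRUE
  chars <- character(region_length)
  prev <- ""
  for (i in seq_len(region_length)) {
    if (is_c[i]) {
      chars[i] <- "C"
    } else if (is_g[i]) {
      chars[i] <- "G"
    } else {
      pool <- if (prev == "C") c("A", "C", "T") else c("A", "C", "G", "T")
      chars[i] <- pool[sample.int(length(pool), 1L)]
    }
    prev <- chars[i]
  }
  paste(chars, collapse = "")
}

#' Simulate reference regions
#'
#' Draws `n_regions` candidate regions on a synthetic chromosome, each with
#' `cpgs_per_region` CpG sites at recorded offsets and group-specific
#' methylation probabilities. A `frac_planted` subset of regions carries the
#' tumor/normal methylation difference; the rest share the background level
#' (so DMR calling has both true positives and true negatives to find).
#'
#' @param config A [sim_config()].
#' @return A list with `regions` (data.frame: chrom, start, end, id,
#'   planted, p_meth_tumor, p_meth_normal, concordance_kappa, and
#'   list-columns cpg_offsets, sequence), and `fasta` (named character
#'   vector of region sequences, writable with [write_fasta()]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "reference"))
  n <- config$n_regions
  gap <- 500L
  starts <- cumsum(rep(config$region_length + gap, n)) - config$region_length
  n_planted <- round(config$frac_planted * n)
  planted <- seq_len(n) <= n_planted   # deterministic: first block planted
  ids <- sprintf("region_%04d", seq_len(n))
  offs <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    # offsets spaced >= 3 apart so CG blocks never touch
    slots <- floor((config$region_length - 2L) / 3L)
    pick <- sort(sample.int(slots, config$cpgs_per_region))
    offs[[i]] <- as.integer((pick - 1L) * 3L + sample.int(2L, 1L) - 1L)
    seqs[i] <- sim_region_sequence(config$region_length, offs[[i]])
  }
  regions <- data.frame(
    chrom = "chrSim", start = as.integer(starts),
    end = as.integer(starts + config$region_length),
    id = ids, planted = planted,
    p_meth_tumor = ifelse(planted, config$p_meth_tumor,
                          config$p_meth_background),
    p_meth_normal = ifelse(planted, config$p_meth_normal,
                           config$p_meth_background),
    concordance_kappa = config$concordance_kappa,
    stringsAsFactors = FALSE
  )
  regions$cpg_offsets <- offs
  regions$sequence <- seqs
  regions$motif <- if (is.null(config$motif)) NA_character_ else config$motif
  list(regions = regions, fasta = setNames(seqs, ids))
}

#' Simulate bisulfite reads from one region
#'
#' Reads are placed uniformly within the region. Each read draws a latent
#' methylation level `mu ~ Beta(p*kappa, (1-p)*kappa)` with `p` the origin's
#' methylation probability and `kappa` the concordance concentration; each
#' covered CpG is then methylated independently `Bernoulli(mu)`. This is the
#' simplest generative model with the pervasiveness property that methylation
#' states tend to agree along a read.
#'
#' @param region One row of the `regions` data.frame from
#'   [simulate_reference()] (or a list with the same fields).
#' @param n_reads Number of reads to draw.
#' @param origin `"tumor"` or `"normal"`; recorded as ground truth.
#' @param seed Integer seed.
#' @param read_length Read length in bp (clipped to the region length).
#' @param sample_id Sample identifier stamped on the reads.
#' @param flip_rate Probability an unmethylated call is flipped to
#'   methylated (non-conversion); default 0.
#' @return A [methyl_reads()] table with `n_reads` rows.
#' @export
simulate_reads <- function(region, n_reads, origin = c("tumor", "normal"),
                           seed = 1L, read_length = 80L,
                           sample_id = "sim", flip_rate = 0) {
  origin <- match.arg(origin)
  if (!is_count(n_reads)) param_error("n_reads must be a non-negative count")
  if (n_reads == 0L) return(empty_reads())
  set.seed(seed)
  p <- if (origin == "tumor") region$p_meth_tumor else region$p_meth_normal
  kappa <- region$concordance_kappa
  rl <- min(as.integer(read_length), region$end - region$start)
  offs_region <- region$cpg_offsets
  if (is.list(offs_region)) offs_region <- offs_region[[1]]
  seq_region <- region$sequence
  motif <- region$motif
  if (is.list(motif)) motif <- motif[[1]]
  has_motif <- origin == "tumor" && !is.na(motif) && nzchar(motif)

  max_off <- region$end - region$start - rl
  rel_starts <- if (max_off > 0) sample.int(max_off + 1L, n_reads,
                                            replace = TRUE) - 1L
               else integer(n_reads)
  mu <- if (p <= 0) rep(0, n_reads)
        else if (p >= 1) rep(1, n_reads)
        else rbeta(n_reads, p * kappa, (1 - p) * kappa)

  seqs <- substring(seq_region, rel_starts + 1L, rel_starts + rl)
  offs <- vector("list", n_reads)
  states <- vector("list", n_reads)
  for (j in seq_len(n_reads)) {
    keep <- offs_region >= rel_starts[j] &
      offs_region + 2L <= rel_starts[j] + rl
    o <- offs_region[keep] - rel_starts[j]
    s <- if (length(o)) rbinom(length(o), 1L, mu[j]) else integer(0)
    if (flip_rate > 0 && length(s))
      s <- as.integer(s | (rbinom(length(s), 1L, flip_rate) == 1L &
                             s == 0L))
    if (has_motif) {
      # embed at the first placement clear of every recorded CpG block
      m <- nchar(motif)
      spots <- setdiff(seq_len(rl - m + 1L) - 1L, integer(0))
      blocked <- unlist(lapply(o, function(x) seq(x - m + 1L, x + 1L)))
      spots <- spots[!spots %in% blocked]
      if (length(spots)) {
        at <- spots[1]
        substr(seqs[j], at + 1L, at + m) <- motif
      }
    }
    offs[[j]] <- o
    states[[j]] <- as.integer(s)
  }
  methyl_reads(
    sample_id = sample_id, chrom = region$chrom,
    start = region$start + rel_starts, strand = "+",
    sequence = seqs, cpg_offsets = offs, cpg_states = states,
    origin_label = origin, validate = FALSE
  )
}

#' Simulate a urine-like mixture sample
#'
#' Each read is independently tumor-origin with probability `theta`, else
#' normal-origin; reads are spread uniformly over the regions. The true
#' `theta` is returned so parameter recovery can be tested.
#'
#' @param regions `regions` data.frame from [simulate_reference()].
#' @param theta Tumor-read fraction in \[0,1\].
#' @param depth_X Coverage equivalent; total reads is
#'   `round(depth_X * reads_per_region_per_X * n_regions)`.
#' @param config The [sim_config()] (for read length, coverage constant,
#'   flip rate).
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return List with `reads` (a [methyl_reads()] table, origin labels kept)
#'   and `theta` (the ground truth).
#' @export
simulate_urine_sample <- function(regions, theta, depth_X = 3, config,
                                  seed = 1L, sample_id = "urine") {
  if (!is_prob(theta)) param_error("theta must be in [0,1], got %s",
                                   format(theta))
  set.seed(seed)
  n_total <- round(depth_X * config$reads_per_region_per_X *
                     nrow(regions))
  if (n_total == 0L) return(list(reads = empty_reads(), theta = theta))
  region_of <- sample.int(nrow(regions), n_total, replace = TRUE)
  is_tumor <- runif(n_total) < theta
  parts <- list()
  for (i in sort(unique(region_of))) {
    for (org in c("tumor", "normal")) {
      k <- sum(region_of == i & (is_tumor == (org == "tumor")))
      if (k == 0L) next
      parts[[length(parts) + 1L]] <- simulate_reads(
        regions[i, ], k, org,
        seed = derive_seed(seed, paste0("r", i, org)),
        read_length = config$read_length, sample_id = sample_id,
        flip_rate = config$flip_rate
      )
    }
  }
  list(reads = rbind_reads(parts), theta = theta)
}

#' Simulate a full cohort
#'
#' Builds reference regions plus tissue samples (pure tumor / pure normal
#' reads) and urine samples (mixtures over `theta_grid`), with a manifest.
#' Tissue samples use `depth_X` coverage of pure-origin reads; PCa urine
#' samples cycle through the positive thetas in the grid, noncancer urine
#' uses theta = 0.
#'
#' @param config A [sim_config()].
#' @param n_tumor_tissue,n_normal_tissue,n_pca_urine,n_noncancer_urine
#'   Cohort sizes; defaults follow a training cohort of 25 tissue pairs and
#'   40 + 40 urine samples.
#' @param sample_prefix Prefix for sample ids (so independent cohorts get
#'   distinct ids).
#' @return List with `regions`, `fasta`, `reads` (all samples, one table),
#'   `manifest` (sample_id, group, grade, theta), and `truth` (named theta
#'   vector for urine samples).
#' @export
simulate_cohort <- function(config,
                            n_tumor_tissue = 25L, n_normal_tissue = 25L,
                            n_pca_urine = 40L, n_noncancer_urine = 40L,
                            sample_prefix = "train") {
  ref <- simulate_reference(config)
  regions <- ref$regions
  reads <- list()
  manifest <- list()
  truth <- numeric(0)
  add_sample <- function(id, group, theta, origin = NULL) {
    sd <- derive_seed(config$seed, paste0(sample_prefix, id))
    if (is.null(origin)) {
      sim <- simulate_urine_sample(regions, theta, config$depth_X, config,
                                   seed = sd, sample_id = id)
      reads[[id]] <<- sim$reads
      truth[id] <<- theta
    } else {
      parts <- lapply(seq_len(nrow(regions)), function(i) {
        n_i <- round(config$depth_X * config$reads_per_region_per_X)
        simulate_reads(regions[i, ], n_i, origin,
                       seed = derive_seed(sd, paste0("r", i)),
                       read_length = config$read_length, sample_id = id,
                       flip_rate = config$flip_rate)
      })
      reads[[id]] <<- rbind_reads(parts)
    }
    manifest[[id]] <<- data.frame(
      sample_id = id, group = group,
      grade = "none", theta = if (is.null(origin)) theta else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n_tumor_tissue))
    add_sample(sprintf("%s_tumorT_%02d", sample_prefix, i),
               "tumor_tissue", NA, origin = "tumor")
  for (i in seq_len(n_normal_tissue))
    add_sample(sprintf("%s_normalT_%02d", sample_prefix, i),
               "normal_tissue", NA, origin = "normal")
  pos_thetas <- config$theta_grid[config$theta_grid > 0]
  if (length(pos_thetas) == 0L) pos_thetas <- 0.1
  for (i in seq_len(n_pca_urine))
    add_sample(sprintf("%s_pcaU_%02d", sample_prefix, i), "pca_urine",
               pos_thetas[((i - 1L) %% length(pos_thetas)) + 1L])
  for (i in seq_len(n_noncancer_urine))
    add_sample(sprintf("%s_ncU_%02d", sample_prefix, i),
               "noncancer_urine", 0)
  list(
    regions = regions, fasta = ref$fasta, reads = rbind_reads(reads),
    manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
    truth = truth
  )
}
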