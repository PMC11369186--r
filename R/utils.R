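#' @keywords internal
"_PACKAGE"

#' @importFrom stats wilcox.test p.adjust hclust cutree dist rbeta rbinom
#'   rnorm runif cor complete.cases setNames aggregate
#' @importFrom utils read.table write.table head modifyList
NULL

# Classed conditions so callers (and the CLI) can distinguish bad
# configuration from bad data.
rml_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rml_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

config_error <- function(msg, ...) rml_stop("rml_config_error", msg, ...)
format_error <- function(msg, ...) rml_stop("rml_format_error", msg, ...)
param_error  <- function(msg, ...) rml_stop("rml_param_error", msg, ...)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' Derive a reproducible stage seed from a master seed
#'
#' Each pipeline stage draws its own seed deterministically from the master
#' seed and the stage name, so stages can be rerun independently and still
#' reproduce. The stage name is hashed with a small polynomial rolling hash;
#' the result stays below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is_count(abs(master_seed)), is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  # every intermediate stays below 2^53 so double arithmetic is exact
  x <- (abs(as.numeric(master_seed)) %% 2147483647)
  x <- (x * 69621 + h) %% 2147483647
  as.integer((x * 48271 + 1) %% 2147483647)
}

# Comma-join / split helpers for list-columns in TSVs.
join_ints <- function(v) vapply(v, function(x) paste(x, collapse = ","), "")

split_ints <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE), function(x) {
    if (length(x) == 1L && (is.na(x) || x == "")) integer(0) else as.integer(x)
  })
}

# Methylation states are stored in memory as integer 0/1 and on disk as
# comma-joined "U"/"M".
join_states <- function(v) {
  vapply(v, function(x) paste(c("U", "M")[x + 1L], collapse = ","), "")
}

split_states <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE), function(x) {
    if (length(x) == 1L && (is.na(x) || x == "")) return(integer(0))
    bad <- !x %in% c("U", "M")
    if (any(bad)) format_error("invalid methylation state '%s'", x[bad][1])
    as.integer(x == "M")
  })
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(s, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""), ""
  ))
}
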