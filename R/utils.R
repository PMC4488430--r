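#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 map_chr map_int map_dbl pmap imap list_rbind
#' @importFrom stats rmultinom rlnorm runif setNames
#' @importFrom utils head tail
NULL

# data.table is used (not just data.frame methods) in the aligner hot path
.datatable.aware <- TRUE

# Reverse complement for plain character vectors of DNA (ACGTN alphabet).
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# Deterministic per-stage seeds derived from one user-facing seed, so stages
# can be rerun independently with identical results.  Kept well below 2^31.
derive_seed <- function(seed, stage) {
  offs <- c(
    genome = 101L, fragments = 211L, capture = 223L, emit = 227L,
    caller = 307L, workflow = 401L
  )
  if (!stage %in% names(offs)) abort(paste0("unknown stage: ", stage))
  (as.integer(seed) %% 2000000000L) + offs[[stage]]
}

# 0-based half-open substring of a transcript/chromosome sequence.
subseq0 <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
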