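#' Reverse-complement nucleotide strings
#'
#' @param x character vector of nucleotide sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All stochastic operations in the package
# funnel through this so that a seed fully determines the output.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Minimum guaranteed exact-run length inside any end-to-end placement of an
# L-mer with at most v mismatches: the v mismatches split L - v matching
# bases into at most v + 1 runs.
run_guarantee_endtoend <- function(read_length, max_mismatches) {
  as.integer(ceiling((read_length - max_mismatches) / (max_mismatches + 1)))
}

# Minimum guaranteed exact-run length inside any local window of length
# >= min_length with identity >= min_identity, minimised over all window
# lengths up to max_length.
run_guarantee_local <- function(min_length, min_identity, max_length = 1000L) {
  ls <- seq.int(min_length, max(min_length, max_length))
  mm <- floor((1 - min_identity) * ls + 1e-9)
  as.integer(min(ceiling((ls - mm) / (mm + 1))))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  }
}
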