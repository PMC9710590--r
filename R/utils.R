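#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import Matrix
#' @importFrom Rcpp sourceCpp
#' @useDynLib causalembed, .registration = TRUE
NULL

# Derive a stream-specific 32-bit sub-seed from a user seed. Keeps independent
# stages (graph sampling, noise flips, walks, ...) decoupled while remaining a
# pure function of the user-facing seed.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 16807L) %% 2147483562L
}

# Lexicographic, locale-independent ordering for reproducible matrices.
lex_sort <- function(x) {
  withr_locale <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", withr_locale), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(unique(x))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
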