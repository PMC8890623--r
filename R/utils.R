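# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global \code{.Random.seed}, so seeded sampling inside
#' the package never disturbs the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Validate a DNA string over {A,C,G,T,N}, case-insensitive; returns the
# upper-cased string.
check_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string", call. = FALSE)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  s
}

# Reverse complement of an upper-case DNA character string (N maps to N).
revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Empty motif table with the canonical column layout.
empty_motifs <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), seq = character(), g_score = integer(),
             source = character(), stringsAsFactors = FALSE)
}
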