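# Small internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] returning plain
#' character vectors, which is what the read-level simulators and the
#' exact-match aligner work with.
#'
#' @param x Character vector of DNA sequences over {A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Accept either a path to an existing file or raw text content; returns a
# readable path (text content is written to a tempfile with the given
# extension). Lets parse_locus() and friends take inline fixtures in tests.
as_input_file <- function(x, ext) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) return(x)
  tf <- tempfile(fileext = paste0(".", ext))
  writeLines(x, tf)
  tf
}

# Hash index of every substring of `seqs` with length in [min_len, max_len].
# For a single sequence with positions = TRUE the environment maps substring
# -> integer vector of 1-based start positions; with positions = FALSE it is
# a plain membership set (used for the structural-RNA filter, where both
# strands of every record are indexed).
substring_index <- function(seqs, min_len = 18L, max_len = 30L,
                            positions = TRUE, both_strands = FALSE) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  if (both_strands) seqs <- c(seqs, revcomp(seqs))
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (positions && length(seqs) > 1L) {
    stop("positional substring index supports a single sequence")
  }
  for (len in min_len:max_len) {
    if (positions) {
      # Keys of different lengths never collide, and split() already groups
      # repeated substrings within the sequence, so list2env() suffices.
      n <- nchar(seqs)
      if (n < len) next
      starts <- seq_len(n - len + 1L)
      subs <- substring(seqs, starts, starts + len - 1L)
      list2env(split(starts, subs), envir = env)
    } else {
      keys <- unlist(lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < len) return(character(0))
        starts <- seq_len(n - len + 1L)
        unique(substring(s, starts, starts + len - 1L))
      }), use.names = FALSE)
      keys <- unique(keys)
      if (length(keys)) {
        list2env(setNames(as.list(rep(TRUE, length(keys))), keys),
                 envir = env)
      }
    }
  }
  attr(env, "min_len") <- min_len
  attr(env, "max_len") <- max_len
  env
}

index_lookup <- function(index, keys) {
  mget(keys, envir = index, ifnotfound = list(NULL))
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent streams for the different generators without reusing streams.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}
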