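# Internal helpers shared across modules.

# Run code with a private RNG stream; the caller's .Random.seed is
# untouched.  All generators funnel through this so that output is a
# pure function of (config, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1103) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

substr0 <- function(x, start, end) {
  # 0-based half-open coordinates on a string
  substr(x, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sample a random codon stream free of stop codons (table 11 sense codons)
random_codons <- function(n_codons) {
  if (n_codons == 0L) return("")
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- paste(sample(DNA_BASES, 3, replace = TRUE), collapse = "")
      if (!cod %in% STOP_CODONS) break
    }
    out[i] <- cod
  }
  paste(out, collapse = "")
}
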