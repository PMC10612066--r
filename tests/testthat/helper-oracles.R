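# Independent oracles, implemented before and apart from the package
# code paths they check.

# Quadratic-space affine-gap global alignment score (Gotoh), pure R.
# A gap of length L costs open + L * ext.
oracle_nw_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, na + 1, nb + 1)
  X <- matrix(NEG, na + 1, nb + 1)  # gap in b
  Y <- matrix(NEG, na + 1, nb + 1)  # gap in a
  M[1, 1] <- 0
  for (j in 2:(nb + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(na + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (i in 2:(na + 1)) for (j in 2:(nb + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      mat[A[i - 1], B[j - 1]]
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[na + 1, nb + 1], X[na + 1, nb + 1], Y[na + 1, nb + 1])
}

# Exhaustive change-point segmentation: minimal total within-segment
# absolute deviation from the per-column segment median, over all
# placements of k-1 boundaries respecting min_len; lexicographically
# earliest boundary vector among optima.
oracle_segment <- function(P, k, min_len) {
  n <- nrow(P)
  seg_cost <- function(i, j) {
    block <- P[i:j, , drop = FALSE]
    sum(abs(sweep(block, 2, apply(block, 2, stats::median))))
  }
  best_cost <- Inf; best_bounds <- NULL
  cuts <- utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)
  if (k == 1) cuts <- list(integer())
  for (cut in cuts) {
    bounds <- c(cut, n)
    starts <- c(1, head(bounds, -1) + 1)
    if (any(bounds - starts + 1 < min_len)) next
    cost <- sum(mapply(seg_cost, starts, bounds))
    if (cost < best_cost - 1e-9 ||
        (abs(cost - best_cost) <= 1e-9 && !is.null(best_bounds) &&
         lex_less(bounds, best_bounds))) {
      best_cost <- cost; best_bounds <- bounds
    }
  }
  list(bounds = best_bounds, cost = best_cost)
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# one-sided upper binomial tail by explicit summation over outcomes
oracle_binom_tail <- function(k, m, f) {
  if (k <= 0) return(1)
  sum(vapply(k:m, function(j) choose(m, j) * f^j * (1 - f)^(m - j), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a plain identity matrix as an IdentityTable
table_from_matrix <- function(P) {
  refs <- colnames(P) %||% paste0("R", seq_len(ncol(P)))
  structure(list(
    query_genome_id = "Q", reference_genome_ids = refs,
    genes = data.frame(gene_index = seq_len(nrow(P)),
                       query_id = paste0("Q|g", seq_len(nrow(P))),
                       product = NA_character_),
    cells = stats::setNames(lapply(seq_along(refs), function(j)
      data.frame(matched_ref_protein_id = NA_character_,
                 percent_identity = P[, j], score = NA_real_,
                 reciprocal_best = NA)), refs)),
    class = "IdentityTable")
}

# seeded random DNA string
with_seed_chars <- function(seed, n) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random amino-acid sequence (no X)
random_aa <- function(n) {
  paste(sample(setdiff(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                         "M","F","P","S","T","W","Y","V"), ""), n,
               replace = TRUE), collapse = "")
}

make_protein <- function(aa, idx = 1L, genome = "T") {
  structure(list(id = paste0(genome, "|p", idx), genome_id = genome,
                 locus_tag = paste0("p", idx), gene_index = idx,
                 aa_sequence = aa, start = 0L, end = 3L * nchar(aa),
                 strand = 1L, product = NA_character_,
                 flags = character()), class = "ProteinRecord")
}

make_proteome <- function(aas, genome = "T") {
  structure(lapply(seq_along(aas), function(i)
    make_protein(aas[i], i, genome)), class = "Proteome")
}
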