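# Module-level summaries of the identity table, exact change-point
# segmentation of module boundaries, and the per-gene two-exemplar
# bipartition that defines the two tail lineages.

#' Define a genome module
#'
#' A named contiguous block of genes on the query genome.  The canonical
#' four-module layout of a small temperate myovirus is nonstructural,
#' head+connector, tail, antireceptor+DGR; manual definitions are
#' first-class inputs, auto-segmentation provides them for synthetic
#' validation and new genomes.
#'
#' @param name module name.
#' @param first,last inclusive gene-index range (1-based gene order).
#' @param provenance `"manual"` or `"auto"`.
#' @return object of class `ModuleDefinition`.
#' @export
module_definition <- function(name, first, last,
                              provenance = c("manual", "auto")) {
  provenance <- match.arg(provenance)
  stopifnot(first >= 1, last >= first)
  structure(list(name = name, first = as.integer(first),
                 last = as.integer(last), provenance = provenance),
            class = "ModuleDefinition")
}

#' Read module definitions from a 3-column range file
#'
#' Tab-separated columns: module_name, first_gene_index,
#' last_gene_index (1-based inclusive, BED-like gene-range dialect).
#'
#' @param path input file.
#' @return list of [module_definition()]s.
#' @export
read_module_definitions <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("name", "first", "last"))
  lapply(seq_len(nrow(df)), function(i)
    module_definition(df$name[i], df$first[i], df$last[i]))
}

#' Median identity of a module against one reference
#'
#' The module statistic is the median of the measured identities (cells
#' with no match are excluded), which resists individual genes
#' interjected into a module by recombinational reassortment better
#' than a mean would.  An even count of measured cells yields the
#' midpoint of the central pair.
#'
#' @param t an `IdentityTable`.
#' @param m a `ModuleDefinition` whose range is valid for `t`.
#' @param ref reference genome id (column of `t`).
#' @return object of class `ModuleSummary`: `median_identity` (`NA` when
#'   nothing is measured), `n_measured`, `n_unmeasured`.
#' @export
summarize_module <- function(t, m, ref) {
  if (!ref %in% t$reference_genome_ids)
    stop("unknown reference: ", ref)
  idx <- which(t$genes$gene_index >= m$first & t$genes$gene_index <= m$last)
  if (length(idx) == 0L) stop("module range contains no genes")
  v <- t$cells[[ref]]$percent_identity[idx]
  meas <- v[!is.na(v)]
  structure(list(module = m, reference_genome_id = ref,
                 median_identity = if (length(meas)) median(meas) else NA_real_,
                 n_measured = length(meas),
                 n_unmeasured = sum(is.na(v))),
            class = "ModuleSummary")
}

#' @export
print.ModuleSummary <- function(x, ...) {
  cat(sprintf("<ModuleSummary %s vs %s: median %s (n=%d, none=%d)>\n",
              x$module$name, x$reference_genome_id,
              ifelse(is.na(x$median_identity), "NA",
                     format(round(x$median_identity, 1))),
              x$n_measured, x$n_unmeasured))
  invisible(x)
}

# cost of one segment [i..j] of profile matrix P (genes x refs):
# total absolute deviation from the per-reference segment median
segment_cost_matrix <- function(P) {
  n <- nrow(P)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    block <- P[i:j, , drop = FALSE]
    C[i, j] <- sum(abs(sweep(block, 2,
                             apply(block, 2, median))))
  }
  C
}

#' Segment a genome into modules by exact change-point analysis
#'
#' Dynamic-programming segmentation of the gene-ordered identity
#' profiles into `n_modules` contiguous segments minimising the total
#' within-segment absolute deviation from the segment median (per
#' reference, summed).  "No match" cells are informative absences and
#' enter the cost imputed at 0; reported medians elsewhere still exclude
#' them.  Deterministic: among cost-tied segmentations the
#' lexicographically earliest boundary vector is returned.
#'
#' @param t an `IdentityTable` with at least 2 reference columns (the
#'   module patterns are contrasts between columns).
#' @param min_len minimum genes per segment.
#' @param n_modules number of segments, or `"auto"` to pick the
#'   smallest count (up to 8) whose relative cost improvement over the
#'   previous count falls below 5 percent.
#' @return list of `ModuleDefinition`s with `provenance = "auto"`,
#'   with attribute `cost` (total segmentation cost).
#' @export
segment_modules <- function(t, min_len = 3, n_modules = 4) {
  P <- identity_matrix(t)
  if (ncol(P) < 2)
    stop("segmentation needs >= 2 reference columns")
  P[is.na(P)] <- 0
  n <- nrow(P)
  auto <- identical(n_modules, "auto")
  kmax <- if (auto) min(8L, n %/% min_len) else as.integer(n_modules)
  if (min_len * kmax > n && !auto)
    stop("min_len * n_modules exceeds the gene count")
  C <- segment_cost_matrix(P)
  # suffix DP: S[i, k] = min cost of segmenting genes i..n into k parts
  S <- matrix(Inf, n + 1L, kmax + 1L)
  S[n + 1L, 1L] <- Inf
  for (i in n:1)  # k index shifted by 1: col k+1
    S[i, 2L] <- if (n - i + 1L >= min_len) C[i, n] else Inf
  if (kmax >= 2) for (k in 2:kmax) for (i in n:1) {
    ends <- seq.int(i + min_len - 1L, n - min_len * (k - 1L))
    if (length(ends) == 0L || ends[1] > ends[length(ends)]) next
    vals <- C[i, ends] + S[ends + 1L, k]
    S[i, k + 1L] <- min(vals)
  }
  # enforce min_len on single segments too
  pick_k <- function(k) is.finite(S[1L, k + 1L]) && n >= min_len * k
  if (auto) {
    costs <- vapply(1:kmax, function(k) S[1L, k + 1L], 0)
    k_use <- 1L
    for (k in seq_len(kmax - 1L)) {
      if (!pick_k(k + 1L)) break
      if ((costs[k] - costs[k + 1L]) > 0.05 * max(costs[k], 1e-9))
        k_use <- k + 1L else break
    }
  } else k_use <- kmax
  if (!pick_k(k_use)) stop("no feasible segmentation under min_len")
  # forward reconstruction: earliest boundary at each step among optima
  bounds <- integer(0)
  i <- 1L
  for (k in k_use:1) {
    if (k == 1L) { bounds <- c(bounds, n); break }
    ends <- seq.int(i + min_len - 1L, n - min_len * (k - 1L))
    vals <- C[i, ends] + S[ends + 1L, k]
    e <- ends[which(vals <= min(vals) + 1e-9)[1]]  # earliest optimum
    bounds <- c(bounds, e)
    i <- e + 1L
  }
  starts <- c(1L, head(bounds, -1L) + 1L)
  mods <- lapply(seq_along(bounds), function(s)
    module_definition(paste0("segment_", s), starts[s], bounds[s],
                      provenance = "auto"))
  attr(mods, "cost") <- S[1L, k_use + 1L]
  mods
}

#' Bipartition a phage panel by one gene's identities to two exemplars
#'
#' Each panel phage is assigned to the exemplar to which the gene shows
#' the higher identity (the "matches better to" criterion); a phage with
#' both cells unmeasured is unresolved (a single unmeasured cell counts
#' as identity 0).  When reference group labels are supplied,
#' `is_separable` reports whether a single threshold on the margin
#' (identity_to_A - identity_to_B) puts every resolved phage of group A
#' above it and every phage of group B below it with no interleaving;
#' `separating_threshold` is then the midpoint of the widest margin gap.
#' Without supplied labels the sign-derived assignment is itself the
#' grouping, and separability holds whenever no resolved margin is zero.
#'
#' @param panel data frame with columns `phage`, `id_A`, `id_B`
#'   (percent identities, `NA` = no match).
#' @param gene gene name (label only).
#' @param exemplars character vector of length 2, ids of exemplars A
#'   and B.
#' @param groups optional named vector (`phage -> "A"` or `"B"`) of
#'   externally known group labels to test separability against.
#' @return object of class `Bipartition`.
#' @export
bipartition_by_gene <- function(panel, gene, exemplars = c("A", "B"),
                                groups = NULL) {
  stopifnot(all(c("phage", "id_A", "id_B") %in% names(panel)))
  both_na <- is.na(panel$id_A) & is.na(panel$id_B)
  a <- ifelse(is.na(panel$id_A), 0, panel$id_A)
  b <- ifelse(is.na(panel$id_B), 0, panel$id_B)
  margin <- a - b
  assign <- ifelse(both_na, "unresolved",
                   ifelse(margin > 0, "A", ifelse(margin < 0, "B",
                                                  "unresolved")))
  names(assign) <- panel$phage
  use <- if (is.null(groups)) assign else groups[panel$phage]
  resolved <- !both_na & use %in% c("A", "B")
  mA <- margin[resolved & use == "A"]
  mB <- margin[resolved & use == "B"]
  if (length(mA) && length(mB)) {
    separable <- min(mA) > max(mB)
    threshold <- if (separable) (min(mA) + max(mB)) / 2 else NA_real_
  } else {
    separable <- length(mA) + length(mB) > 0
    threshold <- NA_real_
  }
  structure(list(gene_name = gene, exemplar_A_id = exemplars[1],
                 exemplar_B_id = exemplars[2],
                 per_phage_assignment = assign, margin = margin,
                 separating_threshold = threshold,
                 is_separable = separable),
            class = "Bipartition")
}

#' Consensus grouping across gene bipartitions
#'
#' Majority vote per phage across a set of per-gene bipartitions (for
#' example, one per tail gene); the agreement score is the fraction of
#' voting genes that concur with the majority.  Vote ties leave the
#' phage unresolved.
#'
#' @param bipartitions list of `Bipartition` objects (at least one).
#' @return data frame with columns `phage`, `group`, `agreement`,
#'   `n_votes`.
#' @export
consensus_groups <- function(bipartitions) {
  if (length(bipartitions) == 0L) stop("at least one bipartition required")
  phages <- unique(unlist(lapply(bipartitions, function(b)
    names(b$per_phage_assignment))))
  res <- lapply(phages, function(p) {
    votes <- vapply(bipartitions, function(b)
      b$per_phage_assignment[p] %||% NA_character_, "")
    votes <- votes[votes %in% c("A", "B")]
    if (length(votes) == 0L)
      return(data.frame(phage = p, group = "unresolved",
                        agreement = NA_real_, n_votes = 0L))
    nA <- sum(votes == "A"); nB <- sum(votes == "B")
    if (nA == nB)
      return(data.frame(phage = p, group = "unresolved",
                        agreement = 0.5, n_votes = length(votes)))
    data.frame(phage = p, group = if (nA > nB) "A" else "B",
               agreement = max(nA, nB) / length(votes),
               n_votes = length(votes))
  })
  do.call(rbind, res)
}

#' Per-gene identity track with module medians
#'
#' Emits the per-gene identity profile plus each module's median per
#' reference -- a text analog of a genome-map similarity track.
#'
#' @param t an `IdentityTable`.
#' @param modules list of `ModuleDefinition`s.
#' @return data frame with `gene_index`, `module`, one identity column
#'   per reference and one `median_<ref>` column per reference.
#' @export
module_track <- function(t, modules) {
  df <- as.data.frame(t)
  df$module <- NA_character_
  for (m in modules)
    df$module[df$gene_index >= m$first & df$gene_index <= m$last] <- m$name
  for (ref in t$reference_genome_ids) {
    med <- rep(NA_real_, nrow(df))
    for (m in modules) {
      s <- summarize_module(t, m, ref)
      med[df$gene_index >= m$first & df$gene_index <= m$last] <-
        s$median_identity
    }
    df[[paste0("median_", ref)]] <- med
  }
  df
}
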