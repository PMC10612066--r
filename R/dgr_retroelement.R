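# Diversity-generating retroelement analysis: template/variable repeat
# (TR/VR) discovery near a reverse-transcriptase gene, classification of
# TR/VR mismatches under the adenine-substitution (A->N) paradigm, an
# exact binomial test of adenine bias, and protein-level comparison of
# variable regions.

#' Compare a template repeat against its variable region
#'
#' Globally aligns the two copies (match +1, mismatch -1, gap -2 per
#' base; equal-length inputs align gaplessly when that is optimal) and
#' classifies every mismatch column: *conforming* iff the template base
#' is `A` and the variable base is one of `C,G,T` -- the substitution
#' specificity of DGR mutagenesis; every other mismatch (including
#' `X -> A`) is nonconforming.  Gap columns are tallied separately and
#' excluded from the binomial test, since the paradigm concerns
#' substitutions at adenines.
#'
#' @param tr,vr DNA strings (template repeat, variable region).
#' @return object of class `VRComparison`: aligned strings, a
#'   `mismatches` data frame (`position_in_TR` 1-based, `tr_base`,
#'   `vr_base`, `class`), counts `n_conforming`, `n_nonconforming`,
#'   `n_indel_columns`, `n_tr_adenines`, `tr_length`, and
#'   `p_value_adenine_bias` from [adenine_bias_test()].
#' @export
classify_variants <- function(tr, vr) {
  if (!nzchar(tr) || !nzchar(vr)) stop("empty input sequence")
  tr <- toupper(tr); vr <- toupper(vr)
  al <- .banded_align_cpp(tr, vr, band = max(16L, abs(nchar(tr) - nchar(vr)) + 8L),
                          match = 1, mismatch = -1, gap_open = 0, gap_ext = 2)
  tc <- seq_chars(al$aligned_a); vc <- seq_chars(al$aligned_b)
  sub_col <- tc != "-" & vc != "-" & tc != vc
  gap_col <- tc == "-" | vc == "-"
  tr_pos <- cumsum(tc != "-")
  mism <- data.frame(position_in_TR = tr_pos[sub_col],
                     tr_base = tc[sub_col], vr_base = vc[sub_col],
                     stringsAsFactors = FALSE)
  mism$class <- ifelse(mism$tr_base == "A" & mism$vr_base %in% c("C", "G", "T"),
                       "conforming", "nonconforming")
  out <- structure(list(
    aligned_tr = al$aligned_a, aligned_vr = al$aligned_b,
    mismatches = mism,
    n_conforming = sum(mism$class == "conforming"),
    n_nonconforming = sum(mism$class == "nonconforming"),
    n_indel_columns = sum(gap_col),
    n_tr_adenines = sum(tc == "A"),
    tr_length = sum(tc != "-"),
    p_value_adenine_bias = NA_real_), class = "VRComparison")
  out$p_value_adenine_bias <- adenine_bias_test(out)
  out
}

#' @export
print.VRComparison <- function(x, ...) {
  cat(sprintf(
    "<VRComparison: %d mismatches (%d conforming A->N, %d other), %d indel cols, p=%.3g>\n",
    nrow(x$mismatches), x$n_conforming, x$n_nonconforming,
    x$n_indel_columns, x$p_value_adenine_bias))
  invisible(x)
}

#' Exact test of adenine-directed hypermutation
#'
#' Under the null that the m mismatch positions fall uniformly over the
#' template repeat, the number of conforming (template-adenine)
#' mismatches is Binomial(m, f) with f the adenine fraction of the
#' template.  The statistic is the one-sided upper tail
#' `P(X >= n_conforming)`.  A Monte-Carlo alternative re-draws the
#' mismatch positions uniformly over the template and must agree with
#' the closed form within sampling error.
#'
#' @param c a `VRComparison`.
#' @param method `"binomial"` (exact, default) or `"permutation"`.
#' @param n_perm draws for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return p-value; 1.0 by convention when there are no mismatches.
#' @export
adenine_bias_test <- function(c, method = c("binomial", "permutation"),
                              n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  m <- c$n_conforming + c$n_nonconforming
  if (m == 0L) return(1.0)
  f <- c$n_tr_adenines / c$tr_length
  if (method == "binomial")
    return(pbinom(c$n_conforming - 1L, m, f, lower.tail = FALSE))
  with_seed(seed, {
    hits <- rbinom(n_perm, m, f)
    (1 + sum(hits >= c$n_conforming)) / (n_perm + 1)
  })
}

#' Detect DGR cassettes around a reverse-transcriptase gene
#'
#' Seed-and-extend enumeration of direct-repeat pairs within
#' `search_window` bp of the RT gene: exact seeds of length `seed_k`
#' are extended in both directions while the mismatch fraction stays at
#' or below `max_mismatch_frac`, then trimmed back to matching end
#' columns.  A pair is kept when its mismatches are significantly
#' adenine-biased in one copy ([adenine_bias_test()] p < `alpha`); that
#' copy is the template repeat (TR).  The other copy, when inside a
#' CDS, makes that CDS the antireceptor.  Identical repeat pairs carry
#' no mismatch signal and are never reported.
#'
#' @param g a `GenomeRecord` with CDS annotations.
#' @param rt_gene locus tag of the reverse-transcriptase gene; by
#'   default the CDS whose product matches "reverse transcriptase".
#' @param search_window bp searched on each side of the RT gene.
#' @param repeat_len_range admissible repeat lengths in bp.
#' @param seed_k exact seed length.
#' @param max_mismatch_frac maximum mismatch fraction during extension.
#' @param alpha significance level of the adenine-bias filter.
#' @return list of `DGRCassette` objects (possibly empty): intervals
#'   for TR and VR (0-based half-open, genome coordinates), the
#'   antireceptor/avd/RT features, the RT pseudogene flag, the
#'   `VRComparison`, and whether the TR reads as an in-frame N-terminal
#'   extension of the RT CDS.
#' @export
find_tr_vr <- function(g, rt_gene = NULL, search_window = 5000,
                       repeat_len_range = c(50, 200), seed_k = 12,
                       max_mismatch_frac = 0.35, alpha = 0.05) {
  cds <- g$features[g$features$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("genome has no CDS annotations")
  if (is.null(rt_gene)) {
    hit <- grepl("reverse transcriptase", cds$product, ignore.case = TRUE)
    if (!any(hit))
      stop("no CDS annotated as 'reverse transcriptase'; ",
           "supply rt_gene = <locus_tag>")
    rt <- cds[which(hit)[1], ]
  } else {
    rt <- cds[match(rt_gene, cds$locus_tag), ]
    if (nrow(rt) == 0L || is.na(rt$start))
      stop("rt_gene not found: ", rt_gene)
  }
  len <- genome_length(g)
  w0 <- max(0L, rt$start - as.integer(search_window))
  w1 <- min(len, rt$end + as.integer(search_window))
  W <- substr0(g$sequence, w0, w1)
  pairs <- repeat_pairs(W, seed_k, repeat_len_range, max_mismatch_frac)
  out <- list()
  for (p in pairs) {
    s1 <- substr0(W, p$i, p$i + p$len)
    s2 <- substr0(W, p$j, p$j + p$len)
    cv12 <- classify_variants(s1, s2)  # copy 1 as template
    cv21 <- classify_variants(s2, s1)
    m <- nrow(cv12$mismatches)
    if (m == 0L) next                  # identical copies: no signal
    p12 <- cv12$p_value_adenine_bias
    p21 <- cv21$p_value_adenine_bias
    if (min(p12, p21) >= alpha) next
    tr_first <- p12 <= p21
    tr_iv <- if (tr_first) c(p$i, p$i + p$len) else c(p$j, p$j + p$len)
    vr_iv <- if (tr_first) c(p$j, p$j + p$len) else c(p$i, p$i + p$len)
    tr_iv <- tr_iv + w0; vr_iv <- vr_iv + w0
    anti <- overlapping_cds(cds, vr_iv)
    avd <- find_avd(cds, anti, rt)
    rt_flags <- character()
    if ((rt$end - rt$start) %% 3L != 0L)
      rt_flags <- "possible frameshift/pseudogene"
    ext <- tr_iv[2] <= rt$end && tr_iv[1] >= rt$start &&
      (tr_iv[1] - rt$start) %% 3L == 0L && rt$strand == 1L
    out[[length(out) + 1L]] <- structure(list(
      genome_id = g$id,
      tr_interval = as.integer(tr_iv), vr_interval = as.integer(vr_iv),
      antireceptor_gene = anti, avd_gene = avd, rt_gene = rt,
      rt_pseudogene = length(rt_flags) > 0,
      tr_is_rt_extension = isTRUE(ext),
      comparison = if (tr_first) cv12 else cv21,
      p_value = min(p12, p21)), class = "DGRCassette")
  }
  out
}

# enumerate direct-repeat pairs in sequence W by exact-seed matching and
# greedy mismatch-bounded extension; coordinates 0-based on W
repeat_pairs <- function(W, k, len_range, max_frac) {
  n <- nchar(W)
  if (n < 2 * len_range[1]) return(list())
  ch <- seq_chars(W)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(W, starts, starts + k - 1L)
  dup <- split(starts - 1L, kmers)
  dup <- dup[lengths(dup) >= 2L & lengths(dup) <= 10L]
  cands <- list()
  seen_diag <- character()
  for (pos in dup) {
    cmb <- utils::combn(sort(pos), 2L)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]; j <- cmb[2, c_i]
      key <- paste0(j - i, ":", (i %/% 25L))
      if (key %in% seen_diag) next
      seen_diag <- c(seen_diag, key)
      ext <- extend_pair(ch, i, j, k, max_frac)
      if (is.null(ext)) next
      if (ext$len < len_range[1] || ext$len > len_range[2]) next
      if (ext$j < ext$i + ext$len) next  # copies must not overlap
      cands[[length(cands) + 1L]] <- ext
    }
  }
  dedupe_pairs(cands)
}

# X-drop extension of an exact seed: columns score +1 on match, -2 on
# mismatch; each direction stops when the running score falls `xdrop`
# below its running maximum and is trimmed back to the maximum (always
# a matching column).  The mismatch-fraction cap is applied to the
# final extent.
extend_pair <- function(ch, i, j, k, max_frac, xdrop = 25) {
  n <- length(ch)
  # span is ch[i+lo .. i+hi) vs ch[j+lo .. j+hi); lo <= 0, hi >= k
  # rightward
  hi <- k; s <- 0; best <- 0; t <- k
  while (j + t < n && i + t < j) {          # keep the copies disjoint
    s <- s + (if (ch[i + t + 1L] == ch[j + t + 1L]) 1 else -2)
    t <- t + 1L
    # ties prefer the longer extent, so a conserved repeat terminus
    # that exactly offsets preceding mismatches is still included
    if (s >= best) { best <- s; hi <- t }
    if (s < best - xdrop) break
  }
  # leftward
  lo <- 0L; s <- 0; best <- 0; t <- 0L
  while (i + t > 0L && j + t - 1L >= i + hi) {
    s <- s + (if (ch[i + t] == ch[j + t]) 1 else -2)
    t <- t - 1L
    if (s >= best) { best <- s; lo <- t }
    if (s < best - xdrop) break
  }
  len <- hi - lo
  if (len <= 0L) return(NULL)
  mism <- sum(ch[(i + lo + 1L):(i + hi)] != ch[(j + lo + 1L):(j + hi)])
  if (mism / len > max_frac) return(NULL)
  list(i = i + lo, j = j + lo, len = len)
}

# keep the longest candidate among those whose copy intervals overlap
dedupe_pairs <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  ord <- order(-vapply(cands, function(x) x$len, 0),
               vapply(cands, function(x) x$i, 0))
  kept <- list()
  for (idx in ord) {
    x <- cands[[idx]]
    clash <- any(vapply(kept, function(y)
      intervals_overlap(x$i, x$i + x$len, y$i, y$i + y$len) &&
        intervals_overlap(x$j, x$j + x$len, y$j, y$j + y$len), TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- x
  }
  kept[order(vapply(kept, function(x) x$i, 0))]
}

intervals_overlap <- function(a0, a1, b0, b1) a0 < b1 && b0 < a1

overlapping_cds <- function(cds, iv) {
  hit <- cds$start < iv[2] & cds$end > iv[1]
  if (!any(hit)) return(NULL)
  cds[which(hit)[1], ]
}

find_avd <- function(cds, anti, rt) {
  hit <- grepl("accessory variability determinant|\\bavd\\b",
               cds$product, ignore.case = TRUE)
  if (any(hit)) return(cds[which(hit)[1], ])
  if (is.null(anti)) return(NULL)
  between <- cds$start >= anti$end & cds$end <= rt$start
  if (any(between)) cds[which(between)[1], ] else NULL
}

#' @export
print.DGRCassette <- function(x, ...) {
  cat(sprintf(
    "<DGRCassette %s: TR [%d,%d) VR [%d,%d) p=%.3g%s%s>\n",
    x$genome_id, x$tr_interval[1], x$tr_interval[2],
    x$vr_interval[1], x$vr_interval[2], x$p_value,
    if (x$tr_is_rt_extension) ", TR = RT N-extension" else "",
    if (x$rt_pseudogene) ", RT pseudogene" else ""))
  invisible(x)
}

#' Residue-level comparison of antireceptor variable regions
#'
#' Aligns each protein against the first (the designated reference) and
#' tabulates per-residue variants over the requested region, with
#' 1-based residue numbers on the reference and a terminator flag for
#' stop symbols (`*`).
#'
#' @param vrs named list of `ProteinRecord`s (or plain amino-acid
#'   strings); at least two, first is the reference.
#' @param region 1-based inclusive residue range on the reference
#'   protein, e.g. `c(300, 360)`.
#' @return data frame: `residue`, reference residue, one column per
#'   other protein (NA where identical to the reference), `terminator`.
#' @export
compare_vr_proteins <- function(vrs, region = NULL) {
  if (length(vrs) < 2L) stop("need at least two proteins")
  seqs <- lapply(vrs, function(v)
    if (inherits(v, "ProteinRecord")) v$aa_sequence else as.character(v))
  ids <- names(vrs) %||% paste0("p", seq_along(vrs))
  ref <- seqs[[1]]
  if (is.null(region)) region <- c(1L, nchar(ref))
  if (region[1] < 1L || region[2] > nchar(ref))
    stop("region outside the reference protein")
  rows <- list()
  aligned <- list()
  for (k in 2:length(seqs)) {
    al <- .banded_align_cpp(ref, seqs[[k]],
                            band = max(16L, abs(nchar(ref) - nchar(seqs[[k]])) + 8L),
                            match = 1, mismatch = -1, gap_open = 2, gap_ext = 1)
    rc <- seq_chars(al$aligned_a); oc <- seq_chars(al$aligned_b)
    pos <- cumsum(rc != "-")
    v <- rep(NA_character_, nchar(ref))
    for (col in which(rc != "-")) if (oc[col] != rc[col]) v[pos[col]] <- oc[col]
    aligned[[ids[k]]] <- v
  }
  refc <- seq_chars(ref)
  for (p in seq.int(region[1], region[2])) {
    vals <- vapply(aligned, function(v) v[p], "")
    if (all(is.na(vals))) next
    rows[[length(rows) + 1L]] <- c(list(residue = p, ref = refc[p]),
                                   as.list(vals),
                                   list(terminator = any(vals == "*", na.rm = TRUE) |
                                          refc[p] == "*"))
  }
  if (length(rows) == 0L) {
    out <- data.frame(residue = integer(), ref = character(),
                      terminator = logical())
    for (k in 2:length(seqs)) out[[ids[k]]] <- character()
    return(out[, c("residue", "ref", ids[-1], "terminator")])
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a cassette report (TSV + GFF3 intervals)
#'
#' @param cassettes list of `DGRCassette`s.
#' @param tsv_path,gff_path output files (either may be `NULL`).
#' @export
write_cassette_report <- function(cassettes, tsv_path = NULL, gff_path = NULL) {
  df <- do.call(rbind, lapply(cassettes, function(x) data.frame(
    genome_id = x$genome_id,
    tr_start = x$tr_interval[1], tr_end = x$tr_interval[2],
    vr_start = x$vr_interval[1], vr_end = x$vr_interval[2],
    n_conforming = x$comparison$n_conforming,
    n_nonconforming = x$comparison$n_nonconforming,
    p_value = x$p_value,
    rt_pseudogene = x$rt_pseudogene,
    tr_is_rt_extension = x$tr_is_rt_extension)))
  if (!is.null(tsv_path))
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gff_path)) {
    lines <- c("##gff-version 3")
    for (x in cassettes) {
      lines <- c(lines,
        sprintf("%s\tphagemosaic\trepeat_region\t%d\t%d\t.\t+\t.\tID=TR",
                x$genome_id, x$tr_interval[1] + 1L, x$tr_interval[2]),
        sprintf("%s\tphagemosaic\tvariable_region\t%d\t%d\t.\t+\t.\tID=VR",
                x$genome_id, x$vr_interval[1] + 1L, x$vr_interval[2]))
    }
    writeLines(lines, gff_path)
  }
  invisible(df)
}
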