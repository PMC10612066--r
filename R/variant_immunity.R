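# Differencing of near-identical genomes with region masks and effect
# classification, read-pileup allele fractions at variant sites, and a
# sigma-70 consensus promoter scan for the immunity region.

#' Difference two near-identical genomes
#'
#' Banded global alignment (band widened automatically on failure) of
#' genome `b` against reference genome `a`; variants are reported in
#' `a` coordinates with named-mask flags and effects classified against
#' `a`'s CDS annotations.  Substitutions are compared codon-wise;
#' indels inside a CDS whose length is not a multiple of 3 are
#' frameshifts.  Sequences below the identity guard raise an error:
#' heavily diverged genomes belong in the identity-profiling workflow,
#' not here.
#'
#' @param a,b `GenomeRecord`s (a is the reference/anchor).
#' @param masks named list of 0-based half-open intervals on `a`, e.g.
#'   `list(antireceptor = c(30100, 32400))`.  The conventional mask is
#'   the antireceptor CDS plus its variable region.
#' @param band initial alignment band width.
#' @param min_identity identity guard (percent).
#' @return object of class `DiffReport` with a `variants` data frame:
#'   `pos` (0-based on `a`), `ref`, `alt`, `type`
#'   (substitution/insertion/deletion), `in_mask`, `mask`, `effect`
#'   (intergenic/synonymous/missense/nonsense/frameshift/NA), and
#'   `n_outside_mask`.
#' @export
diff_genomes <- function(a, b, masks = list(), band = 200,
                         min_identity = 95) {
  band <- max(band, abs(genome_length(a) - genome_length(b)) + 8L)
  al <- NULL
  while (is.null(al) && band <= 3200L) {
    al <- tryCatch(.banded_align_cpp(a$sequence, b$sequence, band,
                                     match = 1, mismatch = -3,
                                     gap_open = 5, gap_ext = 2),
                   error = function(e) NULL)
    if (is.null(al)) band <- band * 2L
  }
  if (is.null(al)) stop("alignment failed even at band 3200")
  ac <- seq_chars(al$aligned_a); bc <- seq_chars(al$aligned_b)
  n_cols <- length(ac)
  ident <- 100 * sum(ac == bc) / n_cols
  if (ident < min_identity)
    stop(sprintf(paste0("genomes are only %.1f%% identical; use the ",
                        "identity-profiling workflow for diverged genomes"),
                 ident))
  apos <- cumsum(ac != "-")            # 1-based position on a
  variants <- list()
  i <- 1L
  while (i <= n_cols) {
    if (ac[i] != "-" && bc[i] != "-" && ac[i] != bc[i]) {
      variants[[length(variants) + 1L]] <-
        list(pos = apos[i] - 1L, ref = ac[i], alt = bc[i],
             type = "substitution")
      i <- i + 1L
    } else if (bc[i] == "-" && ac[i] != "-") {         # deletion in b
      j <- i
      while (j < n_cols && bc[j + 1L] == "-" && ac[j + 1L] != "-") j <- j + 1L
      variants[[length(variants) + 1L]] <-
        list(pos = apos[i] - 1L, ref = paste(ac[i:j], collapse = ""),
             alt = "-", type = "deletion")
      i <- j + 1L
    } else if (ac[i] == "-" && bc[i] != "-") {         # insertion in b
      j <- i
      while (j < n_cols && ac[j + 1L] == "-" && bc[j + 1L] != "-") j <- j + 1L
      variants[[length(variants) + 1L]] <-
        list(pos = apos[i] - 1L, ref = "-",
             alt = paste(bc[i:j], collapse = ""), type = "insertion")
      i <- j + 1L
    } else i <- i + 1L
  }
  df <- if (length(variants)) {
    do.call(rbind, lapply(variants, function(v)
      data.frame(v, stringsAsFactors = FALSE)))
  } else {
    data.frame(pos = integer(), ref = character(), alt = character(),
               type = character(), stringsAsFactors = FALSE)
  }
  df$mask <- rep(NA_character_, nrow(df))
  for (nm in names(masks)) {
    iv <- masks[[nm]]
    in_iv <- df$pos >= iv[1] & df$pos < iv[2]
    df$mask[in_iv & is.na(df$mask)] <- nm
  }
  df$in_mask <- !is.na(df$mask)
  df$effect <- vapply(seq_len(nrow(df)), function(k)
    classify_effect(a, df$pos[k], df$ref[k], df$alt[k], df$type[k]),
    "")
  if (nrow(df) == 0L) df$effect <- character(0)
  structure(list(genome_a_id = a$id, genome_b_id = b$id,
                 variants = df, masks = masks,
                 n_outside_mask = sum(!df$in_mask),
                 alignment_identity = ident),
            class = "DiffReport")
}

classify_effect <- function(a, pos, ref, alt, type) {
  cds <- a$features[a$features$kind == "CDS", , drop = FALSE]
  hit <- cds$start <= pos & cds$end > pos
  if (!any(hit)) return("intergenic")
  feat <- cds[which(hit)[1], ]
  if (type != "substitution") {
    len <- if (type == "deletion") nchar(ref) else nchar(alt)
    return(if (len %% 3L != 0L) "frameshift" else NA_character_)
  }
  # codon-level comparison on the coding strand
  if (feat$strand == 1L) {
    off <- pos - feat$start
    cstart <- feat$start + (off %/% 3L) * 3L
    codon <- substr0(a$sequence, cstart, cstart + 3L)
    ci <- off %% 3L + 1L
    new <- codon
    substr(new, ci, ci) <- alt
  } else {
    off <- feat$end - 1L - pos
    cstart_rc <- (off %/% 3L) * 3L
    nt <- revcomp(substr0(a$sequence, feat$start, feat$end))
    codon <- substr(nt, cstart_rc + 1L, cstart_rc + 3L)
    ci <- off %% 3L + 1L
    new <- codon
    substr(new, ci, ci) <- chartr("ACGT", "TGCA", alt)
  }
  aa_old <- translate_nt(codon)
  aa_new <- translate_nt(new)
  if (aa_old == aa_new) "synonymous"
  else if (aa_new == "*") "nonsense"
  else "missense"
}

#' @export
print.DiffReport <- function(x, ...) {
  cat(sprintf("<DiffReport %s vs %s: %d variants (%d outside masks), %.2f%% identity>\n",
              x$genome_a_id, x$genome_b_id, nrow(x$variants),
              x$n_outside_mask, x$alignment_identity))
  invisible(x)
}

#' Write a DiffReport as minimal VCF
#'
#' Eight columns; POS is 1-based; INFO carries `TYPE`, `EFFECT` and
#' `MASK`.  Indels follow VCF anchoring: the base before the event is
#' included in REF/ALT.
#'
#' @param report a `DiffReport`.
#' @param path output file.
#' @export
write_vcf <- function(report, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##reference=%s", report$genome_a_id),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- report$variants
  rows <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    info <- sprintf("TYPE=%s;EFFECT=%s;MASK=%s", v$type[i],
                    v$effect[i] %||% ".",
                    ifelse(is.na(v$mask[i]), ".", v$mask[i]))
    if (v$type[i] == "substitution") {
      rows[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                         report$genome_a_id, v$pos[i] + 1L, v$ref[i],
                         v$alt[i], info)
    } else {
      # anchor base convention
      rows[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                         report$genome_a_id, v$pos[i],
                         if (v$type[i] == "deletion") paste0("N", v$ref[i]) else "N",
                         if (v$type[i] == "insertion") paste0("N", v$alt[i]) else "N",
                         info)
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Allele fractions at variant sites from a pileup table
#'
#' For each queried site the minor fraction is the designated alternate
#' allele's read count over the total A+C+G+T count.  Sites with zero
#' coverage are flagged and excluded from the summary.
#'
#' @param pileup data frame with columns `pos`, `A`, `C`, `G`, `T`
#'   (and optionally `N`), as written by [write_pileup_tsv()].
#' @param sites data frame with columns `pos` and `alt` (alternate
#'   allele per site).
#' @return object of class `SiteAlleleFractions`: per-site data frame
#'   (`pos`, `alt`, `depth`, `alt_count`, `minor_fraction`,
#'   `zero_coverage`) and `summary` with `min`/`max` minor fraction.
#' @export
allele_fractions <- function(pileup, sites) {
  stopifnot(all(c("pos", "alt") %in% names(sites)))
  m <- match(sites$pos, pileup$pos)
  if (anyNA(m)) stop("sites missing from pileup: ",
                     paste(sites$pos[is.na(m)], collapse = ","))
  depth <- rowSums(pileup[m, c("A", "C", "G", "T"), drop = FALSE])
  altc <- vapply(seq_len(nrow(sites)), function(i)
    pileup[m[i], sites$alt[i]], numeric(1))
  frac <- ifelse(depth > 0, altc / depth, NA_real_)
  per_site <- data.frame(pos = sites$pos, alt = sites$alt, depth = depth,
                         alt_count = altc, minor_fraction = frac,
                         zero_coverage = depth == 0)
  ok <- !per_site$zero_coverage
  structure(list(per_site = per_site,
                 summary = c(min = if (any(ok)) min(frac[ok]) else NA_real_,
                             max = if (any(ok)) max(frac[ok]) else NA_real_)),
            class = "SiteAlleleFractions")
}

#' @export
print.SiteAlleleFractions <- function(x, ...) {
  cat(sprintf("<SiteAlleleFractions: %d sites, minor fraction %.3f-%.3f>\n",
              nrow(x$per_site), x$summary["min"], x$summary["max"]))
  invisible(x)
}

#' Read a pileup TSV (pos, A, C, G, T, N counts)
#' @param path input file.
#' @return data frame.
#' @export
read_pileup_tsv <- function(path) read.delim(path)

#' Scan a region for sigma-70 consensus promoters
#'
#' Both strands are scanned for `TTGACA <spacer> TATAAT` with total
#' Hamming mismatches at most `max_mismatches` and spacer length within
#' `spacer_range`.  Hits are sorted by mismatch count, then position.
#' When two hits on opposite strands overlap -- the opposed
#' early-promoter/repressor-promoter geometry of a P2-style immunity
#' region -- the pair is reported in the `opposing` attribute.
#'
#' @param region DNA string.
#' @param offset 0-based genome coordinate of the region's first base
#'   (hit coordinates are reported in genome space).
#' @param max_mismatches total allowed mismatches over both boxes.
#' @param spacer_range allowed spacer lengths (bp).
#' @return data frame of class `promoter_hits`: `start`, `end`
#'   (0-based half-open, genome space), `strand`, `minus35`, `spacer_len`,
#'   `minus10`, `mismatches`; attribute `opposing` lists overlapping
#'   opposite-strand pairs.
#' @export
promoter_scan <- function(region, offset = 0, max_mismatches = 3,
                          spacer_range = c(15, 19)) {
  region <- toupper(region)
  n <- nchar(region)
  if (n < 35) stop("region shorter than 35 bp")
  scan_one <- function(s, strand) {
    ch <- seq_chars(s)
    m35 <- seq_chars("TTGACA"); m10 <- seq_chars("TATAAT")
    hits <- list()
    for (i in 0:(nchar(s) - 12 - spacer_range[1])) {
      mm35 <- sum(ch[(i + 1):(i + 6)] != m35)
      if (mm35 > max_mismatches) next
      for (sp in spacer_range[1]:spacer_range[2]) {
        j <- i + 6 + sp
        if (j + 6 > nchar(s)) next
        mm10 <- sum(ch[(j + 1):(j + 6)] != m10)
        if (mm35 + mm10 > max_mismatches) next
        hits[[length(hits) + 1L]] <- data.frame(
          start_local = i, end_local = j + 6, strand = strand,
          minus35 = substr(s, i + 1, i + 6), spacer_len = sp,
          minus10 = substr(s, j + 1, j + 6), mismatches = mm35 + mm10)
      }
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  fwd <- scan_one(region, "+")
  rev <- scan_one(revcomp(region), "-")
  if (!is.null(rev)) {
    tmp <- n - rev$end_local
    rev$end_local <- n - rev$start_local
    rev$start_local <- tmp
  }
  hits <- rbind(fwd, rev)
  if (is.null(hits)) {
    hits <- data.frame(start = integer(), end = integer(),
                       strand = character(), minus35 = character(),
                       spacer_len = integer(), minus10 = character(),
                       mismatches = integer())
    attr(hits, "opposing") <- list()
    class(hits) <- c("promoter_hits", "data.frame")
    return(hits)
  }
  hits$start <- hits$start_local + offset
  hits$end <- hits$end_local + offset
  hits <- hits[order(hits$mismatches, hits$start),
               c("start", "end", "strand", "minus35", "spacer_len",
                 "minus10", "mismatches")]
  rownames(hits) <- NULL
  opposing <- list()
  if (nrow(hits) > 1) {
    for (i in seq_len(nrow(hits) - 1)) for (j in (i + 1):nrow(hits)) {
      if (hits$strand[i] != hits$strand[j] &&
          intervals_overlap(hits$start[i], hits$end[i],
                            hits$start[j], hits$end[j]))
        opposing[[length(opposing) + 1L]] <- c(i, j)
    }
  }
  attr(hits, "opposing") <- opposing
  class(hits) <- c("promoter_hits", "data.frame")
  hits
}
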