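# Prophage localisation in a host replicon, attL/attR core-repeat
# discovery, and reconstruction checks for the host gene disrupted by
# integration.

#' Locate an integrated copy of a phage genome in a host replicon
#'
#' Anchors exact 31-mers sampled along the phage record in the host (in
#' both orientations), clusters co-linear anchors allowing one circular
#' rotation of the phage, and extends the boundaries base by base.  The
#' reported `phage_origin_offset` is the rotation relating the start of
#' the phage record to the left end of the prophage, so that downstream
#' attachment-site detection sees the true prophage ends.
#'
#' @param host,phage `GenomeRecord`s (`host` at least as long as
#'   `phage`).
#' @param min_identity minimum mean percent identity over the matched
#'   interval.
#' @param k anchor k-mer length.
#' @param anchor_step spacing of sampled anchors along the phage.
#' @return list of `ProphageLocus` objects (empty when no match covers
#'   at least half the phage at `min_identity`).
#' @export
locate_prophage <- function(host, phage, min_identity = 95, k = 31,
                            anchor_step = 200) {
  if (genome_length(host) < genome_length(phage))
    stop("host is shorter than phage")
  for (strand in c(1L, -1L)) {
    hseq <- if (strand == 1L) host$sequence else revcomp(host$sequence)
    loc <- locate_prophage_one(hseq, phage, min_identity, k, anchor_step)
    if (!is.null(loc)) {
      if (strand == -1L) {
        H <- genome_length(host)
        loc[c("start", "end")] <- c(H - loc$end, H - loc$start)
      }
      return(list(structure(c(list(host_genome_id = host$id,
                                   matched_phage_id = phage$id,
                                   strand = strand), loc),
                            class = "ProphageLocus")))
    }
  }
  list()
}

locate_prophage_one <- function(hseq, phage, min_identity, k, anchor_step) {
  L <- genome_length(phage)
  pseq <- phage$sequence
  apos <- unique(c(seq(0L, L - k, by = anchor_step), L - k))
  anchors_h <- integer(); anchors_p <- integer()
  hdna <- Biostrings::DNAString(hseq)
  for (p0 in apos) {
    kmer <- substr0(pseq, p0, p0 + k)
    m <- Biostrings::matchPattern(kmer, hdna)
    st <- BiocGenerics::start(m) - 1L
    if (length(st) == 0L || length(st) > 4L) next  # skip repetitive kmers
    anchors_h <- c(anchors_h, st)
    anchors_p <- c(anchors_p, rep(p0, length(st)))
  }
  if (length(anchors_h) < max(3L, length(apos) %/% 4L)) return(NULL)
  # co-linear clustering: host_pos - phage_pos is constant within an arm;
  # a rotated phage contributes two diagonals separated by ~L
  d <- anchors_h - anchors_p
  dmod <- ((d %% L) + L) %% L
  center <- as.integer(names(sort(table(dmod %/% 100L), decreasing = TRUE)[1])) * 100L
  keep <- abs(dmod - center) <= 150L | abs(dmod - center) >= L - 150L
  if (sum(keep) < max(3L, length(apos) %/% 4L)) return(NULL)
  ah <- anchors_h[keep]; ap <- anchors_p[keep]
  left_i <- which.min(ah); right_i <- which.max(ah)
  # extend outward with the phage read circularly
  circ <- function(x) ((x %% L) + L) %% L
  pch <- seq_chars(pseq); hch <- seq_chars(hseq)
  H <- length(hch)
  ext <- function(h0, p0, dir, limit) {
    n <- 0L
    while (n < limit) {
      h <- h0 + dir * (n + 1L)
      if (h < 0L || h >= H) break
      if (hch[h + 1L] != pch[circ(p0 + dir * (n + 1L)) + 1L]) break
      n <- n + 1L
    }
    n
  }
  slack <- as.integer(ceiling(0.05 * L))
  nleft <- ext(ah[left_i], ap[left_i], -1L,
               L + slack - ((ah[right_i] + k) - ah[left_i]))
  start <- ah[left_i] - nleft
  span0 <- (ah[right_i] + k) - start
  nright <- ext(ah[right_i] + k - 1L, ap[right_i] + k - 1L, +1L,
                max(0L, L + slack - span0))
  end <- ah[right_i] + k + nright
  if (end - start < 0.5 * L || end - start > L + slack) {
    if (end - start < 0.5 * L) return(NULL)
    end <- min(end, start + L + slack)
  }
  # rotation offset: record position aligned to the prophage left end
  x0 <- circ(ap[left_i] - (ah[left_i] - start))
  offset <- circ(L - x0)
  # identity over the matched interval (sampled every 7 bp for speed)
  idx <- seq.int(start, end - 1L, by = 7L)
  pid <- 100 * mean(hch[idx + 1L] == pch[circ(idx - start + x0) + 1L])
  if (pid < min_identity) return(NULL)
  list(start = as.integer(start), end = as.integer(end),
       phage_origin_offset = as.integer(offset),
       mean_identity = pid)
}

#' @export
print.ProphageLocus <- function(x, ...) {
  cat(sprintf(
    "<ProphageLocus %s: [%d,%d) strand %+d, phage %s rotated %d bp, id %.1f%%>\n",
    x$host_genome_id, x$start, x$end, x$strand, x$matched_phage_id,
    x$phage_origin_offset, x$mean_identity))
  invisible(x)
}

#' Find the attL/attR direct-repeat cores of a prophage
#'
#' Searches the two boundary neighbourhoods of a located prophage for
#' the longest direct repeat with at most `max_mismatch` mismatches in
#' which one copy spans the left prophage boundary and the other the
#' right boundary -- the attL/attR cores created by site-specific
#' integration.  When a host gene annotation overlaps either core, it
#' is reported as the disrupted gene.  Boundary positions are treated
#' with a small tolerance so the result is robust to a few bp of
#' anchor-extension slop.
#'
#' @param host `GenomeRecord` carrying the prophage.
#' @param locus a `ProphageLocus`.
#' @param flank bp examined on each side of each boundary.
#' @param min_core minimum repeat core length.
#' @param max_mismatch maximum mismatches between the two cores.
#' @param boundary_tol bp of allowed slop between a core and its
#'   boundary.
#' @param max_core longest core considered (bounds the scan).
#' @return an `AttSite`, or `NULL` when no core of at least `min_core`
#'   exists (integration can in principle be core-less).
#' @export
find_att <- function(host, locus, flank = 500, min_core = 12,
                     max_mismatch = 2, boundary_tol = 10,
                     max_core = 150) {
  H <- genome_length(host)
  ls <- locus$start; le <- locus$end
  a0 <- max(0L, ls - flank); a1 <- min(H, ls + flank)
  b0 <- max(0L, le - flank); b1 <- min(H, le + flank)
  A <- seq_chars(substr0(host$sequence, a0, a1))
  B <- seq_chars(substr0(host$sequence, b0, b1))
  na <- length(A); nb <- length(B)
  # qualifying windows must intersect the boundary neighbourhoods, so
  # only columns within max_core + tol of each boundary can matter
  reach <- max_core + boundary_tol
  ctrA <- ls - a0                      # boundary position within A (1-based: +1)
  best <- NULL
  for (s in (-na + 1L):(nb - 1L)) {
    # align A[idxA] with B[idxA + s]; the B-boundary constraint fixes
    # the useful column range on this diagonal
    ctrB <- le - b0 - s
    lo_c <- max(1L, 1L - s, ctrA - reach + 1L, ctrB - reach + 1L)
    hi_c <- min(na, nb - s, ctrA + reach, ctrB + reach)
    if (hi_c - lo_c + 1L < min_core) next
    iA <- lo_c:hi_c
    eq <- A[iA] == B[iA + s]
    w <- best_window(eq, max_mismatch, min_core)
    for (row in w) {
      lo <- iA[1] + row[1] - 1L; hi <- iA[1] + row[2] - 1L
      attL <- c(a0 + lo - 1L, a0 + hi)          # 0-based half-open
      attR <- c(b0 + lo + s - 1L, b0 + hi + s)
      if (attL[1] > ls + boundary_tol || attL[2] < ls - boundary_tol) next
      if (attR[1] > le + boundary_tol || attR[2] < le - boundary_tol) next
      mm <- sum(!eq[row[1]:row[2]])
      len <- row[2] - row[1] + 1L
      if (is.null(best) || len > best$len ||
          (len == best$len && mm < best$mm) ||
          (len == best$len && mm == best$mm && attL[1] < best$attL[1])) {
        best <- list(attL = attL, attR = attR, mm = mm, len = len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  core <- substr0(host$sequence, best$attL[1], best$attL[2])
  f <- host$features
  dg <- NULL
  if (nrow(f)) {
    hit <- f$kind %in% c("CDS", "misc") &
      ((f$start < best$attL[2] & f$end > best$attL[1]) |
         (f$start < best$attR[2] & f$end > best$attR[1]) |
         # the disrupted gene's remnant typically abuts attR
         (abs(f$start - best$attR[2]) <= 2L))
    if (any(hit)) dg <- f[which(hit)[1], ]
  }
  structure(list(core_sequence = core,
                 attL_interval = as.integer(best$attL),
                 attR_interval = as.integer(best$attR),
                 n_core_mismatches = best$mm,
                 disrupted_gene = dg,
                 reconstruction_report = NULL),
            class = "AttSite")
}

# maximal-length windows of a logical vector with at most k FALSE,
# endpoints TRUE; returns list of c(lo, hi) (1-based, best first)
best_window <- function(eq, k, min_len) {
  n <- length(eq)
  out <- list()
  lo <- 1L; bad <- 0L
  best_len <- min_len - 1L
  for (hi in seq_len(n)) {
    if (!eq[hi]) bad <- bad + 1L
    while (bad > k) { if (!eq[lo]) bad <- bad - 1L; lo <- lo + 1L }
    l <- lo; h <- hi
    while (l <= h && !eq[l]) l <- l + 1L
    while (h >= l && !eq[h]) h <- h - 1L
    if (h - l + 1L > best_len) {
      best_len <- h - l + 1L
      out[[length(out) + 1L]] <- c(l, h)
    }
  }
  out
}

#' @export
print.AttSite <- function(x, ...) {
  cat(sprintf("<AttSite: core %d bp '%s' (%d mismatch), attL [%d,%d) attR [%d,%d)%s>\n",
              nchar(x$core_sequence),
              if (nchar(x$core_sequence) <= 30) x$core_sequence
              else paste0(substr(x$core_sequence, 1, 27), "..."),
              x$n_core_mismatches,
              x$attL_interval[1], x$attL_interval[2],
              x$attR_interval[1], x$attR_interval[2],
              if (is.null(x$disrupted_gene)) "" else
                paste0(", disrupts ", x$disrupted_gene$locus_tag)))
  invisible(x)
}

#' Check reconstruction of the gene disrupted by integration
#'
#' The 3' remnant of the disrupted host gene sits just right of attR;
#' integration can place phage sequence upstream that restores the
#' gene's 5' end in frame.  This scans upstream of the remnant in
#' frame, codon by codon, until a start codon (ATG, or also GTG/TTG
#' when `alt_starts`) or an in-frame terminator is met, and reports
#' whether the frame is open to a start.  When the free phage record is
#' supplied, it also reports the first in-frame terminator past the
#' circularisation junction -- the codon that would truncate the
#' polypeptide in the circular phage -- and the phage-side region
#' upstream of the restored start where a driving promoter would have
#' to sit (coordinates only; promoter prediction is a separate scan).
#'
#' @param host `GenomeRecord` carrying the prophage (the lysogen).
#' @param att an `AttSite` with `disrupted_gene` set.
#' @param alt_starts also accept GTG/TTG start codons.
#' @param phage optional free phage `GenomeRecord` (record start at the
#'   attP core, as deposited).
#' @param locus optional `ProphageLocus` (needed to map lysogen
#'   positions onto the circular phage).
#' @param max_scan_codons upstream scan limit.
#' @return list of class `ReconstructionReport`: `frame_open`,
#'   `start_pos` (0-based on the lysogen) and `start_codon` when open,
#'   `blocking_stop_pos` otherwise, `terminator_offset` (nt from the
#'   circularisation junction to the first in-frame stop, when `phage`
#'   given), and `promoter_search_region`.
#' @export
check_reconstruction <- function(host, att, alt_starts = TRUE,
                                 phage = NULL, locus = NULL,
                                 max_scan_codons = 400) {
  if (is.null(att$disrupted_gene)) stop("attachment site has no disrupted gene")
  starts <- if (alt_starts) c("ATG", "GTG", "TTG") else "ATG"
  rs <- att$disrupted_gene$start
  # honour an annotated codon phase on the remnant, if present
  phase <- 0L
  note <- att$disrupted_gene$note
  if (!is.na(note) && grepl("phase=", note))
    phase <- as.integer(sub("^.*phase=(\\d).*$", "\\1", note))
  frame0 <- rs + phase            # first complete codon of the remnant
  seqc <- host$sequence
  frame_open <- FALSE; start_pos <- NA_integer_; start_codon <- NA_character_
  blocking <- NA_integer_
  for (t in seq_len(max_scan_codons)) {
    q <- frame0 - 3L * t
    if (q < 0L) break
    codon <- substr0(seqc, q, q + 3L)
    if (codon %in% STOP_CODONS) { blocking <- q; break }
    if (codon %in% starts) {
      frame_open <- TRUE; start_pos <- q; start_codon <- codon; break
    }
  }
  terminator_offset <- NA_integer_
  if (!is.null(phage) && !is.null(locus)) {
    L <- genome_length(phage)
    # lysogen position -> original phage coordinate (prophage left end
    # corresponds to phage position 0 of the deposited record)
    anchor <- if (frame_open) start_pos else frame0
    o <- ((anchor - locus$start) %% L + L) %% L
    circ_seq <- paste0(phage$sequence, phage$sequence)
    for (t in 0:max_scan_codons) {
      q <- o + 3L * t
      codon <- substr0(circ_seq, q, q + 3L)
      if (codon %in% STOP_CODONS) {
        # offset measured from the circularisation junction (record
        # start) to the stop codon, within the wrapped region
        terminator_offset <- as.integer(q %% L)
        break
      }
    }
  }
  promoter_region <- if (frame_open)
    c(max(0L, start_pos - 150L), start_pos) else NULL
  structure(list(frame_open = frame_open, start_pos = start_pos,
                 start_codon = start_codon,
                 blocking_stop_pos = blocking,
                 terminator_offset = terminator_offset,
                 promoter_search_region = promoter_region),
            class = "ReconstructionReport")
}

#' @export
print.ReconstructionReport <- function(x, ...) {
  cat(sprintf("<Reconstruction: frame %s%s%s>\n",
              if (x$frame_open) "OPEN" else "closed",
              if (x$frame_open) sprintf(" to %s at %d", x$start_codon, x$start_pos)
              else if (!is.na(x$blocking_stop_pos))
                sprintf(" (stop at %d)", x$blocking_stop_pos) else "",
              if (!is.na(x$terminator_offset))
                sprintf(", circular-phage stop at +%d nt", x$terminator_offset)
              else ""))
  invisible(x)
}

#' GFF3 emission of a prophage locus and its attachment sites
#'
#' @param locus a `ProphageLocus`.
#' @param att an `AttSite` or `NULL`.
#' @param path output file.
#' @export
write_prophage_gff <- function(locus, att, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tphagemosaic\tprophage\t%d\t%d\t.\t%s\t.\tID=prophage;phage=%s;offset=%d",
                     locus$host_genome_id, locus$start + 1L, locus$end,
                     if (locus$strand > 0) "+" else "-",
                     locus$matched_phage_id, locus$phage_origin_offset))
  if (!is.null(att)) {
    lines <- c(lines,
      sprintf("%s\tphagemosaic\tattL\t%d\t%d\t.\t+\t.\tID=attL;core=%s",
              locus$host_genome_id, att$attL_interval[1] + 1L,
              att$attL_interval[2], att$core_sequence),
      sprintf("%s\tphagemosaic\tattR\t%d\t%d\t.\t+\t.\tID=attR;mismatches=%d",
              locus$host_genome_id, att$attR_interval[1] + 1L,
              att$attR_interval[2], att$n_core_mismatches))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Human-readable junction alignment block
#'
#' A text block showing the attL and attR neighbourhoods stacked over
#' the core, in the style of an attachment-figure panel.
#'
#' @param host `GenomeRecord`; `att` an `AttSite`; `pad` context bp.
#' @param att an `AttSite`.
#' @param pad context bp shown on each side of the cores.
#' @return character vector of lines.
#' @export
format_att_block <- function(host, att, pad = 20) {
  l <- att$attL_interval; r <- att$attR_interval
  line <- function(iv) sprintf(
    "%9d  %s[%s]%s",
    iv[1] + 1L,
    substr0(host$sequence, max(0, iv[1] - pad), iv[1]),
    substr0(host$sequence, iv[1], iv[2]),
    substr0(host$sequence, iv[2], min(genome_length(host), iv[2] + pad)))
  c(sprintf("att core: %s (%d bp, %d mismatch between copies)",
            att$core_sequence, nchar(att$core_sequence),
            att$n_core_mismatches),
    paste0("attL ", line(l)), paste0("attR ", line(r)))
}
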