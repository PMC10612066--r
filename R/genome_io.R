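# Genome containers, coordinate conventions, translation and FASTA IO.
#
# Internal coordinates are 0-based half-open [start, end), strand +1/-1.
# GenBank emission/parsing converts to and from 1-based inclusive.
# Features on circular records may wrap: they carry end > genome length
# and wraps = TRUE; positions are resolved modulo the length.

#' Construct a genome record
#'
#' A `GenomeRecord` holds one replicon: its id, uppercase DNA sequence,
#' topology and an annotation table.  Features use 0-based half-open
#' intervals; wrapping features on circular records carry
#' `end > nchar(sequence)` and `wraps = TRUE`.
#'
#' @param id accession-like identifier.
#' @param sequence DNA string over `A,C,G,T,N` (coerced to upper case).
#' @param topology `"linear"` or `"circular"`.
#' @param features data frame with columns `kind`, `start`, `end`,
#'   `strand`, `locus_tag`, `product`, `note`, `codon_table`, `wraps`.
#'   Missing columns are filled with defaults.  Rows are sorted stably
#'   by `start`.
#' @param definition free-text definition line.
#' @return an object of class `GenomeRecord`.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular"),
                          features = NULL, definition = "") {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence length must be >= 1")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains symbols outside {A,C,G,T,N}")
  features <- normalize_features(features, nchar(sequence), topology)
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features, definition = definition),
            class = "GenomeRecord")
}

empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             strand = integer(), locus_tag = character(),
             product = character(), note = character(),
             codon_table = integer(), wraps = logical(),
             stringsAsFactors = FALSE)
}

normalize_features <- function(features, len, topology) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  defaults <- list(kind = "misc", strand = 1L, locus_tag = NA_character_,
                   product = NA_character_, note = NA_character_,
                   codon_table = 11L, wraps = FALSE)
  for (nm in names(defaults))
    if (is.null(features[[nm]])) features[[nm]] <- defaults[[nm]]
  features <- features[, names(empty_features())]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  bad <- features$start < 0L | features$start >= features$end |
    (!features$wraps & features$end > len)
  if (any(bad))
    stop("feature coordinates outside [0, genome length): rows ",
         paste(which(bad), collapse = ", "))
  if (any(features$wraps) && topology != "circular")
    stop("wrapping features are only valid on circular records")
  features[order(features$start), , drop = FALSE]
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("<GenomeRecord %s: %d bp, %s, %d features>\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features)))
  invisible(x)
}

#' Genome length in bp
#' @param g a `GenomeRecord`.
#' @return integer length.
#' @export
genome_length <- function(g) nchar(g$sequence)

# sequence of a feature row, honouring wrap and strand
feature_seq <- function(g, feat) {
  len <- genome_length(g)
  if (isTRUE(feat$wraps)) {
    s <- paste0(g$sequence, g$sequence)
    nt <- substr0(s, feat$start, feat$end)
  } else {
    nt <- substr0(g$sequence, feat$start, feat$end)
  }
  if (feat$strand < 0L) nt <- revcomp(nt)
  nt
}

#' G+C content of a genome
#'
#' 100 * (#G + #C) / (#A + #C + #G + #T); `N` is excluded from the
#' denominator.  All-`N` sequences raise an error.
#'
#' @param g a `GenomeRecord` (or a plain DNA string).
#' @param digits decimal places for the returned percentage (default 1,
#'   the precision at which genome reports state it).
#' @return percentage in `[0, 100]`.
#' @export
gc_content <- function(g, digits = 1) {
  s <- if (inherits(g, "GenomeRecord")) g$sequence else toupper(g)
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
  acgt <- sum(f[c("A", "C", "G", "T")])
  if (acgt == 0L) stop("gc_content undefined: no A/C/G/T in sequence")
  round(100 * sum(f[c("G", "C")]) / acgt, digits)
}

#' Rotate a circular-origin genome
#'
#' Returns a record whose sequence starts at position `offset` (0-based)
#' of the input.  Features are shifted accordingly; features that come to
#' straddle the new origin become wrapping features.  Phage genomes
#' deposited "linear with known origin" are rotated explicitly rather
#' than matched under implicit permutation.
#'
#' @param g a `GenomeRecord`.
#' @param offset 0-based position that becomes the new first base.
#' @return a rotated `GenomeRecord`.
#' @export
rotate_genome <- function(g, offset) {
  len <- genome_length(g)
  offset <- ((offset %% len) + len) %% len
  if (offset == 0L) return(g)
  s <- paste0(substr0(g$sequence, offset, len), substr0(g$sequence, 0, offset))
  f <- g$features
  if (nrow(f)) {
    ns <- (f$start - offset) %% len
    width <- f$end - f$start
    f$start <- as.integer(ns)
    f$end <- as.integer(ns + width)
    f$wraps <- f$end > len
  }
  genome_record(g$id, s, g$topology, f, g$definition)
}

#' Extract the annotated proteome of a genome
#'
#' Translates every CDS feature with its codon table (default 11,
#' bacterial), reverse-complementing minus-strand CDS first.  Records are
#' returned in gene order along the genome and carry `gene_index`.  A CDS
#' whose length is not divisible by 3 is translated over its longest
#' in-frame prefix and flagged `"possible frameshift/pseudogene"` -- the
#' flag downstream DGR analysis reads for a broken reverse transcriptase.
#' Terminal stops are stripped; an internal stop truncates the
#' translation and adds an `"internal stop"` flag.
#'
#' @param g a `GenomeRecord` with at least one CDS feature.
#' @return list of `ProteinRecord` objects (class `Proteome`).
#' @export
extract_proteome <- function(g) {
  cds <- g$features[g$features$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("genome has no CDS features")
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    feat <- cds[i, ]
    nt <- feature_seq(g, feat)
    flags <- character()
    if (nchar(nt) %% 3L != 0L) {
      flags <- c(flags, "possible frameshift/pseudogene")
      nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
    }
    aa <- translate_nt(nt, feat$codon_table)
    # strip terminal stop; truncate at an internal stop
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE)) {
      flags <- c(flags, "internal stop")
      aa <- sub("\\*.*$", "", aa)
    }
    tag <- if (is.na(feat$locus_tag)) sprintf("cds%03d", i) else feat$locus_tag
    out[[i]] <- structure(
      list(id = paste0(g$id, "|", tag), genome_id = g$id, locus_tag = tag,
           gene_index = i, aa_sequence = aa, start = feat$start,
           end = feat$end, strand = feat$strand,
           product = feat$product, flags = flags),
      class = "ProteinRecord")
  }
  structure(out, class = "Proteome")
}

.code_cache <- new.env(parent = emptyenv())
genetic_code <- function(table = 11L) {
  key <- as.character(table)
  if (is.null(.code_cache[[key]]))
    .code_cache[[key]] <- Biostrings::getGeneticCode(key)
  .code_cache[[key]]
}

translate_nt <- function(nt, table = 11L) {
  # direct codon lookup; ~40x faster than building XString objects
  code <- genetic_code(table)
  n <- nchar(nt) %/% 3L
  cods <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- code[cods]
  aa[is.na(aa)] <- "X"   # ambiguous codons
  paste(aa, collapse = "")
}

#' @export
print.Proteome <- function(x, ...) {
  cat(sprintf("<Proteome: %d proteins from %s>\n", length(x),
              if (length(x)) x[[1]]$genome_id else "?"))
  invisible(x)
}

#' Write a proteome to FASTA
#'
#' Definition lines are `<genome_id>|<locus_tag>|<gene_index>` so that
#' downstream labels carry their provenance; sequences wrap at 70
#' columns.
#'
#' @param proteome list of `ProteinRecord`s.
#' @param path output file.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(vapply(proteome, function(p) p$aa_sequence, ""))
  names(aa) <- vapply(proteome, function(p)
    paste(p$genome_id, p$locus_tag, p$gene_index, sep = "|"), "")
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Read a DNA FASTA file into genome records
#'
#' @param path FASTA file; each sequence becomes one linear record.
#' @return list of `GenomeRecord`s without features.
#' @export
read_fasta_genomes <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(x), function(i)
    genome_record(sub("\\s.*$", "", names(x)[i]), as.character(x[[i]])))
}

#' Write genome records to FASTA (70-column wrap)
#' @param genomes list of `GenomeRecord`s.
#' @param path output file.
#' @export
write_fasta_genomes <- function(genomes, path) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  x <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$sequence, ""))
  names(x) <- vapply(genomes, function(g) g$id, "")
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
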