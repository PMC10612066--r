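# GenBank flat-file reading and writing.
#
# Only the subset of the format the pipeline relies on is implemented:
# LOCUS (name, length, topology), DEFINITION, the FEATURES table with
# simple, complement(), join() and complement(join()) locations, and
# ORIGIN.  GenBank 1-based inclusive coordinates are converted to the
# package's 0-based half-open convention; join() parts that run across
# the origin of a circular record become wrapping intervals.

#' Read a GenBank flat file
#'
#' @param path path to a GenBank flat file with at least LOCUS and
#'   ORIGIN sections per record.
#' @return list of [genome_record()] objects, one per LOCUS.  A CDS
#'   whose `/translation` length disagrees with its location by more
#'   than the terminal stop triggers a warning; the location is trusted.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- list()
  for (r in seq_along(ends)) {
    chunk <- lines[starts[r]:ends[r]]
    chunk <- chunk[!grepl("^//\\s*$", chunk)]
    if (!any(nzchar(trimws(chunk)))) next
    records[[length(records) + 1L]] <- parse_genbank_record(chunk)
  }
  records
}

parse_genbank_record <- function(lines) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("GenBank record without LOCUS line")
  locus <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[locus_i[1]])),
                    "\\s+")[[1]]
  id <- locus[1]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  def_i <- grep("^DEFINITION", lines)
  definition <- if (length(def_i)) trimws(sub("^DEFINITION", "", lines[def_i[1]])) else ""

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) stop("GenBank record without ORIGIN section")
  seq_lines <- lines[(origin_i[1] + 1L):length(lines)]
  seq_parts <- character(length(seq_lines))
  for (k in seq_along(seq_lines)) {
    ln <- seq_lines[k]
    if (!nzchar(trimws(ln))) next
    if (!grepl("^\\s*\\d+\\s", ln))
      stop(sprintf("malformed ORIGIN line %d: '%s'", origin_i[1] + k, ln))
    body <- gsub("[0-9 ]", "", ln)
    if (grepl("[^ACGTNacgtn]", body))
      stop(sprintf("malformed ORIGIN line %d: non-nucleotide symbols", origin_i[1] + k))
    seq_parts[k] <- body
  }
  sequence <- toupper(paste(seq_parts, collapse = ""))

  feat_i <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_i)) {
    fl <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    fl <- fl[nzchar(trimws(fl))]
    # a new feature starts at column 6; qualifiers/continuations at 22
    is_head <- grepl("^\\s{5}\\S", fl) & !grepl("^\\s{21}", fl)
    idx <- cumsum(is_head)
    for (fi in seq_len(max(idx, 0))) {
      block <- fl[idx == fi]
      if (trimws(substr(block[1], 1, 21)) == "source") next
      features <- rbind(features,
                        parse_feature_block(block, nchar(sequence), topology))
    }
  }
  g <- genome_record(id, sequence, topology, features, definition)
  check_translations(g)
  g
}

parse_feature_block <- function(block, len, topology) {
  head_line <- block[1]
  kind_raw <- trimws(substr(head_line, 1, 21))
  loc <- trimws(substr(head_line, 22, nchar(head_line)))
  rest <- block[-1]
  # location may continue onto following lines until the first qualifier
  qual_start <- grep("^\\s*/", rest)
  n_cont <- if (length(qual_start)) qual_start[1] - 1L else length(rest)
  if (n_cont > 0) {
    loc <- paste0(loc, paste(trimws(rest[seq_len(n_cont)]), collapse = ""))
    rest <- rest[-seq_len(n_cont)]
  }
  quals <- parse_qualifiers(rest)
  parsed <- parse_location(loc, len, topology)
  kind <- if (kind_raw %in% c("CDS", "rRNA", "tRNA", "repeat_region",
                              "misc_feature", "gene")) kind_raw else "misc"
  kind <- switch(kind, repeat_region = "repeat", misc_feature = "misc",
                 gene = "misc", kind)
  data.frame(kind = kind, start = parsed$start, end = parsed$end,
             strand = parsed$strand,
             locus_tag = quals[["locus_tag"]] %||% NA_character_,
             product = quals[["product"]] %||% NA_character_,
             note = build_note(quals),
             codon_table = as.integer(quals[["transl_table"]] %||% 11L),
             wraps = parsed$wraps, stringsAsFactors = FALSE)
}

build_note <- function(quals) {
  note <- quals[["note"]] %||% NA_character_
  tr <- quals[["translation"]]
  if (!is.null(tr)) {
    tr <- gsub("\\s", "", tr)
    note <- if (is.na(note)) paste0("translation=", tr)
    else paste0(note, ";translation=", tr)
  }
  note
}

parse_qualifiers <- function(lines) {
  quals <- list()
  cur <- NULL
  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      m <- regmatches(t, regexec("^/([A-Za-z_]+)=?(.*)$", t))[[1]]
      cur <- m[2]
      val <- gsub('^"|"$', "", m[3])
      quals[[cur]] <- val
    } else if (!is.null(cur)) {
      sep <- if (cur == "translation") "" else " "
      quals[[cur]] <- paste0(quals[[cur]], sep, gsub('"$', "", t))
    }
  }
  quals
}

parse_location <- function(loc, len, topology) {
  strand <- 1L
  x <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- -1L
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  wraps <- FALSE
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    iv <- t(vapply(parts, parse_simple_interval, c(0, 0)))
    # contiguity across the origin of a circular record -> wrapping
    if (nrow(iv) == 2 && topology == "circular" &&
        iv[1, 2] == len && iv[2, 1] == 1) {
      start <- iv[1, 1] - 1L
      end <- len + iv[2, 2]
      wraps <- TRUE
    } else {
      start <- min(iv[, 1]) - 1L
      end <- max(iv[, 2])
    }
  } else {
    iv <- parse_simple_interval(x)
    start <- iv[1] - 1L
    end <- iv[2]
  }
  list(start = as.integer(start), end = as.integer(end),
       strand = strand, wraps = wraps)
}

parse_simple_interval <- function(x) {
  x <- gsub("[<>]", "", x)
  if (grepl("^\\d+$", x)) return(c(as.numeric(x), as.numeric(x)))
  m <- regmatches(x, regexec("^(\\d+)\\.\\.(\\d+)$", x))[[1]]
  if (length(m) != 3) stop("cannot parse location element: ", x)
  c(as.numeric(m[2]), as.numeric(m[3]))
}

check_translations <- function(g) {
  cds <- g$features[g$features$kind == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    note <- cds$note[i]
    if (is.na(note) || !grepl("translation=", note)) next
    tr <- sub("^.*translation=([A-Za-z*]+).*$", "\\1", note)
    expect_aa <- (cds$end[i] - cds$start[i]) %/% 3L - 1L  # minus stop
    if (abs(nchar(tr) - expect_aa) > 1L)
      warning(sprintf(
        "CDS %s: /translation length %d disagrees with location (%d aa); location trusted",
        cds$locus_tag[i] %||% i, nchar(tr), expect_aa), call. = FALSE)
  }
  invisible(g)
}

#' Write genome records as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/FEATURES/ORIGIN with 1-based inclusive
#' coordinates.  Wrapping features on circular records are written as
#' `join(a..len,1..b)`; minus-strand features as `complement()`.
#'
#' @param genomes a `GenomeRecord` or list of them.
#' @param path output file.
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "GenomeRecord")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) write_genbank_record(g, con)
  invisible(path)
}

write_genbank_record <- function(g, con) {
  len <- genome_length(g)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s PHG",
                     g$id, len, g$topology), con)
  if (nzchar(g$definition))
    writeLines(paste0("DEFINITION  ", g$definition), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     %-16s1..%d", "source", len), con)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    kind <- switch(f$kind[i], "repeat" = "repeat_region",
                   misc = "misc_feature", f$kind[i])
    loc <- format_location(f$start[i], f$end[i], f$strand[i], f$wraps[i], len)
    writeLines(sprintf("     %-16s%s", kind, loc), con)
    if (!is.na(f$locus_tag[i]))
      writeLines(sprintf('                     /locus_tag="%s"', f$locus_tag[i]), con)
    if (!is.na(f$product[i]))
      writeLines(sprintf('                     /product="%s"', f$product[i]), con)
    if (!is.na(f$note[i]) && !grepl("^translation=", f$note[i]))
      writeLines(sprintf('                     /note="%s"',
                         sub(";?translation=.*$", "", f$note[i])), con)
    if (f$kind[i] == "CDS" && f$codon_table[i] != 1L)
      writeLines(sprintf("                     /transl_table=%d", f$codon_table[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$sequence)
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    line <- substr(s, p, min(p + 59L, len))
    blocks <- substring(line, seq(1, nchar(line), 10),
                        pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
    writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
}

format_location <- function(start, end, strand, wraps, len) {
  loc <- if (isTRUE(wraps)) {
    sprintf("join(%d..%d,1..%d)", start + 1L, len, end - len)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand < 0L) loc <- sprintf("complement(%s)", loc)
  loc
}
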