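# Synthetic-data generators.  Every downstream analysis is testable
# against these: a mosaic phage family with module-structured
# divergence, a DGR cassette mutated under the adenine-substitution
# paradigm, a lysogen with a duplicated attachment core inside a host
# gene, and mixed-variant read pileups.  All generators are pure
# functions of (config, seed).

aa_from_codon_table <- function() {
  code <- Biostrings::getGeneticCode("11")
  split(names(code), unname(code))
}

# codons excluding stops and, optionally, start-like codons
codon_pool <- function(exclude_starts = FALSE) {
  all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
               collapse = "")
  drop <- STOP_CODONS
  if (exclude_starts) drop <- c(drop, "ATG", "GTG", "TTG")
  setdiff(all, drop)
}

random_protein <- function(len) {
  paste(c("M", sample(setdiff(AA_SYMBOLS, c("X")), len - 1L,
                      replace = TRUE)), collapse = "")
}

# mutate a protein so expected identity to the input is `target` percent
diverge_protein <- function(aa, target) {
  ch <- seq_chars(aa)
  p <- 1 - target / 100
  hit <- which(runif(length(ch)) < p)
  hit <- setdiff(hit, 1L)  # keep the initiator methionine
  for (i in hit) ch[i] <- sample(setdiff(setdiff(AA_SYMBOLS, "X"), ch[i]), 1)
  list(aa = paste(ch, collapse = ""),
       realized_identity = 100 * (1 - length(hit) / length(ch)))
}

back_translate <- function(aa, codons_by_aa) {
  ch <- seq_chars(aa)
  cods <- vapply(ch, function(a) {
    pool <- codons_by_aa[[a]]
    pool[sample.int(length(pool), 1L)]
  }, "")
  paste0(paste(cods, collapse = ""), sample(STOP_CODONS, 1))
}

#' Configuration for the mosaic-family generator
#'
#' Defaults emulate the four-module divergence contrast of a small
#' temperate myovirus against two reference lineages: a nonstructural
#' module nearly identical to reference 1 (recent block exchange), a
#' head+connector module equidistant from both, a tail module closer to
#' reference 1 than reference 2, and an antireceptor module unrelated
#' to either.  `NA` targets mean "unrelated" (fresh random proteins).
#'
#' @param n_genes named integer vector, genes per module.
#' @param mean_prot_len mean protein length (aa).
#' @param identity_targets matrix (modules x lineages) of percent
#'   identities, `NA` = unrelated.
#' @param recombination list of events
#'   `list(module =, donor =, identity =)` applied to the query.
#' @param seed mandatory integer seed.
#' @return list of class `MosaicConfig`.
#' @export
mosaic_config <- function(n_genes = c(nonstructural = 12, head_connector = 10,
                                      tail = 10, antireceptor_dgr = 8),
                          mean_prot_len = 100,
                          identity_targets = NULL,
                          recombination = list(),
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(identity_targets)) {
    identity_targets <- rbind(nonstructural = c(92, 35),
                              head_connector = c(45, 45),
                              tail = c(33, 13),
                              antireceptor_dgr = c(NA, NA))
    colnames(identity_targets) <- c("REF1", "REF2")
  }
  stopifnot(all(rownames(identity_targets) == names(n_genes)))
  structure(list(n_genes = n_genes, mean_prot_len = mean_prot_len,
                 identity_targets = identity_targets,
                 recombination = recombination, seed = seed),
            class = "MosaicConfig")
}

#' Generate a mosaic phage family with known module structure
#'
#' Simulates an ancestral proteome, evolves one reference proteome per
#' lineage to the per-module identity targets (each site substituted
#' independently, so the realized identity is unbiased for the target),
#' optionally applies block recombinations to the query, back-translates
#' everything with uniform synonymous codon choice (table 11), and
#' assembles annotated genome records.
#'
#' @param cfg a [mosaic_config()].
#' @return list with `query` (`GenomeRecord`), `references` (named
#'   list of `GenomeRecord`s), and `truth`: module boundary table and
#'   per-gene realized identities.
#' @export
gen_mosaic <- function(cfg) {
  stopifnot(inherits(cfg, "MosaicConfig"))
  with_seed(cfg$seed, {
    codons_by_aa <- aa_from_codon_table()
    mods <- names(cfg$n_genes)
    lineages <- colnames(cfg$identity_targets)
    n_total <- sum(cfg$n_genes)
    gene_module <- rep(mods, cfg$n_genes)
    lens <- pmax(60L, rpois(n_total, cfg$mean_prot_len))
    ancestor <- vapply(lens, random_protein, "")
    query <- ancestor
    realized <- matrix(NA_real_, n_total, length(lineages),
                       dimnames = list(NULL, lineages))
    refs_aa <- list()
    for (lg in lineages) {
      aa <- character(n_total)
      for (gi in seq_len(n_total)) {
        t <- cfg$identity_targets[gene_module[gi], lg]
        if (is.na(t)) {
          aa[gi] <- random_protein(max(60L, rpois(1, cfg$mean_prot_len)))
          realized[gi, lg] <- NA_real_
        } else {
          d <- diverge_protein(ancestor[gi], t)
          aa[gi] <- d$aa
          realized[gi, lg] <- d$realized_identity
        }
      }
      refs_aa[[lg]] <- aa
    }
    recomb_log <- list()
    for (ev in cfg$recombination) {
      idx <- which(gene_module == ev$module)
      tgt <- ev$identity %||% 99
      for (gi in idx) {
        d <- diverge_protein(refs_aa[[ev$donor]][gi], tgt)
        query[gi] <- d$aa
        realized[gi, ev$donor] <- d$realized_identity
      }
      recomb_log[[length(recomb_log) + 1L]] <-
        data.frame(module = ev$module, donor = ev$donor, identity = tgt)
    }
    assemble <- function(aa_vec, id) {
      spacer <- function() random_dna(20L)
      seqs <- character(0); feats <- list(); pos <- 0L
      s <- spacer(); seqs <- s; pos <- nchar(s)
      for (gi in seq_along(aa_vec)) {
        nt <- back_translate(aa_vec[gi], codons_by_aa)
        feats[[gi]] <- data.frame(kind = "CDS", start = pos,
                                  end = pos + nchar(nt), strand = 1L,
                                  locus_tag = sprintf("%s_g%03d", id, gi),
                                  product = paste0("hypothetical protein (",
                                                   gene_module[gi], " module)"),
                                  codon_table = 11L)
        seqs <- c(seqs, nt, spacer())
        pos <- pos + nchar(nt) + 20L
      }
      genome_record(id, paste(seqs, collapse = ""), "linear",
                    do.call(rbind, feats))
    }
    boundaries <- data.frame(module = mods,
                             first = cumsum(c(1, head(cfg$n_genes, -1))),
                             last = cumsum(cfg$n_genes))
    list(query = assemble(query, "QRY"),
         references = setNames(lapply(lineages, function(lg)
           assemble(refs_aa[[lg]], lg)), lineages),
         truth = list(modules = boundaries,
                      gene_module = gene_module,
                      realized_identity = realized,
                      recombination = recomb_log))
  })
}

#' Configuration for the DGR cassette simulator
#'
#' Defaults model a BPP-1-scale template repeat: 135 bp with adenine
#' fraction 0.35 (about 47 adenines), per-adenine substitution
#' probability `theta`, and background substitution rate `epsilon` at
#' all non-terminal sites.  The three terminal bases on each end of the
#' repeat are held invariant (real TR/VR pairs keep their boundary
#' segments) and the bases flanking each copy are forced to differ so
#' the repeat has a well-defined extent.
#'
#' @param repeat_len repeat length in bp (multiple of 3).
#' @param adenine_fraction target adenine fraction of the template.
#' @param theta per-adenine A->N substitution probability.
#' @param epsilon per-site background substitution probability.
#' @param rt_frameshift plant a 1-bp insertion in the RT gene (the
#'   broken-prophage-RT case).
#' @param seed mandatory integer seed.
#' @return list of class `DGRSimConfig`.
#' @export
dgr_sim_config <- function(repeat_len = 135, adenine_fraction = 0.35,
                           theta = 0.1, epsilon = 0.01,
                           rt_frameshift = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(repeat_len %% 3 == 0, theta >= 0, theta <= 1,
            epsilon >= 0, epsilon <= 1)
  structure(list(repeat_len = repeat_len,
                 adenine_fraction = adenine_fraction, theta = theta,
                 epsilon = epsilon, rt_frameshift = rt_frameshift,
                 seed = seed),
            class = "DGRSimConfig")
}

# random repeat with target adenine fraction, stop-free in frame 0,
# fixed non-adenine termini
random_tr <- function(len, f) {
  repeat {
    ch <- ifelse(runif(len) < f, "A",
                 sample(c("C", "G", "T"), len, replace = TRUE))
    ch[1:3] <- c("G", "G", "C"); ch[(len - 2):len] <- c("G", "C", "C")
    s <- paste(ch, collapse = "")
    cods <- substring(s, seq(1, len - 2, 3), seq(3, len, 3))
    bad <- which(cods %in% STOP_CODONS)
    if (length(bad) == 0L) return(s)
    for (b in bad) {
      i <- (b - 1L) * 3L + sample.int(3L, 1L)
      ch[i] <- sample(c("C", "G"), 1L)
    }
    s <- paste(ch, collapse = "")
    cods <- substring(s, seq(1, len - 2, 3), seq(3, len, 3))
    if (!any(cods %in% STOP_CODONS)) return(s)
  }
}

# Invariant boundary width of simulated repeats: real TR/VR pairs keep
# conserved anchor segments at their ends (the 3'-end element that
# guides mutagenic homing), and the detector relies on the boundary
# being locally clean.
DGR_TERMINUS <- 9L

# apply the A->N paradigm plus background noise to a template repeat;
# the terminal DGR_TERMINUS bases on each side stay invariant
mutate_vr <- function(tr, theta, epsilon) {
  ch <- seq_chars(tr)
  n <- length(ch)
  core <- (DGR_TERMINUS + 1L):(n - DGR_TERMINUS)
  a_hits <- core[ch[core] == "A" & runif(length(core)) < theta]
  for (i in a_hits) ch[i] <- sample(c("C", "G", "T"), 1)
  e_hits <- core[runif(length(core)) < epsilon]
  for (i in e_hits) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  list(vr = paste(ch, collapse = ""), a_positions = a_hits,
       background_positions = e_hits)
}

# pick a base differing from `avoid` (and from `avoid2` when given)
other_base <- function(avoid, avoid2 = NULL) {
  pool <- setdiff(DNA_BASES, c(avoid, avoid2))
  pool[sample.int(length(pool), 1L)]
}

#' Generate a genome carrying a DGR cassette with known truth
#'
#' Plants the canonical cassette layout on the plus strand:
#' antireceptor CDS containing the variable region (VR), the accessory
#' variability determinant (avd) gene, then the template repeat (TR)
#' as an in-frame N-terminal extension of the reverse-transcriptase
#' CDS.  The VR is the TR mutated under the A->N paradigm
#' ([dgr_sim_config()]).
#'
#' @param cfg a [dgr_sim_config()].
#' @param genome_id id of the emitted record.
#' @return list with `genome` (`GenomeRecord`) and `truth`:
#'   `tr_interval`, `vr_interval` (0-based half-open), `tr`, `vr`
#'   sequences, mutated positions, and the expected conforming count.
#' @export
gen_dgr <- function(cfg, genome_id = "DGRSIM") {
  stopifnot(inherits(cfg, "DGRSimConfig"))
  with_seed(cfg$seed, {
    L <- cfg$repeat_len
    tr <- random_tr(L, cfg$adenine_fraction)
    mut <- mutate_vr(tr, cfg$theta, cfg$epsilon)
    vr <- mut$vr
    # antireceptor: ATG + 100 codons + VR + 33 codons + stop
    anti_nt <- paste0("ATG", random_codons(100L), vr, random_codons(33L),
                      sample(STOP_CODONS, 1))
    if (nchar(anti_nt) %% 3L != 0L)  # VR length is a multiple of 3
      stop("internal error: antireceptor frame")
    avd_nt <- paste0("ATG", random_codons(80L), sample(STOP_CODONS, 1))
    rt_body <- random_codons(200L)
    if (cfg$rt_frameshift)
      rt_body <- paste0(substr(rt_body, 1, 300), "G",
                        substr(rt_body, 301, nchar(rt_body)))
    rt_nt <- paste0("ATG", tr, rt_body, sample(STOP_CODONS, 1))
    pad_l <- random_dna(400L); gap1 <- random_dna(60L); gap2 <- random_dna(60L)
    pad_r <- random_dna(400L)
    seqs <- c(pad_l, anti_nt, gap1, avd_nt, gap2, rt_nt, pad_r)
    offs <- cumsum(c(0L, nchar(seqs)))
    anti_start <- offs[2]; avd_start <- offs[4]; rt_start <- offs[6]
    vr_start <- anti_start + 3L + 300L
    tr_start <- rt_start + 3L
    s <- paste(seqs, collapse = "")
    ch <- seq_chars(s)
    # force the bases flanking the VR to differ from those flanking the
    # TR, so the repeat extent is well defined; only the antireceptor
    # side is edited and its reading frame is kept stop-free
    fix_flank <- function(i_vr, i_tr) {
      if (ch[i_vr] != ch[i_tr]) return(invisible(NULL))
      cod_start <- i_vr - ((i_vr - (anti_start + 1L)) %% 3L)
      for (cand in setdiff(c("C", "G", "T", "A"), ch[i_tr])) {
        ch[i_vr] <<- cand
        cod <- paste(ch[cod_start:(cod_start + 2L)], collapse = "")
        if (!(cod %in% STOP_CODONS)) break
      }
      invisible(NULL)
    }
    for (d in 1:3) {                 # three guard columns on each side
      fix_flank(vr_start - d + 1L, tr_start - d + 1L)    # before each copy
      fix_flank(vr_start + L + d, tr_start + L + d)      # after each copy
    }
    s <- paste(ch, collapse = "")
    feats <- data.frame(
      kind = "CDS",
      start = c(anti_start, avd_start, rt_start),
      end = c(anti_start + nchar(anti_nt), avd_start + nchar(avd_nt),
              rt_start + nchar(rt_nt)),
      strand = 1L,
      locus_tag = c("gpA", "gpB", "gpC"),
      product = c("antireceptor (receptor-binding tail fiber domain)",
                  "accessory variability determinant (avd)",
                  "reverse transcriptase (mobile intron II family)"),
      codon_table = 11L)
    list(genome = genome_record(genome_id, s, "linear", feats),
         truth = list(
           tr_interval = c(tr_start, tr_start + L),
           vr_interval = c(vr_start, vr_start + L),
           tr = tr, vr = vr,
           a_positions = mut$a_positions,
           background_positions = mut$background_positions,
           n_conforming_planted = length(mut$a_positions) +
             sum(seq_chars(tr)[mut$background_positions] == "A"),
           rt_frameshift = cfg$rt_frameshift))
  })
}

#' Configuration for the lysogen generator
#'
#' Geometry of a site-specific integration event: a host replicon with
#' one target gene, an attachment core duplicated on both sides of the
#' inserted phage, an optional in-frame reconstruction of the target
#' gene's 5' end by the phage right arm, optional planted core
#' mismatches, an optional +1 frameshift at the right junction, and a
#' phage record rotated by a configurable offset.  Lengths default to
#' desk scale (60 kb host, 30 kb phage) so the whole round trip runs in
#' seconds; the geometry is identical at real scale.
#'
#' @param host_length host replicon length (bp).
#' @param phage_length free phage genome length (bp).
#' @param gene_start 0-based start of the target gene on the host.
#' @param gene_codons length of the target gene in codons (incl. start,
#'   excl. stop).
#' @param insertion_offset bases into the gene where the core begins
#'   (multiple of 3).
#' @param core_len attachment core length (0 = blunt insertion).
#' @param core_mismatches mismatches planted into the attR copy.
#' @param phage_rotation offset by which the emitted phage record is
#'   rotated relative to the deposited (core-first) orientation.
#' @param reconstruct phage right arm restores an in-frame start for
#'   the disrupted gene.
#' @param junction_frameshift plant a +1 insertion at the right
#'   junction (breaks the reconstructed frame).
#' @param circular_stop_offset position (bp past the circularisation
#'   junction, multiple of 3) of the planted in-frame terminator in the
#'   free phage.
#' @param seed mandatory integer seed.
#' @return list of class `LysogenConfig`.
#' @export
lysogen_config <- function(host_length = 60000, phage_length = 30000,
                           gene_start = 30000, gene_codons = 300,
                           insertion_offset = 180, core_len = 21,
                           core_mismatches = 0, phage_rotation = 0,
                           reconstruct = TRUE, junction_frameshift = FALSE,
                           circular_stop_offset = 90, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(insertion_offset %% 3 == 0, circular_stop_offset %% 3 == 0,
            core_len >= 0, insertion_offset + core_len < gene_codons * 3)
  if (core_len > gene_codons * 3) stop("core longer than the target gene")
  structure(list(host_length = host_length, phage_length = phage_length,
                 gene_start = gene_start, gene_codons = gene_codons,
                 insertion_offset = insertion_offset, core_len = core_len,
                 core_mismatches = core_mismatches,
                 phage_rotation = phage_rotation,
                 reconstruct = reconstruct,
                 junction_frameshift = junction_frameshift,
                 circular_stop_offset = circular_stop_offset, seed = seed),
            class = "LysogenConfig")
}

#' Generate a lysogen, its free phage record, and the integration truth
#'
#' The deposited-orientation phage record is `core + P`: it begins with
#' the attachment core, mirroring genome records reported with the same
#' end points as the prophage.  The lysogen is
#' `host[0..p) | core + P | core' | host[p+core..)`, with `p` the attB
#' position inside the target gene and `core'` the attR copy (with any
#' planted mismatches).  The emitted phage record is rotated by
#' `phage_rotation`.
#'
#' @param cfg a [lysogen_config()].
#' @return list with `lysogen`, `phage` (rotated record),
#'   `phage_deposited` (unrotated), `host` (without the prophage), and
#'   `truth` (locus interval, att intervals, core sequence, expected
#'   reconstruction start, ...).
#' @export
gen_lysogen <- function(cfg) {
  stopifnot(inherits(cfg, "LysogenConfig"))
  with_seed(cfg$seed, {
    gl <- cfg$gene_codons * 3L
    io <- cfg$insertion_offset
    c_len <- cfg$core_len
    # target gene; codons in the future attL-adjacent and core stretches
    # avoid start-like codons so the reconstructed start is unambiguous
    n_pre <- io %/% 3L              # codons before the insertion point
    gene <- paste0("ATG", random_codons(n_pre - 2L),
                   "GAC",           # codon just left of the core: forced
                                    # mismatch vs the phage arm's "CTA"
                   paste(sample(codon_pool(exclude_starts = TRUE),
                                (gl - io) %/% 3L, replace = TRUE),
                         collapse = ""),
                   sample(STOP_CODONS, 1))
    stopifnot(nchar(gene) == gl + 3L)
    host_seq <- paste0(random_dna(cfg$gene_start), gene,
                       random_dna(cfg$host_length - cfg$gene_start -
                                    nchar(gene)))
    core <- substr0(host_seq, cfg$gene_start + io,
                    cfg$gene_start + io + c_len)
    # phage record (deposited orientation): core + middle + right arm
    arm <- if (cfg$reconstruct)
      paste0("ATG", paste(sample(codon_pool(exclude_starts = TRUE), 58L,
                                 replace = TRUE), collapse = ""), "CTA")
    else random_dna(180L)
    mid_len <- cfg$phage_length - c_len - nchar(arm)
    mid <- random_dna(mid_len)
    # force mismatches right of the core: the first 3 bases of the
    # phage middle differ from the host bases right of attB; the first
    # base stays in {C,G} so the codon at the junction is never a stop
    host_right <- seq_chars(substr0(host_seq, cfg$gene_start + io + c_len,
                                    cfg$gene_start + io + c_len + 3L))
    force_mid_start <- function(mid) {
      mid_ch <- seq_chars(substr(mid, 1, 3))
      if (mid_ch[1] == host_right[1] || !(mid_ch[1] %in% c("C", "G")))
        mid_ch[1] <- setdiff(c("C", "G"), host_right[1])[1]
      for (t in 2:3) if (mid_ch[t] == host_right[t])
        mid_ch[t] <- other_base(host_right[t])
      paste0(paste(mid_ch, collapse = ""), substr(mid, 4, nchar(mid)))
    }
    mid <- force_mid_start(mid)
    # plant the circularisation terminator: reading frame entering the
    # record start from the right arm is codon-aligned with the core
    if (cfg$reconstruct && c_len %% 3L == 0L) {
      off <- cfg$circular_stop_offset - c_len  # position within mid
      if (off > 3L) {
        pre <- paste(sample(codon_pool(), off %/% 3L, replace = TRUE),
                     collapse = "")
        mid <- paste0(pre, "TAA", substr(mid, off + 4L, nchar(mid)))
        # re-force the junction mismatches clobbered by the rewrite
        mid <- force_mid_start(mid)
      }
    }
    phage_seq <- paste0(core, mid, arm)
    if (cfg$junction_frameshift) phage_seq <- paste0(phage_seq, "G")
    Lp <- nchar(phage_seq)
    # attR copy with planted mismatches (middle positions)
    corep <- seq_chars(core)
    mm_pos <- integer()
    if (cfg$core_mismatches > 0L && c_len > 0L) {
      mm_pos <- round(seq(c_len / 2, c_len / 2 + cfg$core_mismatches - 1))
      for (i in mm_pos) corep[i] <- other_base(corep[i])
    }
    core_r <- paste(corep, collapse = "")
    p <- cfg$gene_start + io
    lys_seq <- paste0(substr0(host_seq, 0, p), phage_seq, core_r,
                      substr0(host_seq, p + c_len, cfg$host_length))
    remnant_start <- p + Lp + c_len
    remnant_len <- gl + 3L - io - c_len
    lys_feats <- data.frame(
      kind = "CDS", start = remnant_start,
      end = remnant_start + remnant_len, strand = 1L,
      locus_tag = "dusA_rem",
      product = "tRNA dihydrouridine synthase family protein, 3' remnant (synthetic)",
      note = "phase=0")
    host_feats <- data.frame(
      kind = "CDS", start = cfg$gene_start, end = cfg$gene_start + gl + 3L,
      strand = 1L, locus_tag = "dusA",
      product = "tRNA dihydrouridine synthase family protein (synthetic)")
    phage_rec <- genome_record("PHAGE", phage_seq, "linear")
    list(
      lysogen = genome_record("LYSOGEN", lys_seq, "linear", lys_feats),
      phage = rotate_genome(phage_rec, cfg$phage_rotation),
      phage_deposited = phage_rec,
      host = genome_record("HOST", host_seq, "linear", host_feats),
      truth = list(
        locus_interval = c(p, p + Lp + c_len),
        attL_interval = c(p, p + c_len),
        attR_interval = c(p + Lp, p + Lp + c_len),
        core = core, core_mismatch_positions = mm_pos,
        phage_origin_offset = cfg$phage_rotation %% max(Lp, 1L),
        reconstruction_start = if (cfg$reconstruct)
          p + Lp - 180L - cfg$junction_frameshift else NA,
        remnant_interval = c(remnant_start, remnant_start + remnant_len),
        circular_stop_offset = if (cfg$reconstruct)
          cfg$circular_stop_offset else NA))
  })
}

#' Simulate a mixed-variant pileup at given sites
#'
#' Per-site alternate counts are Binomial(depth, mixture); remaining
#' reads carry the reference allele.  Emulates short-read pileups over
#' a lysogen partially induced during phage propagation, where a minor
#' fraction of reads matches the prophage variant.
#'
#' @param sites integer vector of (0-based) site positions.
#' @param depth reads per site.
#' @param mixture minor-variant fraction in `[0, 1]`.
#' @param seed mandatory integer seed.
#' @return list with `pileup` (data frame `pos,A,C,G,T,N`), `sites`
#'   (data frame `pos,ref,alt`), and `truth` (the drawn alternate
#'   counts).
#' @export
gen_pileup <- function(sites, depth, mixture, seed) {
  stopifnot(depth >= 1, mixture >= 0, mixture <= 1)
  with_seed(seed, {
    n <- length(sites)
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), "")
    altc <- rbinom(n, depth, mixture)
    pu <- data.frame(pos = sites, A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
    for (i in seq_len(n)) {
      pu[i, ref[i]] <- depth - altc[i]
      pu[i, alt[i]] <- pu[i, alt[i]] + altc[i]
    }
    list(pileup = pu,
         sites = data.frame(pos = sites, ref = ref, alt = alt,
                            row.names = NULL),
         truth = list(alt_counts = altc, mixture = mixture, depth = depth))
  })
}

#' Write a pileup table as TSV (pos, A, C, G, T, N)
#' @param pileup data frame as returned in `gen_pileup()$pileup`.
#' @param path output file.
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point for the simulators
#'
#' `Rscript -e 'phagemosaic::simulate_cli()' mosaic --seed 1 --out dir`
#' (subcommands: mosaic, dgr, lysogen, pileup).  `--seed` is mandatory.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @export
simulate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: simulate_cli() <mosaic|dgr|lysogen|pileup> --seed N [--out DIR]")
  sub <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i)) args[i[1] + 1L] else default
  }
  seed <- opt("seed")
  if (is.null(seed)) stop("--seed is mandatory")
  seed <- as.integer(seed)
  out <- opt("out", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  switch(sub,
    mosaic = {
      fam <- gen_mosaic(mosaic_config(seed = seed))
      write_genbank(c(list(fam$query), unname(fam$references)),
                    file.path(out, "mosaic.gbk"))
      write.table(data.frame(gene_index = seq_along(fam$truth$gene_module),
                             module = fam$truth$gene_module,
                             fam$truth$realized_identity),
                  file.path(out, "mosaic_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    },
    dgr = {
      sim <- gen_dgr(dgr_sim_config(seed = seed))
      write_genbank(sim$genome, file.path(out, "dgr.gbk"))
      writeLines(c(paste0("tr_interval\t", paste(sim$truth$tr_interval, collapse = "\t")),
                   paste0("vr_interval\t", paste(sim$truth$vr_interval, collapse = "\t"))),
                 file.path(out, "dgr_truth.tsv"))
    },
    lysogen = {
      sim <- gen_lysogen(lysogen_config(seed = seed))
      write_genbank(list(sim$lysogen, sim$phage), file.path(out, "lysogen.gbk"))
      writeLines(paste0("locus\t",
                        paste(sim$truth$locus_interval, collapse = "\t")),
                 file.path(out, "lysogen_truth.tsv"))
    },
    pileup = {
      sim <- gen_pileup(sites = c(100, 200, 300, 400, 500, 600),
                        depth = 200, mixture = 0.08, seed = seed)
      write_pileup_tsv(sim$pileup, file.path(out, "pileup.tsv"))
    },
    stop("unknown subcommand: ", sub))
  invisible(out)
}
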