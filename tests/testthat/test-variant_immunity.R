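# a compact annotated genome for differencing tests
diff_fixture <- function(seed = 17, n = 6000) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # plant two clean CDS on known frames
  cds1 <- paste0("ATG", phagemosaic:::random_codons(120),
                 sample(phagemosaic:::STOP_CODONS, 1))
  cds2 <- paste0("ATG", phagemosaic:::random_codons(200),
                 sample(phagemosaic:::STOP_CODONS, 1))
  s <- paste0(substr(s, 1, 1000), cds1,
              substr(s, 1001 + nchar(cds1), 3000), cds2,
              substr(s, 3001 + nchar(cds2), n))
  genome_record("FIX", substr(s, 1, n), features = data.frame(
    kind = "CDS", start = c(1000, 3000),
    end = c(1000 + nchar(cds1), 3000 + nchar(cds2)),
    strand = 1L, locus_tag = c("c1", "c2"),
    product = c("protein one", "antireceptor-like protein")))
}

mutate_at <- function(seqstr, pos0, base) {
  substr(seqstr, pos0 + 1, pos0 + 1) <- base
  seqstr
}

test_that("diff_genomes of identical records is empty", {
  a <- diff_fixture()
  d <- diff_genomes(a, a)
  expect_equal(nrow(d$variants), 0)
  expect_equal(d$n_outside_mask, 0)
})

test_that("mask bookkeeping mirrors the six-differences tabulation", {
  a <- diff_fixture()
  s <- a$sequence
  mask <- c(3000, 3620)              # the antireceptor-like CDS
  inside <- seq(3050, 3450, length.out = 8)
  outside <- c(200, 700, 1500, 2400, 4200, 5100)
  for (p in c(inside, outside)) {
    cur <- substr(s, p + 1, p + 1)
    s <- mutate_at(s, p, setdiff(c("A", "C", "G", "T"), cur)[1])
  }
  b <- genome_record("B", s)
  d <- diff_genomes(a, b, masks = list(antireceptor = mask))
  expect_equal(nrow(d$variants), 14)
  expect_equal(d$n_outside_mask, 6)
  expect_equal(sum(d$variants$in_mask), 8)
  expect_true(all(d$variants$mask[d$variants$in_mask] == "antireceptor"))
  expect_true(all(diff(d$variants$pos) > 0))
  # symmetric variant count
  d2 <- diff_genomes(b, a)
  expect_equal(nrow(d2$variants), nrow(d$variants))
})

test_that("effects are classified against the reference annotation", {
  a <- diff_fixture()
  # synonymous: third position of a codon in c1 where the change is silent
  cds_start <- 1000
  s <- a$sequence
  # find a codon whose third-base change is synonymous (Leu CTx)
  codons <- substring(s, seq(cds_start + 1, cds_start + 360, 3),
                      seq(cds_start + 3, cds_start + 362, 3))
  i_leu <- which(substr(codons, 1, 2) == "CT")[1]
  expect_false(is.na(i_leu))
  p_syn <- cds_start + (i_leu - 1) * 3 + 2
  cur <- substr(s, p_syn + 1, p_syn + 1)
  b1 <- genome_record("B", mutate_at(s, p_syn,
                                     setdiff(c("A", "C", "G", "T"), cur)[1]))
  d1 <- diff_genomes(a, b1)
  expect_equal(d1$variants$effect, "synonymous")

  # nonsense: turn a TGG (Trp) into TGA, or plant TAA directly
  i_trp <- which(codons == "TGG")
  if (length(i_trp)) {
    p_non <- cds_start + (i_trp[1] - 1) * 3 + 2
    b2 <- genome_record("B", mutate_at(s, p_non, "A"))
    expect_equal(diff_genomes(a, b2)$variants$effect, "nonsense")
  }

  # intergenic substitution
  b3 <- genome_record("B", mutate_at(s, 200,
                                     setdiff(c("A", "C", "G", "T"),
                                             substr(s, 201, 201))[1]))
  expect_equal(diff_genomes(a, b3)$variants$effect, "intergenic")

  # 1 bp deletion inside a CDS is a frameshift
  s_del <- paste0(substr(s, 1, 1050), substr(s, 1052, nchar(s)))
  d4 <- diff_genomes(a, genome_record("B", s_del))
  expect_equal(d4$variants$type, "deletion")
  expect_equal(d4$variants$effect, "frameshift")

  # 3 bp insertion inside a CDS is in frame (no frameshift call)
  s_ins <- paste0(substr(s, 1, 1050), "GGG", substr(s, 1051, nchar(s)))
  d5 <- diff_genomes(a, genome_record("B", s_ins))
  expect_equal(d5$variants$type, "insertion")
  expect_false(identical(d5$variants$effect, "frameshift"))
})

test_that("heavily diverged inputs are rejected with guidance", {
  a <- genome_record("A", with_seed_chars(18, 2000))
  b <- genome_record("B", with_seed_chars(19, 2000))
  expect_error(diff_genomes(a, b), "identity-profiling")
})

test_that("minimal VCF emission is well formed", {
  a <- diff_fixture()
  s <- mutate_at(a$sequence, 200, setdiff(c("A", "C", "G", "T"),
                                          substr(a$sequence, 201, 201))[1])
  d <- diff_genomes(a, genome_record("B", s))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(d, path)
  lines <- readLines(path)
  expect_match(lines[1], "VCFv4.2", fixed = TRUE)
  row <- strsplit(lines[4], "\t")[[1]]
  expect_length(row, 8)
  expect_equal(as.integer(row[2]), 201)  # 1-based POS
})

test_that("allele_fractions computes per-site minor fractions", {
  pu <- data.frame(pos = c(10, 20, 30), A = c(92, 100, 0),
                   C = c(8, 0, 0), G = c(0, 0, 0), T = c(0, 0, 0),
                   N = c(0, 0, 0))
  sites <- data.frame(pos = c(10, 20), alt = c("C", "C"))
  af <- allele_fractions(pu, sites)
  expect_equal(af$per_site$minor_fraction, c(0.08, 0))
  expect_equal(unname(af$summary), c(0, 0.08))
  # zero-coverage site flagged and excluded from the summary
  af2 <- allele_fractions(pu, data.frame(pos = c(10, 30), alt = c("C", "G")))
  expect_true(af2$per_site$zero_coverage[2])
  expect_equal(unname(af2$summary), c(0.08, 0.08))
  expect_error(allele_fractions(pu, data.frame(pos = 99, alt = "A")),
               "missing")
})

test_that("the allele-fraction estimator is unbiased", {
  mix <- 0.08; depth <- 200; n_rep <- 1000
  set.seed(131)
  fr <- rbinom(n_rep, depth, mix) / depth
  se <- sqrt(mix * (1 - mix) / depth / n_rep)
  expect_lt(abs(mean(fr) - mix), 3 * se)
})

test_that("pileup TSV round-trips through the reader", {
  sim <- gen_pileup(sites = c(5, 15), depth = 50, mixture = 0.1, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup_tsv(sim$pileup, path)
  back <- read_pileup_tsv(path)
  expect_equal(back$pos, c(5, 15))
  expect_equal(rowSums(back[, c("A", "C", "G", "T")]), c(50, 50))
})

test_that("promoter_scan finds sigma-70 boxes and opposing geometry", {
  spacer <- strrep("C", 17)
  region <- paste0(strrep("G", 12), "TTGACA", spacer, "TATAAT",
                   strrep("G", 12))
  hits <- promoter_scan(region, max_mismatches = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$minus10, "TATAAT")
  expect_equal(hits$strand, "+")
  # -10 box off by one base scores one mismatch
  region1 <- sub("TATAAT", "TATAAC", region)
  h1 <- promoter_scan(region1, max_mismatches = 1)
  expect_equal(h1$mismatches[1], 1)
  expect_equal(h1$minus10[1], "TATAAC")
  # hit set is strand-symmetric under reverse complement
  hrc <- promoter_scan(revcomp(region), max_mismatches = 0)
  expect_equal(nrow(hrc), 1)
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$start, nchar(region) - hits$end)
  # opposed promoters firing into each other: a rightwards promoter
  # (one -10 mismatch) overlapping a leftwards promoter by one base,
  # the P_e/P_c geometry of a P2-style immunity region
  both <- paste0("TTGACA", strrep("C", 17), "TATAAATTATA",
                 strrep("G", 17), "TGTCAA", strrep("C", 4))
  hb <- promoter_scan(both, max_mismatches = 1)
  expect_setequal(unique(hb$strand), c("-", "+"))
  expect_gte(length(attr(hb, "opposing")), 1)
  expect_error(promoter_scan("TTGACA"), "35")
})

test_that("positional offset places hits in genome coordinates", {
  region <- paste0("TTGACA", strrep("C", 17), "TATAAT", strrep("G", 8))
  h <- promoter_scan(region, offset = 5000, max_mismatches = 0)
  expect_equal(h$start[1], 5000)
  expect_equal(h$end[1], 5029)
})
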