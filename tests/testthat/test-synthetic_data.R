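test_that("all generators are pure functions of (config, seed)", {
  f1 <- gen_mosaic(mosaic_config(seed = 5))
  f2 <- gen_mosaic(mosaic_config(seed = 5))
  expect_identical(f1$query$sequence, f2$query$sequence)
  expect_identical(f1$truth, f2$truth)
  expect_false(identical(
    f1$query$sequence, gen_mosaic(mosaic_config(seed = 6))$query$sequence))

  d1 <- gen_dgr(dgr_sim_config(seed = 5))
  d2 <- gen_dgr(dgr_sim_config(seed = 5))
  expect_identical(d1$genome$sequence, d2$genome$sequence)

  cfg <- lysogen_config(host_length = 20000, phage_length = 9000,
                        gene_start = 10000, seed = 5)
  expect_identical(gen_lysogen(cfg)$lysogen$sequence,
                   gen_lysogen(cfg)$lysogen$sequence)

  p1 <- gen_pileup(1:4 * 10, 100, 0.1, seed = 5)
  p2 <- gen_pileup(1:4 * 10, 100, 0.1, seed = 5)
  expect_identical(p1$pileup, p2$pileup)
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_dgr(dgr_sim_config(seed = 9))); after <- runif(1)
  expect_identical(before, after)
})

test_that("seeds are mandatory and configs validate", {
  expect_error(mosaic_config(), "seed")
  expect_error(dgr_sim_config(), "seed")
  expect_error(lysogen_config(), "seed")
  expect_error(dgr_sim_config(theta = 2, seed = 1))
  expect_error(lysogen_config(core_len = 2000, gene_codons = 300,
                              insertion_offset = 180, seed = 1))
})

test_that("gen_dgr honours the A->N paradigm edge cases", {
  s0 <- gen_dgr(dgr_sim_config(theta = 0, epsilon = 0, seed = 12))
  expect_identical(s0$truth$tr, s0$truth$vr)
  # theta = 1: every non-terminal adenine substituted, all conforming
  s1 <- gen_dgr(dgr_sim_config(theta = 1, epsilon = 0, seed = 13))
  trc <- strsplit(s1$truth$tr, "")[[1]]
  g9 <- phagemosaic:::DGR_TERMINUS
  core <- (g9 + 1):(length(trc) - g9)
  nA <- sum(trc[core] == "A")
  cv <- classify_variants(s1$truth$tr, s1$truth$vr)
  expect_equal(cv$n_conforming, nA)
  expect_equal(cv$n_nonconforming, 0)
  expect_equal(length(s1$truth$a_positions), nA)
  # the VR sits inside the antireceptor CDS; the TR is the in-frame
  # N-terminal extension of the RT CDS
  g <- s1$genome
  cds <- g$features[g$features$kind == "CDS", ]
  anti <- cds[grepl("antireceptor", cds$product), ]
  rt <- cds[grepl("reverse transcriptase", cds$product), ]
  expect_true(s1$truth$vr_interval[1] >= anti$start &&
                s1$truth$vr_interval[2] <= anti$end)
  expect_equal(s1$truth$tr_interval[1], rt$start + 3)
  expect_equal((s1$truth$tr_interval[1] - rt$start) %% 3, 0)
})

test_that("conforming counts match the closed-form expectation", {
  theta <- 0.1; eps <- 0.01
  n_rep <- 400
  tot_conf <- 0; tot_A <- 0
  g9 <- phagemosaic:::DGR_TERMINUS
  for (s in 1:n_rep) {
    sim <- gen_dgr(dgr_sim_config(theta = theta, epsilon = eps,
                                  seed = 5000 + s))
    trc <- strsplit(sim$truth$tr, "")[[1]]
    core <- (g9 + 1):(length(trc) - g9)
    tot_A <- tot_A + sum(trc[core] == "A")
    cv <- classify_variants(sim$truth$tr, sim$truth$vr)
    tot_conf <- tot_conf + cv$n_conforming
  }
  # per-adenine conforming probability: theta, else epsilon to a non-A
  p_exp <- theta + (1 - theta) * eps
  se <- sqrt(p_exp * (1 - p_exp) / tot_A)
  expect_lt(abs(tot_conf / tot_A - p_exp), 3 * se)
})

test_that("gen_mosaic realizes its identity targets", {
  # all-100 targets give identical proteomes
  cfg <- mosaic_config(identity_targets = rbind(
    nonstructural = c(100, 100), head_connector = c(100, 100),
    tail = c(100, 100), antireceptor_dgr = c(100, 100)),
    seed = 14)
  colnames(cfg$identity_targets) <- c("REF1", "REF2")
  fam <- gen_mosaic(cfg)
  expect_equal(unname(fam$truth$realized_identity[, 1]), rep(100, 40))
  pq <- vapply(extract_proteome(fam$query), function(p) p$aa_sequence, "")
  pr <- vapply(extract_proteome(fam$references$REF1),
               function(p) p$aa_sequence, "")
  expect_identical(pq, pr)
  # realized identity is unbiased for the target (mean over genes)
  fam2 <- gen_mosaic(mosaic_config(seed = 15))
  ns <- fam2$truth$gene_module == "nonstructural"
  expect_lt(abs(mean(fam2$truth$realized_identity[ns, 1]) - 92), 3)
  # unrelated modules have no realized identity
  expect_true(all(is.na(
    fam2$truth$realized_identity[fam2$truth$gene_module ==
                                   "antireceptor_dgr", ])))
})

test_that("a recombination event overwrites the module from the donor", {
  cfg <- mosaic_config(
    identity_targets = rbind(nonstructural = c(35, 35),
                             head_connector = c(45, 45),
                             tail = c(33, 13),
                             antireceptor_dgr = c(NA, NA)),
    recombination = list(list(module = "nonstructural", donor = "REF2",
                              identity = 95)),
    seed = 16)
  colnames(cfg$identity_targets) <- c("REF1", "REF2")
  fam <- gen_mosaic(cfg)
  tab <- build_identity_table(extract_proteome(fam$query),
                              lapply(fam$references, extract_proteome))
  m <- module_definition("ns", 1, 12)
  s2 <- summarize_module(tab, m, "REF2")
  s1 <- summarize_module(tab, m, "REF1")
  expect_gt(s2$median_identity, 90)
  expect_true(is.na(s1$median_identity) || s1$median_identity < 60)
  expect_equal(fam$truth$recombination[[1]]$donor, "REF2")
})

test_that("gen_pileup hits its mixture edge cases", {
  p0 <- gen_pileup(c(10, 20), depth = 100, mixture = 0, seed = 2)
  af0 <- allele_fractions(p0$pileup, p0$sites)
  expect_equal(af0$per_site$minor_fraction, c(0, 0))
  p1 <- gen_pileup(c(10, 20), depth = 100, mixture = 1, seed = 2)
  af1 <- allele_fractions(p1$pileup, p1$sites)
  expect_equal(af1$per_site$minor_fraction, c(1, 1))
})

test_that("the simulate CLI writes its fixture files", {
  out <- withr::local_tempdir()
  simulate_cli(c("dgr", "--seed", "3", "--out", out))
  expect_true(file.exists(file.path(out, "dgr.gbk")))
  expect_length(read_genbank(file.path(out, "dgr.gbk")), 1)
  simulate_cli(c("pileup", "--seed", "3", "--out", out))
  expect_true(file.exists(file.path(out, "pileup.tsv")))
  expect_error(simulate_cli(c("dgr")), "--seed")
  expect_error(simulate_cli(c("wat", "--seed", "1")), "unknown")
})
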