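test_that("classify_variants follows the A->N paradigm column by column", {
  cv <- classify_variants("AAGCTA", "TCGCTG")
  # enumeration: mismatches at template positions 1, 2, 6, all A -> non-A
  expect_equal(cv$mismatches$position_in_TR, c(1, 2, 6))
  expect_equal(cv$mismatches$class, rep("conforming", 3))
  expect_equal(cv$n_conforming, 3)
  expect_equal(cv$n_nonconforming, 0)

  cv2 <- classify_variants("TGGA", "TCGA")
  expect_equal(cv2$mismatches$position_in_TR, 2)
  expect_equal(cv2$mismatches$class, "nonconforming")

  cv3 <- classify_variants("ACGTACGT", "ACGTACGT")
  expect_equal(nrow(cv3$mismatches), 0)
  expect_equal(cv3$p_value_adenine_bias, 1.0)
  expect_error(classify_variants("", "ACGT"), "empty")
})

test_that("indel columns are tallied separately and excluded from the test", {
  tr <- "GGCAAAATTTTCCCCGGC"
  vr <- paste0(substr(tr, 1, 8), substr(tr, 12, 18))  # 3 bp deletion
  cv <- classify_variants(tr, vr)
  expect_equal(cv$n_indel_columns, 3)
  expect_equal(cv$n_conforming + cv$n_nonconforming, 0)
  expect_equal(cv$p_value_adenine_bias, 1.0)
})

test_that("adenine_bias_test equals the closed-form tail and the oracle", {
  mk <- function(nc, nn, nA, len) structure(
    list(n_conforming = nc, n_nonconforming = nn, n_tr_adenines = nA,
         tr_length = len), class = "VRComparison")
  # m = 3 all conforming at adenine fraction 0.4 -> 0.4^3
  expect_equal(adenine_bias_test(mk(3, 0, 40, 100)), 0.4^3)
  # single non-conforming mismatch -> P(X >= 0) = 1
  expect_equal(adenine_bias_test(mk(0, 1, 40, 100)), 1.0)
  # exhaustive small cases vs the summation oracle
  for (m in 1:5) for (k in 0:m) for (f in c(0.2, 0.35, 0.5)) {
    nA <- round(f * 200)
    expect_equal(adenine_bias_test(mk(k, m - k, nA, 200)),
                 oracle_binom_tail(k, m, nA / 200),
                 tolerance = 1e-12, info = paste(m, k, f))
  }
})

test_that("permutation p-value agrees with the closed form", {
  mk <- function(nc, nn, nA, len) structure(
    list(n_conforming = nc, n_nonconforming = nn, n_tr_adenines = nA,
         tr_length = len), class = "VRComparison")
  c12 <- mk(12, 0, 34, 135)
  p_exact <- adenine_bias_test(c12)
  p_perm <- adenine_bias_test(c12, method = "permutation",
                              n_perm = 10000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(p_perm - p_exact), 3 * se + 2e-4)
})

test_that("find_tr_vr recovers a strongly mutated cassette exactly", {
  sim <- gen_dgr(dgr_sim_config(theta = 0.4, epsilon = 0.01, seed = 7))
  cas <- find_tr_vr(sim$genome)
  expect_length(cas, 1)
  x <- cas[[1]]
  expect_equal(x$tr_interval, sim$truth$tr_interval)
  expect_equal(x$vr_interval, sim$truth$vr_interval)
  expect_true(x$tr_is_rt_extension)
  expect_false(x$rt_pseudogene)
  expect_equal(x$antireceptor_gene$locus_tag, "gpA")
  expect_equal(x$avd_gene$locus_tag, "gpB")
  expect_lt(x$p_value, 0.05)
})

test_that("identical repeats and missing RT annotations are handled", {
  sim0 <- gen_dgr(dgr_sim_config(theta = 0, epsilon = 0, seed = 8))
  expect_identical(sim0$truth$tr, sim0$truth$vr)
  expect_length(find_tr_vr(sim0$genome), 0)   # no mismatch signal

  g <- gen_dgr(dgr_sim_config(theta = 0.4, seed = 9))$genome
  g$features$product <- "hypothetical protein"
  expect_error(find_tr_vr(g), "reverse transcriptase")
  expect_length(find_tr_vr(g, rt_gene = "gpC"), 1)
  expect_error(find_tr_vr(g, rt_gene = "nope"), "not found")
})

test_that("a frameshifted RT is reported as a pseudogene", {
  sim <- gen_dgr(dgr_sim_config(theta = 0.4, rt_frameshift = TRUE,
                                seed = 10))
  cas <- find_tr_vr(sim$genome)
  expect_length(cas, 1)
  expect_true(cas[[1]]$rt_pseudogene)
  # the same flag comes out of the proteome extraction path
  prot <- extract_proteome(sim$genome)
  rt <- prot[[which(vapply(prot, function(p)
    grepl("reverse transcriptase", p$product), TRUE))]]
  expect_true("possible frameshift/pseudogene" %in% rt$flags)
})

test_that("the designated TR is the simulated template when detected", {
  # orientation property at theta = 0.1, epsilon = 0: every detected
  # cassette must point at the true template
  n_det <- 0L; n_correct <- 0L
  for (s in 1:20) {
    sim <- gen_dgr(dgr_sim_config(theta = 0.1, epsilon = 0, seed = 300 + s))
    cas <- find_tr_vr(sim$genome)
    if (length(cas) == 1) {
      n_det <- n_det + 1L
      if (all(cas[[1]]$tr_interval == sim$truth$tr_interval))
        n_correct <- n_correct + 1L
    }
  }
  expect_gt(n_det, 5)           # detection is partial at weak theta
  expect_equal(n_correct, n_det) # but orientation never flips
})

test_that("compare_vr_proteins tabulates residue variants and terminators", {
  ref <- "MKLVNNAQRSTWYVHG"
  expect_equal(nrow(compare_vr_proteins(list(a = ref, b = ref))), 0)
  # four planted residue changes
  var <- ref
  substr(var, 3, 3) <- "A"; substr(var, 5, 5) <- "D"
  substr(var, 9, 9) <- "K"; substr(var, 14, 14) <- "F"
  tab <- compare_vr_proteins(list(a = ref, b = var))
  expect_equal(tab$residue, c(3, 5, 9, 14))
  expect_equal(tab$b, c("A", "D", "K", "F"))
  expect_false(any(tab$terminator))
  # an internal stop is flagged as a terminator
  var2 <- ref; substr(var2, 7, 7) <- "*"
  tab2 <- compare_vr_proteins(list(a = ref, b = var2))
  expect_true(tab2$terminator[tab2$residue == 7])
  expect_error(compare_vr_proteins(list(a = ref, b = var), region = c(1, 99)),
               "region")
})

test_that("cassette reports serialise to TSV and GFF3", {
  sim <- gen_dgr(dgr_sim_config(theta = 0.4, seed = 11))
  cas <- find_tr_vr(sim$genome)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gff <- withr::local_tempfile(fileext = ".gff3")
  df <- write_cassette_report(cas, tsv, gff)
  expect_equal(df$tr_start, sim$truth$tr_interval[1])
  expect_match(readLines(gff)[1], "gff-version 3")
  back <- read.delim(tsv)
  expect_equal(back$vr_end, sim$truth$vr_interval[2])
})
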