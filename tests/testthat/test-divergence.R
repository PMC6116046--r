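test_that("ng86 site fractions match hand enumeration", {
  s <- ng86_sites("TTT")   # only the third-position T->C change is silent
  expect_equal(unname(s["S"]), 1 / 3)
  expect_equal(unname(s["N"]), 8 / 3)
  s <- ng86_sites("TGG")   # tryptophan: every non-stop change is replacement
  expect_equal(unname(s["S"]), 0)
  expect_error(ng86_sites("TAA"), "stop")
  expect_error(ng86_sites("TNT"), "non-ACGT")
})

test_that("site fractions of every sense codon partition into S + N = 3", {
  gc <- Biostrings::GENETIC_CODE
  for (codon in names(gc)[gc != "*"]) {
    s <- ng86_sites(codon)
    expect_equal(unname(s["S"] + s["N"]), 3)
    expect_gte(unname(s["S"]), 0)
  }
})

test_that("codon masking drops every column touched by N, gap or stop", {
  clean <- mask_codons(c(Z = "ATGAAA", W = "ATGAAG"))
  expect_equal(clean$n_retained, 2L)
  expect_equal(clean$n_dropped, 0L)

  one_n <- mask_codons(c(Z = "ATGNAA", W = "ATGAAG", out = "ATGAAA"))
  expect_equal(one_n$n_retained, 1L)
  expect_equal(unname(one_n$seqs), rep("ATG", 3L))

  gap <- mask_codons(c(Z = "AT-AAA", W = "ATGAAG"))
  expect_equal(gap$n_retained, 1L)

  stopc <- mask_codons(c(Z = "TAAAAA", W = "ATGAAG"))  # stop codon column
  expect_equal(stopc$n_retained, 1L)

  empty <- mask_codons(c(Z = "NNN", W = "AAA"))
  expect_equal(empty$n_retained, 0L)
  expect_equal(unname(empty$seqs), c("", ""))

  expect_error(mask_codons(c(Z = "ATG", W = "ATGAAA")), "unequal")
})

test_that("the worked single-change example reproduces exactly", {
  a <- strrep("TTT", 10)
  b <- paste0("TTC", strrep("TTT", 9))
  d <- pairwise_dnds(a, b)
  expect_equal(d$Nd, 0)
  expect_equal(d$Sd, 1)
  expect_equal(d$S_sites, 10 / 3)
  expect_equal(d$pS, 0.3)
  expect_equal(d$dS, -0.75 * log(0.6))
  expect_equal(d$dN, 0)
  expect_equal(d$omega, 0)
})

test_that("identical sequences give zero divergence and an undefined ratio", {
  d <- pairwise_dnds("ATGAAACCC", "ATGAAACCC")
  expect_equal(d$dN, 0)
  expect_equal(d$dS, 0)
  expect_true(d$omega_undefined)
  expect_true(is.na(d$omega))
  expect_error(pairwise_dnds("", ""), "length not divisible|empty")
  expect_error(pairwise_dnds("ATGNNN", "ATGAAA"), "mask")
})

test_that("saturation flags replace nonsense rates", {
  a <- strrep("TTT", 4)
  b <- strrep("TTC", 4)   # 4 silent changes over 4/3 silent sites
  d <- pairwise_dnds(a, b)
  expect_true(d$saturated)
  expect_true(is.na(d$dS))
})

test_that("dN and dS are symmetric in their arguments", {
  set.seed(7)
  for (i in 1:20) {
    pr <- random_codon_pair(20)
    d1 <- pairwise_dnds(pr$a, pr$b)
    d2 <- pairwise_dnds(pr$b, pr$a)
    expect_equal(d1$dS, d2$dS)
    expect_equal(d1$dN, d2$dN)
    expect_equal(d1$S_sites, d2$S_sites)
  }
})

test_that("the Jukes-Cantor correction is monotone below saturation", {
  p <- seq(0, 0.74, by = 0.02)
  d <- neosexr:::.jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p - 1e-12))
})

test_that("counting estimates equal the exhaustive path-enumeration oracle", {
  set.seed(99)
  for (i in 1:150) {
    pr <- random_codon_pair(30)
    d <- pairwise_dnds(pr$a, pr$b)
    o <- oracle_pair_dnds(pr$a, pr$b)
    expect_equal(d$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(d$Nd, o$Nd, tolerance = 1e-9)
    expect_equal(d$S_sites, o$S_sites, tolerance = 1e-9)
    if (!is.na(o$dS)) expect_equal(d$dS, o$dS, tolerance = 1e-9)
    if (!is.na(o$dN)) expect_equal(d$dN, o$dN, tolerance = 1e-9)
  }
})

test_that("GC statistics and the Z/W ratio handle the degenerate cases", {
  g <- gc_stats(c(Z = "ATGC", W = "ATGC"))
  expect_equal(g$gc_Z, 50)
  expect_equal(g$gc_ratio_ZW, 1)
  g <- gc_stats(c(Z = "ATAT", W = "ATAT"))
  expect_equal(g$gc_Z, 0)
  expect_true(is.na(g$gc_ratio_ZW))
  expect_true(g$gc_ratio_undefined)
  g <- gc_stats(c(Z = "GGCC", W = "GGCA", outgroup = "GGCC"))
  expect_equal(g$gc_outgroup, 100)
  expect_equal(g$gc_ratio_ZW, 100 / 75)
})

test_that("transcript selection applies length, dS and longest-isoform rules", {
  tbl <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g4"),
    transcript_id = c("t1", "t2", "t3", "t4a", "t4b"),
    retained_bp = c(499, 600, 900, 600, 900),
    dS = c(0.05, 0.005, 0.05, 0.05, 0.05),
    stringsAsFactors = FALSE
  )
  sel <- select_transcripts(tbl)
  expect_equal(sort(sel$kept$transcript_id), c("t3", "t4b"))
  expect_equal(sel$removed$filter[sel$removed$transcript_id == "t1"], "short")
  expect_equal(sel$removed$filter[sel$removed$transcript_id == "t2"],
               "low_ds")
  expect_equal(sel$removed$filter[sel$removed$transcript_id == "t4a"],
               "shorter_transcript")
  expect_equal(unname(sel$counts["kept"]), 2L)
})

test_that("a zero-length sex-linked branch collapses the outgroup contrast", {
  cfg <- tiny_cfg(t_sexlinked = 0, w_loss_fraction = 0,
                  codons_per_gene = 60)
  g <- simulate_gene_set(cfg)
  div <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) rbind(
    pairwise_dnds(g$seq_Z[i], g$seq_outgroup[i], g$gene_id[i], "Z-outgroup"),
    pairwise_dnds(g$seq_W[i], g$seq_outgroup[i], g$gene_id[i], "W-outgroup")
  )))
  oc <- outgroup_contrast(div)
  expect_equal(oc$table$dN_Z_out, oc$table$dN_W_out)
  expect_equal(oc$table$dS_Z_out, oc$table$dS_W_out)
  expect_true(is.na(oc$t_dN$statistic))  # degenerate: all differences zero
})
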