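site4 <- function(gt, ref = "A", alt = "G", qual = 50, dp = rep(30, 4),
                  sex = c("M", "M", "F", "F")) {
  variant_site(ref, alt, qual = qual, gt = gt, dp = dp, sex = sex)
}

test_that("classify_site reproduces the sex-pattern allele assignments", {
  # Z = reference / W = variant and the mirrored orientation
  cl <- classify_site(site4(c("0/0", "0/0", "0/1", "0/1")))
  expect_equal(c(cl$z_allele, cl$w_allele, cl$rule_id), c("A", "G", "R5"))
  cl <- classify_site(site4(c("1/1", "1/1", "0/1", "0/1")))
  expect_equal(c(cl$z_allele, cl$w_allele), c("G", "A"))
  # monomorphic record
  cl <- classify_site(variant_site("A", character(0), 50,
                                   rep("0/0", 4), rep(30, 4),
                                   c("M", "M", "F", "F")))
  expect_equal(c(cl$z_allele, cl$w_allele, cl$rule_id), c("A", "A", "R4"))
  # everyone homozygous for the alternate
  cl <- classify_site(site4(rep("1/1", 4)))
  expect_equal(c(cl$z_allele, cl$w_allele), c("G", "G"))
  # males and females fixed for different alleles
  cl <- classify_site(site4(c("0/0", "0/0", "1/1", "1/1")))
  expect_equal(c(cl$z_allele, cl$w_allele), c("A", "G"))
})

test_that("classify_site masks by quality, depth, missing and allele count", {
  base <- c("0/0", "0/0", "0/1", "0/1")
  cl <- classify_site(site4(base, qual = 15))
  expect_equal(c(cl$z_allele, cl$w_allele), c("N", "N"))
  expect_equal(cl$mask_reason, "low_qual")
  cl <- classify_site(site4(base, dp = c(30, 19, 30, 30)))
  expect_equal(cl$mask_reason, "low_depth")
  cl <- classify_site(site4(c("0/0", "./.", "0/1", "0/1")))
  expect_equal(cl$mask_reason, "missing_gt")
  # tri-allelic site
  s <- variant_site("A", c("G", "T"), 50, c("0/0", "0/1", "0/2", "0/0"),
                    rep(30, 4), c("M", "M", "F", "F"))
  cl <- classify_site(s)
  expect_equal(c(cl$z_allele, cl$w_allele), c("N", "N"))
  expect_equal(cl$mask_reason, "multiallelic")
  # indel masks a reference-length span
  s <- variant_site("ACT", "A", 50, c("0/0", "0/0", "0/1", "0/1"),
                    rep(30, 4), c("M", "M", "F", "F"))
  cl <- classify_site(s)
  expect_equal(cl$mask_reason, "indel")
  expect_equal(cl$span, 3L)
  # discordant females keep the Z consensus but never the W
  cl <- classify_site(site4(c("0/0", "0/0", "0/1", "0/0")))
  expect_equal(c(cl$z_allele, cl$w_allele), c("A", "N"))
  expect_equal(cl$mask_reason, "female_discordant")
  # a split consensus masks Z too
  cl <- classify_site(site4(c("0/0", "1/1", "0/0", "1/1")))
  expect_equal(c(cl$z_allele, cl$w_allele), c("N", "N"))
  expect_equal(cl$mask_reason, "z_tie")
  # malformed genotypes are an input error, not a silent mask
  s <- variant_site("A", "G", 50, c("0/0/1", "0/0", "0/1", "0/1"),
                    rep(30, 4), c("M", "M", "F", "F"))
  expect_error(classify_site(s), "malformed")
})

test_that("the 81-configuration truth table matches the enumeration oracle", {
  gts <- c("0/0", "0/1", "1/1")
  grid <- expand.grid(m1 = gts, m2 = gts, f1 = gts, f2 = gts,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 81L)
  for (i in seq_len(nrow(grid))) {
    g <- unlist(grid[i, ])
    cl <- classify_site(site4(unname(g)))
    orc <- oracle_zw("A", "G", unname(g), c("M", "M", "F", "F"))
    expect_equal(c(cl$z_allele, cl$w_allele), unname(orc),
                 info = paste(g, collapse = " "))
    expect_true(cl$z_allele %in% c("A", "G", "N"))
    expect_true(cl$w_allele %in% c("A", "G", "N"))
  }
})

test_that("raising the quality threshold never unmasks a site", {
  set.seed(42)
  gts <- c("0/0", "0/1", "1/1")
  for (i in 1:200) {
    s <- site4(sample(gts, 4, replace = TRUE),
               qual = runif(1, 0, 60), dp = rpois(4, 25))
    lo <- classify_site(s, min_qual_depth = 20)
    hi <- classify_site(s, min_qual_depth = 30)
    if (lo$z_allele == "N") expect_equal(hi$z_allele, "N")
    if (lo$w_allele == "N") expect_equal(hi$w_allele, "N")
  }
})

test_that("phase_transcripts assembles exons, masks gaps and audits calls", {
  vp <- tempfile()
  gts5 <- function(g) rep(g, 4)
  rows <- c(
    mini_vcf_rec(1, "A", ".", 50, gts5("0/0"), rep(30, 4)),
    mini_vcf_rec(2, "C", ".", 50, gts5("0/0"), rep(30, 4)),
    mini_vcf_rec(3, "G", "T", 50, c("0/0", "0/0", "0/1", "0/1"), rep(30, 4)),
    mini_vcf_rec(4, "T", "C", 15, c("0/0", "0/0", "0/1", "0/1"), rep(30, 4)),
    mini_vcf_rec(5, "A", "G", 50, c("0/0", "./.", "0/1", "0/1"), rep(30, 4)),
    mini_vcf_rec(6, "ACT", "A", 50, c("0/0", "0/0", "0/1", "0/1"),
                 rep(30, 4)),
    # positions 7, 8 swallowed by the indel span; no record at position 10
    mini_vcf_rec(9, "G", ".", 50, gts5("0/0"), rep(30, 4))
  )
  writeLines(c(mini_vcf_header(), rows), vp)
  bed <- data.frame(chrom = "ctg", start = c(0L, 5L), end = c(5L, 10L),
                    name = "tx1")
  sex <- c(M1 = "M", M2 = "M", F1 = "F", F2 = "F")
  ph <- phase_transcripts(vp, bed, sex)
  p <- ph[["tx1"]]
  expect_equal(nchar(p$z_seq), 10L)
  expect_equal(p$z_seq, "ACGNNNNNGN")
  expect_equal(p$w_seq, "ACTNNNNNGN")
  expect_equal(p$n_sites_called + p$n_sites_masked, 10L)
  expect_equal(p$n_sites_masked, 6L)
  aud <- p$audit
  expect_equal(unname(aud["low_qual"]), 1L)
  expect_equal(unname(aud["missing_gt"]), 1L)
  expect_equal(unname(aud["indel"]), 3L)
  expect_equal(unname(aud["no_record"]), 1L)
})

test_that("phasing recovers the simulated truth exactly without corruption", {
  cfg <- sim_config(n_genes = 5, codons_per_gene = 100, mean_depth = 60,
                    p_low_qual = 0, p_low_dp = 0, p_missing_gt = 0,
                    p_triallelic = 0, w_loss_fraction = 0.2, seed = 21)
  g <- simulate_gene_set(cfg)
  vp <- tempfile(); bp <- tempfile()
  em <- emit_vcf(g, cfg, vp, bp)
  ph <- phase_transcripts(vp, bp, em$sex)
  for (i in seq_len(nrow(g))) {
    p <- ph[[g$gene_id[i]]]
    expect_equal(p$z_seq, g$seq_Z[i])
    if (g$w_present[i]) {
      expect_equal(p$w_seq, g$seq_W[i])
    } else {
      # a deleted W leaves hemizygous females: the phaser sees only Z
      expect_equal(p$w_seq, g$seq_Z[i])
    }
    expect_equal(p$n_sites_masked, 0L)
  }
})
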