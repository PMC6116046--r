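test_that("config validation rejects inconsistent parameter settings", {
  expect_error(sim_config(t_sexlinked = 0.05, t_outgroup = 0.04),
               "t_sexlinked")
  expect_error(sim_config(t_outgroup = 0.9, t_sexlinked = 0.1), "saturation")
  expect_error(sim_config(omega_Z = 0), "omega")
  expect_error(sim_config(w_loss_fraction = 1.2), "w_loss_fraction")
  expect_error(sim_config(beta_link = 2), "beta_link")
  expect_error(sim_config(n_females_dna = 0), "per sex")
})

test_that("a zero sex-linked branch leaves Z and W identical", {
  g <- simulate_gene_set(tiny_cfg(t_sexlinked = 0, w_loss_fraction = 0))
  expect_identical(g$seq_Z, g$seq_W)
  expect_true(all(g$true_dS_ZW == 0))
  expect_true(all(g$true_dN_ZW == 0))
})

test_that("simulation and emitters are deterministic given the seed", {
  cfg <- tiny_cfg()
  g1 <- simulate_gene_set(cfg)
  g2 <- simulate_gene_set(cfg)
  expect_identical(g1, g2)
  p1 <- tempfile(); b1 <- tempfile(); p2 <- tempfile(); b2 <- tempfile()
  emit_vcf(g1, cfg, p1, b1)
  emit_vcf(g2, cfg, p2, b2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(b1), readLines(b2))
  expect_identical(emit_dna_coverage(g1, cfg), emit_dna_coverage(g1, cfg))
  expect_identical(emit_expression_counts(g1, cfg),
                   emit_expression_counts(g1, cfg))
  g3 <- simulate_gene_set(tiny_cfg(seed = 12L))
  expect_false(identical(g1$seq_Z, g3$seq_Z))
})

test_that("recorded substitution events recover the lineage omega targets", {
  cfg <- sim_config(n_genes = 200, codons_per_gene = 500, omega_Z = 0.1,
                    omega_W = 0.5, t_sexlinked = 0.1, t_outgroup = 0.11,
                    rate_shape = Inf, w_loss_fraction = 0, seed = 3)
  g <- simulate_gene_set(cfg)
  est_Z <- (sum(g$nd_Z) / sum(g$N_sites_anc)) /
    (sum(g$sd_Z) / sum(g$S_sites_anc))
  est_W <- (sum(g$nd_W) / sum(g$N_sites_anc)) /
    (sum(g$sd_W) / sum(g$S_sites_anc))
  expect_lt(abs(est_Z - 0.1), 0.1)
  expect_lt(abs(est_W - 0.5), 0.1)
})

test_that("counting estimates track the recorded truth across genes", {
  cfg <- sim_config(n_genes = 200, codons_per_gene = 300,
                    w_loss_fraction = 0, seed = 8)
  g <- simulate_gene_set(cfg)
  est_dS <- vapply(seq_len(nrow(g)), function(i)
    pairwise_dnds(g$seq_Z[i], g$seq_W[i])$dS, 0)
  expect_gt(cor(est_dS, g$true_dS_ZW, method = "spearman"), 0.9)
})

test_that("the divergence-expression link behaves at its endpoints", {
  g0 <- simulate_gene_set(tiny_cfg(beta_link = 0, w_loss_fraction = 0))
  expect_true(all(g0$female_expr_ratio == 1))

  g1 <- simulate_gene_set(tiny_cfg(w_loss_fraction = 0.5))
  expect_true(all(g1$female_expr_ratio[!g1$w_present] == 0.5))
  expect_true(all(is.na(g1$seq_W[!g1$w_present])))
  expect_true(all(!is.na(g1$seq_W[g1$w_present])))

  g2 <- simulate_gene_set(sim_config(n_genes = 40, codons_per_gene = 100,
                                     w_loss_fraction = 0, seed = 5))
  # monotone link: ratio never increases with recorded dN, and the cap pins
  # the ratio at the no-compensation floor
  if (stats::sd(g2$true_dN_ZW) > 0)
    expect_lte(cor(g2$female_expr_ratio, g2$true_dN_ZW,
                   method = "spearman"), 0)
  expect_true(all(g2$female_expr_ratio[g2$true_dN_ZW >= 0.05] == 0.5))
})

test_that("the emitted VCF honours the diploid ZW genotype model", {
  cfg <- sim_config(n_genes = 6, codons_per_gene = 200, w_loss_fraction = 0.5,
                    p_low_qual = 0, p_low_dp = 0, p_missing_gt = 0,
                    p_triallelic = 0, seed = 17)
  g <- simulate_gene_set(cfg)
  vp <- tempfile(); bp <- tempfile()
  emit_vcf(g, cfg, vp, bp)
  lines <- readLines(vp)
  body <- lines[!startsWith(lines, "#")]
  # monomorphic reporting: one record per reference base
  expect_equal(length(body), sum(nchar(g$seq_outgroup)))
  fld <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  gt <- substr(fld[, 10:13], 1, 3)
  dim(gt) <- c(nrow(fld), 4L)

  o <- unlist(strsplit(g$seq_outgroup, ""))
  z <- unlist(strsplit(g$seq_Z, ""))
  w <- unlist(strsplit(ifelse(g$w_present, g$seq_W, g$seq_Z), ""))
  # Z = reference, W = variant: males hom-ref, females het
  i <- which(z == o & w != o)
  expect_gt(length(i), 0)
  expect_true(all(gt[i, 1:2] == "0/0"))
  expect_true(all(gt[i, 3:4] == "0/1"))
  # hemizygous females: W-deleted genes carry only the Z allele
  lens <- nchar(g$seq_outgroup)
  gene_of <- rep(seq_len(nrow(g)), lens)
  lost <- which(!g$w_present[gene_of])
  expect_true(all(gt[lost, 3] == gt[lost, 1]))
  expect_true(all(gt[lost, 4] == gt[lost, 1]))
  # BED covers each gene with three half-open exons
  bed <- read.table(bp, sep = "\t")
  expect_equal(nrow(bed), 3L * nrow(g))
  expect_equal(sum(bed$V3 - bed$V2), sum(lens))
})

test_that("coverage and expression emitters encode the copy-number truth", {
  cfg <- sim_config(n_genes = 20, codons_per_gene = 100, w_loss_fraction = 0.5,
                    seed = 9)
  g <- simulate_gene_set(cfg)
  cov <- emit_dna_coverage(g, cfg)
  agg <- tapply(cov$counts$count / cov$counts$exon_length,
                list(cov$counts$transcript_id, cov$counts$sample), mean)
  sex <- cov$sex[colnames(agg)]
  fm <- rowMeans(agg[, sex == "F"]) / rowMeans(agg[, sex == "M"])
  lost <- !g$w_present[match(rownames(agg), g$gene_id)]
  # raw-expectation check before any normalization: half coverage when the
  # W copy is deleted (library jitter keeps this loose)
  expect_lt(mean(fm[lost]), 0.65)
  expect_gt(mean(fm[!lost]), 0.8)

  expr <- emit_expression_counts(g, cfg, background_genes = 10L)
  expect_equal(nrow(expr$counts), nrow(g) + 10L)
  expect_equal(unname(expr$ratios[paste0("bg", sprintf("%06d", 1:10))]),
               rep(1, 10))
  expect_equal(colnames(expr$counts), names(expr$sex))
})
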