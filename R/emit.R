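## Emitters: turn simulated gene truths into the file formats the inference
## stages consume (VCF v4.2 + BED exons, per-exon DNA read counts, an
## RNA-seq count matrix). All output is plain text and byte-identical for a
## given seed.

.CONTIG <- "neo_contig"

#' Exon table for a simulated gene set
#'
#' Genes are concatenated onto one synthetic contig in order; each gene is
#' split deterministically into three exons (equal thirds, remainder to the
#' last exon). Coordinates are BED-style 0-based half-open.
#'
#' @param genes Output of [simulate_gene_set()].
#' @return `data.frame` with `transcript_id`, `exon_id`, `chrom`, `start`,
#'   `end`, `length` and the gene's 0-based contig offset.
#' @export
exon_table <- function(genes) {
  lens <- nchar(genes$seq_outgroup)
  offs <- cumsum(c(0L, utils::head(lens, -1L)))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    L <- lens[i]
    third <- L %/% 3L
    el <- c(third, third, L - 2L * third)
    st <- offs[i] + cumsum(c(0L, el[1:2]))
    data.frame(
      transcript_id = genes$gene_id[i],
      exon_id = sprintf("%s.e%d", genes$gene_id[i], 1:3),
      chrom = .CONTIG,
      start = st,
      end = st + el,
      length = el,
      gene_offset = offs[i],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# DNA sample names and sexes, males first
dna_samples <- function(config) {
  s <- c(sprintf("M%d", seq_len(config$n_males_dna)),
         sprintf("F%d", seq_len(config$n_females_dna)))
  stats::setNames(rep(c("M", "F"), c(config$n_males_dna, config$n_females_dna)), s)
}

rna_samples <- function(config) {
  s <- c(sprintf("RM%d", seq_len(config$n_males_rna)),
         sprintf("RF%d", seq_len(config$n_females_rna)))
  stats::setNames(rep(c("M", "F"), c(config$n_males_rna, config$n_females_rna)), s)
}

#' Emit a VCF (with monomorphic records) and BED exon annotation
#'
#' One record per reference position is written (emulating variant calling
#' with monomorphic reporting), with the outgroup base as the reference
#' allele. Males are drawn as Z/Z diploids and females as Z/W (Z/Z where the
#' W copy is deleted). A configurable fraction of records is corrupted --
#' low site QUAL, one low-DP sample, one missing genotype, or an injected
#' third allele -- to exercise every masking rule of the phaser.
#'
#' @param genes Output of [simulate_gene_set()].
#' @param config The [sim_config()] used to simulate them.
#' @param vcf_path,bed_path Output file paths.
#' @return Invisibly, a list with the paths, the sample sex map, and the
#'   per-record corruption flags.
#' @export
emit_vcf <- function(genes, config, vcf_path, bed_path) {
  set.seed(stage_seed(config$seed, "vcf"))
  sex <- dna_samples(config)
  ns <- length(sex)
  exons <- exon_table(genes)

  o <- unlist(strsplit(genes$seq_outgroup, ""), use.names = FALSE)
  z <- unlist(strsplit(genes$seq_Z, ""), use.names = FALSE)
  wseq <- ifelse(genes$w_present, genes$seq_W, genes$seq_Z)
  w <- unlist(strsplit(wseq, ""), use.names = FALSE)
  npos <- length(o)
  pos <- seq_len(npos)

  # genotype pattern per position: both male haplotypes are Z, females Z/W
  alt <- character(npos)
  gt_m <- character(npos)
  gt_f <- character(npos)
  mono <- z == o & w == o
  alt[mono] <- "."
  gt_m[mono] <- "0/0"
  gt_f[mono] <- "0/0"
  cs1 <- z == o & w != o
  alt[cs1] <- w[cs1]
  gt_m[cs1] <- "0/0"
  gt_f[cs1] <- "0/1"
  cs2 <- z != o & w == o
  alt[cs2] <- z[cs2]
  gt_m[cs2] <- "1/1"
  gt_f[cs2] <- "0/1"
  cs3 <- z != o & w != o & z == w
  alt[cs3] <- z[cs3]
  gt_m[cs3] <- "1/1"
  gt_f[cs3] <- "1/1"
  cs4 <- z != o & w != o & z != w
  alt[cs4] <- paste(z[cs4], w[cs4], sep = ",")
  gt_m[cs4] <- "1/1"
  gt_f[cs4] <- "1/2"

  qual <- sprintf("%.1f", stats::runif(npos, 30, 60))
  dp <- matrix(stats::rpois(npos * ns, config$mean_depth), nrow = npos)
  gt <- cbind(
    matrix(gt_m, npos, config$n_males_dna),
    matrix(gt_f, npos, config$n_females_dna)
  )

  # corruption: four independent per-record injections
  c_lq <- stats::runif(npos) < config$p_low_qual
  c_ld <- stats::runif(npos) < config$p_low_dp
  c_mg <- stats::runif(npos) < config$p_missing_gt
  c_ta <- stats::runif(npos) < config$p_triallelic
  qual[c_lq] <- sprintf("%.1f", stats::runif(sum(c_lq), 0, 19.9))
  for (i in which(c_ld))
    dp[i, sample.int(ns, 1L)] <- sample(0:19, 1L)
  for (i in which(c_mg))
    gt[i, sample.int(ns, 1L)] <- "./."
  for (i in which(c_ta)) {
    seen <- unique(c(o[i], z[i], w[i]))
    novel <- sample(setdiff(.BASES, seen), 1L)
    alt[i] <- if (alt[i] == ".") novel else paste(alt[i], novel, sep = ",")
    k <- length(strsplit(alt[i], ",")[[1L]])      # index of the novel allele
    j <- sample.int(ns, 1L)
    first <- strsplit(gt[i, j], "/")[[1L]][1L]
    if (first == ".") first <- "0"
    gt[i, j] <- paste0(first, "/", k)
  }

  fields <- matrix(paste0(gt, ":", dp), npos, ns)
  body <- paste(.CONTIG, pos, ".", o, alt, qual, ".", ".", "GT:DP",
                apply(fields, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", .CONTIG, npos),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(sex)), collapse = "\t")
  )
  writeLines(c(header, body), vcf_path)
  writeLines(paste(exons$chrom, exons$start, exons$end, exons$transcript_id,
                   sep = "\t"), bed_path)
  invisible(list(vcf = vcf_path, bed = bed_path, sex = sex,
                 corrupted = data.frame(pos = pos, low_qual = c_lq,
                                        low_dp = c_ld, missing_gt = c_mg,
                                        triallelic = c_ta)))
}

#' Emit per-exon DNA read counts per sample
#'
#' Poisson counts with per-sample library-size multipliers; the expected
#' female coverage of a W-deleted gene is 50% of the male expectation (one
#' copy instead of two).
#'
#' @param genes Output of [simulate_gene_set()].
#' @param config The matching [sim_config()].
#' @param counts_path,totals_path Optional TSV output paths.
#' @return List with `counts` (sample, exon_id, transcript_id, count,
#'   exon_length), `totals` (sample, total_reads, sex) and the sex map.
#' @export
emit_dna_coverage <- function(genes, config, counts_path = NULL,
                              totals_path = NULL) {
  set.seed(stage_seed(config$seed, "coverage"))
  sex <- dna_samples(config)
  ns <- length(sex)
  lib <- exp(stats::rnorm(ns, 0, 0.1))
  totals <- stats::setNames(round(2e6 * lib), names(sex))
  exons <- exon_table(genes)
  copy <- ifelse(genes$w_present[match(exons$transcript_id, genes$gene_id)],
                 1, 0.5)
  rows <- lapply(seq_len(ns), function(s) {
    cf <- if (sex[s] == "M") 1 else copy
    lambda <- config$mean_depth * exons$length * lib[s] * cf
    data.frame(sample = names(sex)[s], exon_id = exons$exon_id,
               transcript_id = exons$transcript_id,
               count = stats::rpois(nrow(exons), lambda),
               exon_length = exons$length, stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  totals_df <- data.frame(sample = names(sex), total_reads = unname(totals),
                          sex = unname(sex), stringsAsFactors = FALSE)
  if (!is.null(counts_path))
    utils::write.table(counts, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(totals_path))
    utils::write.table(totals_df, totals_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(counts = counts, totals = totals_df, sex = sex)
}

#' Emit an RNA-seq count matrix with known female/male truth ratios
#'
#' Male sample means equal `expr_mean` (jittered per-sample library sizes);
#' female means are `expr_mean * female_expr_ratio`, where the truth ratio
#' was fixed at simulation time: `1 - beta_link * min(true_dN_ZW/d_cap, 1)/2`
#' for W-present genes and 0.5 for W-deleted genes (single expressed copy,
#' no compensatory up-regulation). Counts are negative binomial with
#' dispersion `expr_dispersion` (Poisson when 0).
#'
#' @param genes Output of [simulate_gene_set()] (only `gene_id` and
#'   `female_expr_ratio` are used).
#' @param config The matching [sim_config()].
#' @param counts_path Optional TSV output path (genes x samples).
#' @param background_genes Number of additional autosomal background genes
#'   (female/male ratio exactly 1, ids `bg...`) appended to the matrix.
#'   Median-of-ratios normalization assumes most genes are not sex-biased;
#'   a background emulates the rest of the genome so that assumption holds
#'   when the simulated sex-linked set is strongly biased.
#' @return List with `counts` (integer matrix, genes x samples), `sex`
#'   (named vector) and `ratios` (named truth vector).
#' @export
emit_expression_counts <- function(genes, config, counts_path = NULL,
                                   background_genes = 0L) {
  set.seed(stage_seed(config$seed, "expression"))
  sex <- rna_samples(config)
  ns <- length(sex)
  lib <- exp(stats::rnorm(ns, 0, 0.1))
  if (background_genes > 0L) {
    bg <- data.frame(gene_id = sprintf("bg%06d", seq_len(background_genes)),
                     female_expr_ratio = 1)
    genes <- rbind(genes[, c("gene_id", "female_expr_ratio")], bg)
  }
  ratios <- stats::setNames(genes$female_expr_ratio, genes$gene_id)
  mu <- outer(rep(config$expr_mean, nrow(genes)), lib) *
    ifelse(matrix(sex == "F", nrow(genes), ns, byrow = TRUE),
           genes$female_expr_ratio, 1)
  counts <- if (config$expr_dispersion > 0)
    matrix(stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config$expr_dispersion), nrow(genes))
  else
    matrix(stats::rpois(length(mu), mu), nrow(genes))
  dimnames(counts) <- list(genes$gene_id, names(sex))
  if (!is.null(counts_path)) {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(counts = counts, sex = sex, ratios = ratios)
}

#' Write truth sequences as FASTA
#'
#' Headers are `<gene_id>|outgroup`, `<gene_id>|Z`, `<gene_id>|W`; genes
#' without a W copy get no W entry.
#'
#' @param genes Output of [simulate_gene_set()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_truth_fasta <- function(genes, path) {
  seqs <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    seqs[paste0(g, "|outgroup")] <- genes$seq_outgroup[i]
    seqs[paste0(g, "|Z")] <- genes$seq_Z[i]
    if (genes$w_present[i]) seqs[paste0(g, "|W")] <- genes$seq_W[i]
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
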