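## Integrated statistics and the end-to-end pipeline driver.

#' Spearman rank correlation with a tidy result
#'
#' Average ranks for ties; two-sided p-value from the t approximation with
#' n - 2 degrees of freedom (the common software default). For small
#' samples an exact permutation p-value over all n! orderings is available.
#'
#' @param x,y Equal-length numeric vectors without NA.
#' @param label Optional label for the variable pair.
#' @param exact_perm If `TRUE` and `n <= 8`, compute the p-value by full
#'   permutation enumeration instead of the t approximation.
#' @return One-row data frame: `label`, `r_S`, `n`, `p`, `method`.
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5)) # r_S = 0.7
#' @export
spearman_test <- function(x, y, label = NA_character_, exact_perm = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(label = label, r_S = NA_real_, n = n, p = NA_real_,
                      method = "undefined (constant input)",
                      stringsAsFactors = FALSE))
  r <- stats::cor(x, y, method = "spearman")
  if (exact_perm && n <= 8L) {
    ry <- rank(y)
    rhos <- vapply(.perms(seq_len(n)),
                   function(o) stats::cor(rank(x), ry[o]), 0)
    p <- mean(abs(rhos) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    p <- ct$p.value
    method <- "t approximation, tie-corrected"
  }
  data.frame(label = label, r_S = r, n = n, p = p, method = method,
             stringsAsFactors = FALSE)
}

#' Rank-based and t location tests
#'
#' For paired input: Wilcoxon signed-rank (zero differences dropped; exact
#' distribution for n <= 25 without ties, tie-corrected normal approximation
#' otherwise) and the paired t-test. For two-sample input: Wilcoxon
#' rank-sum (tie-corrected normal approximation) and Welch's t-test. All
#' two-sided.
#'
#' @param x,y Numeric vectors (equal length when `paired`).
#' @param paired Paired (`TRUE`, default) or two independent samples.
#' @return Data frame with one row per test: `test`, `statistic`, `p`, `n`,
#'   `note`.
#' @export
rank_tests <- function(x, y, paired = TRUE) {
  rows <- list()
  if (paired) {
    if (length(x) != length(y)) stop("paired vectors must have equal length")
    d <- x - y
    nz <- sum(d != 0)
    if (nz == 0L) {
      rows$wilcoxon <- data.frame(test = "wilcoxon_signed_rank",
                                  statistic = NA_real_, p = NA_real_,
                                  n = 0L, note = "all differences zero",
                                  stringsAsFactors = FALSE)
    } else {
      ties <- any(duplicated(abs(d[d != 0])))
      w <- suppressWarnings(stats::wilcox.test(
        x, y, paired = TRUE, exact = nz <= 25L && !ties, correct = TRUE))
      rows$wilcoxon <- data.frame(test = "wilcoxon_signed_rank",
                                  statistic = unname(w$statistic),
                                  p = w$p.value, n = nz,
                                  note = if (ties) "ties; normal approx"
                                         else if (nz <= 25L) "exact"
                                         else "normal approx",
                                  stringsAsFactors = FALSE)
    }
    if (length(x) >= 2L && stats::sd(d) > 0) {
      tt <- stats::t.test(x, y, paired = TRUE)
      rows$t <- data.frame(test = "paired_t", statistic = unname(tt$statistic),
                           p = tt$p.value, n = length(x), note = "",
                           stringsAsFactors = FALSE)
    } else {
      rows$t <- data.frame(test = "paired_t", statistic = NA_real_,
                           p = NA_real_, n = length(x),
                           note = "degenerate differences",
                           stringsAsFactors = FALSE)
    }
  } else {
    ties <- any(duplicated(c(x, y)))
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
    rows$wilcoxon <- data.frame(test = "wilcoxon_rank_sum",
                                statistic = unname(w$statistic),
                                p = w$p.value, n = length(x) + length(y),
                                note = if (ties) "ties; normal approx"
                                       else "normal approx",
                                stringsAsFactors = FALSE)
    tt <- stats::t.test(x, y)
    rows$t <- data.frame(test = "welch_t", statistic = unname(tt$statistic),
                         p = tt$p.value, n = length(x) + length(y), note = "",
                         stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' GC erosion versus divergence
#'
#' The signature of recombination-driven GC-biased gene conversion: the
#' Z/W GC ratio should grow with gametolog divergence, and Z should exceed
#' W overall. Runs Spearman correlations of `gc_ratio_ZW` against dN and dS
#' and a Wilcoxon signed-rank contrast of gc_Z vs gc_W.
#'
#' @param gc Data frame of [gc_stats()] rows.
#' @param div Data frame of [pairwise_dnds()] rows (`pair == "Z-W"` used).
#' @return List with `correlations` (Spearman rows) and `gc_contrast`
#'   (signed-rank + paired t of gc_Z vs gc_W).
#' @export
gc_divergence_analysis <- function(gc, div) {
  zw <- div[div$pair == "Z-W", c("gene_id", "dN", "dS")]
  m <- merge(gc, zw, by = "gene_id")
  m <- m[stats::complete.cases(m[, c("gc_ratio_ZW", "dN", "dS")]), ,
         drop = FALSE]
  if (nrow(m) < 3L)
    return(list(correlations = NULL, gc_contrast = NULL, n = nrow(m)))
  cors <- rbind(
    spearman_test(m$dN, m$gc_ratio_ZW, "gc_ratio_ZW~dN"),
    spearman_test(m$dS, m$gc_ratio_ZW, "gc_ratio_ZW~dS")
  )
  list(correlations = cors,
       gc_contrast = rank_tests(m$gc_Z, m$gc_W, paired = TRUE),
       n = nrow(m))
}

#' Expression ratio versus divergence
#'
#' The dosage-compensation question: does the female/male expression ratio
#' decline as the W gametolog degenerates? Spearman correlations of the
#' log2 female/male fold change against dN, dS and dN/dS over genes present
#' in both tables.
#'
#' @param de Output of [test_sex_bias()].
#' @param div Data frame of [pairwise_dnds()] rows (`pair == "Z-W"` used).
#' @return List with `correlations` and the merged gene count `n` plus
#'   `n_excluded` (genes in only one table).
#' @export
expression_divergence_analysis <- function(de, div) {
  zw <- div[div$pair == "Z-W", c("gene_id", "dN", "dS", "omega")]
  dd <- de[de$status == "tested", c("gene_id", "log2fc_FM")]
  m <- merge(dd, zw, by = "gene_id")
  n_excluded <- length(union(dd$gene_id, zw$gene_id)) - nrow(m)
  res <- list()
  for (v in c("dN", "dS", "omega")) {
    ok <- stats::complete.cases(m$log2fc_FM, m[[v]])
    if (sum(ok) >= 3L)
      res[[v]] <- spearman_test(m[[v]][ok], m$log2fc_FM[ok],
                                paste0("log2fc_FM~", v))
  }
  list(correlations = if (length(res)) do.call(rbind, res) else NULL,
       n = nrow(m), n_excluded = n_excluded)
}

#' Run the whole synthetic pipeline
#'
#' simulate -> emit VCF/BED/coverage/expression -> phase -> coverage filter
#' -> divergence + GC -> transcript selection -> expression testing ->
#' integrated correlations, with per-stage artifacts written under
#' `out_dir` and a machine-readable JSON summary. Idempotent for a given
#' config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed; a fresh temporary
#'   directory by default).
#' @return A list of class `report_bundle`: merged per-gene table, all
#'   stage tables, test results and run metadata.
#' @export
run_pipeline <- function(config, out_dir = tempfile("neosexr_run_")) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  genes <- simulate_gene_set(config)
  write_truth_fasta(genes, pth("truth.fasta"))
  utils::write.table(
    genes[, setdiff(names(genes), c("seq_outgroup", "seq_Z", "seq_W"))],
    pth("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  em <- emit_vcf(genes, config, pth("variants.vcf"), pth("exons.bed"))
  cov <- emit_dna_coverage(genes, config, pth("dna_coverage.tsv"),
                           pth("dna_totals.tsv"))
  expr <- emit_expression_counts(genes, config, pth("expression_counts.tsv"))
  writeLines(paste(names(em$sex), em$sex, sep = "\t"), pth("sex_map.tsv"))

  phased <- phase_transcripts(pth("variants.vcf"), pth("exons.bed"), em$sex)
  write_phased_fasta(phased, pth("phased.fasta"))

  factors <- library_size_factors(stats::setNames(cov$totals$total_reads,
                                                  cov$totals$sample))
  covrec <- transcript_coverage(cov$counts, factors, cov$sex)
  filt <- filter_w_absent(covrec)
  utils::write.table(filt$table, pth("coverage_filter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # divergence on phased Z/W against the outgroup CDS for retained genes
  div_rows <- list()
  gc_rows <- list()
  retained_bp <- integer(0)
  for (g in intersect(filt$retained, names(phased))) {
    p <- phased[[g]]
    og <- genes$seq_outgroup[genes$gene_id == g]
    gd <- gene_divergence(p$z_seq, p$w_seq, og, g)
    if (is.null(gd$div)) next
    div_rows[[g]] <- gd$div
    gc_rows[[g]] <- gd$gc
    retained_bp[g] <- 3L * gd$n_retained
  }
  div <- if (length(div_rows)) do.call(rbind, div_rows) else NULL
  gc_tbl <- if (length(gc_rows)) do.call(rbind, gc_rows) else NULL

  sel <- if (!is.null(div)) {
    zw <- div[div$pair == "Z-W", , drop = FALSE]
    select_transcripts(data.frame(gene_id = zw$gene_id,
                                  transcript_id = zw$gene_id,
                                  retained_bp = unname(retained_bp[zw$gene_id]),
                                  dS = zw$dS, stringsAsFactors = FALSE))
  } else list(kept = data.frame(gene_id = character(0)),
              removed = NULL, counts = c(kept = 0L))
  keep_ids <- sel$kept$gene_id
  div_keep <- if (!is.null(div)) div[div$gene_id %in% keep_ids, , drop = FALSE]
              else NULL

  oc <- if (!is.null(div_keep) && nrow(div_keep)) outgroup_contrast(div_keep)
        else NULL
  de <- test_sex_bias(expr$counts, expr$sex)
  regions <- stats::setNames(rep("neo-sex", nrow(genes)), genes$gene_id)
  regsum <- region_summary(de, regions)
  gc_an <- if (!is.null(gc_tbl) && length(keep_ids))
    gc_divergence_analysis(gc_tbl[gc_tbl$gene_id %in% keep_ids, ,
                                  drop = FALSE], div_keep)
  else NULL
  ed_an <- if (!is.null(div_keep) && nrow(div_keep))
    expression_divergence_analysis(de, div_keep)
  else NULL

  merged <- if (length(keep_ids)) {
    zw <- div_keep[div_keep$pair == "Z-W",
                   c("gene_id", "dN", "dS", "omega")]
    m <- merge(zw, gc_tbl[, c("gene_id", "gc_Z", "gc_W", "gc_ratio_ZW")],
               by = "gene_id")
    m <- merge(m, de[, c("gene_id", "log2fc_FM", "padj")], by = "gene_id",
               all.x = TRUE)
    m <- merge(m, filt$table[, c("transcript_id", "fm_ratio", "w_absent")],
               by.x = "gene_id", by.y = "transcript_id", all.x = TRUE)
    m$region <- "neo-sex"
    m[order(m$gene_id), , drop = FALSE]
  } else NULL

  summary <- list(
    n_genes_simulated = nrow(genes),
    n_genes_coverage_retained = length(filt$retained),
    n_genes_selected = length(keep_ids),
    selection_counts = as.list(sel$counts),
    outgroup_contrast = if (!is.null(oc))
      list(t_dN = oc$t_dN$statistic, p_dN = oc$t_dN$p,
           t_dS = oc$t_dS$statistic, p_dS = oc$t_dS$p) else NULL,
    n_de_significant = sum(de$significant, na.rm = TRUE),
    region_summary = regsum$summary,
    gc_correlations = if (!is.null(gc_an)) gc_an$correlations else NULL,
    expression_correlations = if (!is.null(ed_an)) ed_an$correlations
                              else NULL,
    config = unclass(config),
    schema_version = "1"
  )
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = 10, null = "null", pretty = TRUE,
                       dataframe = "rows")

  structure(list(genes = merged, truth = genes, divergence = div,
                 gc = gc_tbl, coverage = filt$table, de = de,
                 contrast = oc, region_summary = regsum,
                 gc_analysis = gc_an, expression_analysis = ed_an,
                 selection = sel, phased = phased, config = config,
                 out_dir = out_dir, summary = summary),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  genes simulated: %d | coverage-retained: %d | selected: %d\n",
              x$summary$n_genes_simulated,
              x$summary$n_genes_coverage_retained,
              x$summary$n_genes_selected))
  if (!is.null(x$contrast))
    cat(sprintf("  outgroup contrast: t(dN) = %.2f (p = %.3g), t(dS) = %.2f (p = %.3g)\n",
                x$contrast$t_dN$statistic, x$contrast$t_dN$p,
                x$contrast$t_dS$statistic, x$contrast$t_dS$p))
  if (!is.null(x$expression_analysis) &&
      !is.null(x$expression_analysis$correlations)) {
    cc <- x$expression_analysis$correlations
    for (i in seq_len(nrow(cc)))
      cat(sprintf("  %s: r_S = %.3f (p = %.3g, n = %d)\n",
                  cc$label[i], cc$r_S[i], cc$p[i], cc$n[i]))
  }
  cat("  artifacts: ", x$out_dir, "\n")
  invisible(x)
}
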