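## Sex-biased expression analysis: median-of-ratios library normalization,
## a per-gene negative-binomial Wald test of female vs male means with a
## method-of-moments dispersion estimate, and Benjamini-Hochberg FDR.

#' Median-of-ratios size factors
#'
#' The classic RNA-seq normalization: for every gene expressed in all
#' samples, the ratio of each sample's count to the gene's geometric mean
#' across samples is formed; a sample's size factor is the median of its
#' ratios.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of per-sample size factors.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' size_factors_median_ratio(m) # c(1, 2) / sqrt(2)
#' @export
size_factors_median_ratio <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)          # genes with nonzero counts in all samples
  if (!any(use))
    stop("no gene has nonzero counts in every sample; a pseudo-reference ",
         "fallback is out of scope")
  apply(counts, 2L, function(cnts)
    exp(stats::median(log(cnts[use]) - loggeo[use])))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement,
#' order-preserving on the input index.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed and
#'   propagated).
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test of sex-biased expression
#'
#' Counts are normalized with [size_factors_median_ratio()] (or supplied
#' factors); for each gene the log2 female/male ratio of normalized group
#' means is tested with a Wald statistic whose standard error comes from a
#' pooled method-of-moments negative-binomial dispersion (delta method on
#' the log ratio), against a two-sided t reference with the within-group
#' degrees of freedom (the dispersion is estimated from the same few
#' samples, so a normal reference would be anticonservative). Genes with zero
#' counts everywhere are dropped before testing; genes where one sex has a
#' zero mean are reported with an infinite fold change but excluded from
#' testing, mirroring the removal of transcripts without adjusted p-values.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param sex Named `"M"`/`"F"` vector over the columns of `counts`.
#' @param pseudocount Added to both group means in the log2 ratio (default
#'   0.5) so sparse genes stay finite.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param size_factors Optional pre-computed size factors.
#' @return Data frame with one row per input gene: `base_mean`, group means,
#'   `log2fc_FM`, `se`, `wald_z`, `p`, `padj`, `significant` and a `status`
#'   column (`tested`, `all_zero`, `zero_group`).
#' @export
test_sex_bias <- function(counts, sex, pseudocount = 0.5, alpha = 0.05,
                          size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
  sexv <- unname(sex[colnames(counts)])
  if (any(is.na(sexv))) sexv <- unname(sex)[seq_len(ncol(counts))]
  if (sum(sexv == "F") < 2L || sum(sexv == "M") < 2L)
    stop("need at least two samples per sex")
  sf <- if (is.null(size_factors)) size_factors_median_ratio(counts)
        else size_factors
  norm <- sweep(counts, 2L, sf, "/")
  f <- sexv == "F"
  m <- sexv == "M"
  nf <- sum(f)
  nm <- sum(m)
  mu_f <- rowMeans(norm[, f, drop = FALSE])
  mu_m <- rowMeans(norm[, m, drop = FALSE])
  rowvar <- function(x, mu, n) rowSums((x - mu)^2) / (n - 1L)
  v_f <- rowvar(norm[, f, drop = FALSE], mu_f, nf)
  v_m <- rowvar(norm[, m, drop = FALSE], mu_m, nm)

  status <- rep("tested", nrow(counts))
  status[rowSums(counts) == 0] <- "all_zero"
  status[status == "tested" & (mu_f == 0 | mu_m == 0)] <- "zero_group"
  tested <- status == "tested"

  # pooled method-of-moments NB dispersion, floored
  num <- (nf - 1L) * (v_f - mu_f) + (nm - 1L) * (v_m - mu_m)
  den <- (nf - 1L) * mu_f^2 + (nm - 1L) * mu_m^2
  disp <- pmax(ifelse(den > 0, num / den, NA_real_), 1e-8)

  log2fc <- log2((mu_f + pseudocount) / (mu_m + pseudocount))
  log2fc[status == "zero_group" & mu_f == 0] <- -Inf
  log2fc[status == "zero_group" & mu_m == 0] <- Inf
  log2fc[status == "all_zero"] <- NA_real_

  se <- sqrt((1 / mu_f + disp) / nf + (1 / mu_m + disp) / nm) / log(2)
  se[!tested] <- NA_real_
  z <- ifelse(tested, log2fc / se, NA_real_)
  z[tested & log2fc == 0] <- 0
  p <- ifelse(tested, 2 * stats::pt(-abs(z), df = nf + nm - 2L), NA_real_)
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])

  data.frame(gene_id = rownames(counts),
             base_mean = rowMeans(norm),
             mean_F = mu_f, mean_M = mu_m,
             log2fc_FM = log2fc, se = se, wald_z = z, p = p, padj = padj,
             significant = !is.na(padj) & padj < alpha,
             status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-region summary of sex-biased expression
#'
#' Groups genes by region label (e.g. neo-sex, ancestral-Z, autosomal) and
#' reports the mean and standard error of the log2 female/male fold change,
#' a paired t-test of per-gene female vs male mean expression (on the log2
#' scale with the pseudocount), and Welch t-tests comparing the fold-change
#' distributions between regions.
#'
#' @param de Output of [test_sex_bias()].
#' @param regions Named character vector mapping `gene_id` to a region
#'   label.
#' @param pseudocount Pseudocount used on the log2 scale (default 0.5).
#' @return List with `summary` (per region: n, mean, se, paired t), and
#'   `welch` (pairwise region comparisons of log2fc).
#' @export
region_summary <- function(de, regions, pseudocount = 0.5) {
  de <- de[de$status == "tested", , drop = FALSE]
  de$region <- unname(regions[de$gene_id])
  de <- de[!is.na(de$region), , drop = FALSE]
  regs <- unique(de$region)
  summ <- do.call(rbind, lapply(regs, function(r) {
    d <- de[de$region == r, , drop = FALSE]
    n <- nrow(d)
    lf <- log2(d$mean_F + pseudocount)
    lm_ <- log2(d$mean_M + pseudocount)
    if (n >= 2L && stats::sd(lf - lm_) > 0) {
      tt <- stats::t.test(lf, lm_, paired = TRUE)
      ts <- unname(tt$statistic)
      tp <- tt$p.value
    } else {
      ts <- NA_real_
      tp <- NA_real_
    }
    data.frame(region = r, n = n,
               mean_log2fc = mean(d$log2fc_FM),
               se_log2fc = if (n >= 2L) stats::sd(d$log2fc_FM) / sqrt(n)
                           else NA_real_,
               paired_t = ts, paired_p = tp, stringsAsFactors = FALSE)
  }))
  welch <- NULL
  if (length(regs) >= 2L) {
    cmb <- utils::combn(regs, 2L)
    welch <- do.call(rbind, apply(cmb, 2L, function(pr) {
      a <- de$log2fc_FM[de$region == pr[1L]]
      b <- de$log2fc_FM[de$region == pr[2L]]
      if (length(a) < 2L || length(b) < 2L)
        return(data.frame(region_a = pr[1L], region_b = pr[2L],
                          statistic = NA_real_, p = NA_real_))
      tt <- stats::t.test(a, b)
      data.frame(region_a = pr[1L], region_b = pr[2L],
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, welch = welch)
}
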