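#' Simulation configuration for a synthetic gametolog system
#'
#' Bundles every parameter of the gametolog-evolution generator. Branch
#' lengths are expected proposed substitutions per site; the chronology
#' mirrors a neo-sex chromosome that stopped recombining (`t_sexlinked`)
#' after the split from the outgroup (`t_outgroup`), so
#' `t_sexlinked < t_outgroup` is enforced (defaults follow a 19 vs 22 My
#' chronology scaled to a realized Z-W dS near 0.05).
#'
#' @param n_genes Number of genes to simulate.
#' @param codons_per_gene Codons per gene (including the start codon).
#' @param t_outgroup Expected substitutions/site on each branch since the
#'   outgroup split.
#' @param t_sexlinked Expected substitutions/site on the Z and W branches
#'   since Z-W recombination stopped; must be `< t_outgroup`.
#' @param omega_Z,omega_W dN/dS acceptance ratios on the Z and W branches.
#' @param kappa Transition/transversion rate ratio of substitution proposals.
#' @param gc_bias_Z Weight multiplying A/T->G/C proposals on the Z branch
#'   only (1 = unbiased), emulating GC-biased gene conversion on the still
#'   recombining Z.
#' @param rate_shape Gamma shape of the per-gene rate multiplier (mean 1).
#'   `Inf` disables between-gene rate heterogeneity; the default 1
#'   (exponential) reproduces an order-of-magnitude spread of divergence
#'   across genes.
#' @param w_loss_fraction Fraction of genes whose W copy is deleted.
#' @param n_males_dna,n_females_dna DNA (resequencing) sample counts.
#' @param n_males_rna,n_females_rna RNA (expression) sample counts.
#' @param mean_depth Expected per-base DNA coverage per sample.
#' @param expr_mean Mean expression count of a male sample.
#' @param expr_dispersion Negative-binomial dispersion of expression counts.
#' @param beta_link Strength in `[0, 1]` coupling female expression
#'   suppression to W divergence (0 = no coupling).
#' @param d_cap dN value at which the expression-suppression link saturates.
#' @param p_low_qual,p_low_dp,p_missing_gt,p_triallelic Independent
#'   per-record probabilities of injecting a corrupted VCF record (low site
#'   quality, one low-depth sample, one missing genotype, a third allele).
#' @param seed Integer random seed; every stage derives its own substream.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 5, codons_per_gene = 50, seed = 42)
#' @export
sim_config <- function(n_genes = 50L,
                       codons_per_gene = 500L,
                       t_outgroup = 0.029,
                       t_sexlinked = 0.025,
                       omega_Z = 0.1,
                       omega_W = 0.5,
                       kappa = 2,
                       gc_bias_Z = 3,
                       rate_shape = 1,
                       w_loss_fraction = 0.2,
                       n_males_dna = 2L,
                       n_females_dna = 2L,
                       n_males_rna = 6L,
                       n_females_rna = 6L,
                       mean_depth = 30,
                       expr_mean = 500,
                       expr_dispersion = 0.05,
                       beta_link = 1,
                       d_cap = 0.05,
                       p_low_qual = 0.0125,
                       p_low_dp = 0.0125,
                       p_missing_gt = 0.0125,
                       p_triallelic = 0.0125,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), codons_per_gene = as.integer(codons_per_gene),
    t_outgroup = t_outgroup, t_sexlinked = t_sexlinked,
    omega_Z = omega_Z, omega_W = omega_W, kappa = kappa,
    gc_bias_Z = gc_bias_Z, rate_shape = rate_shape,
    w_loss_fraction = w_loss_fraction,
    n_males_dna = as.integer(n_males_dna), n_females_dna = as.integer(n_females_dna),
    n_males_rna = as.integer(n_males_rna), n_females_rna = as.integer(n_females_rna),
    mean_depth = mean_depth, expr_mean = expr_mean,
    expr_dispersion = expr_dispersion, beta_link = beta_link, d_cap = d_cap,
    p_low_qual = p_low_qual, p_low_dp = p_low_dp,
    p_missing_gt = p_missing_gt, p_triallelic = p_triallelic,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(cfg$n_genes >= 1L, "n_genes must be >= 1")
  chk(cfg$codons_per_gene >= 2L, "codons_per_gene must be >= 2")
  chk(cfg$t_outgroup > 0, "t_outgroup must be > 0")
  chk(cfg$t_sexlinked >= 0, "t_sexlinked must be >= 0")
  chk(cfg$t_sexlinked < cfg$t_outgroup, "t_sexlinked must be < t_outgroup")
  chk(cfg$omega_Z > 0 && cfg$omega_W > 0, "omega_Z and omega_W must be > 0")
  chk(cfg$kappa > 0, "kappa must be > 0")
  chk(cfg$gc_bias_Z > 0, "gc_bias_Z must be > 0")
  chk(cfg$rate_shape > 0, "rate_shape must be > 0")
  chk(cfg$w_loss_fraction >= 0 && cfg$w_loss_fraction <= 1,
      "w_loss_fraction must lie in [0, 1]")
  chk(cfg$beta_link >= 0 && cfg$beta_link <= 1, "beta_link must lie in [0, 1]")
  chk(cfg$d_cap > 0, "d_cap must be > 0")
  chk(all(c(cfg$n_males_dna, cfg$n_females_dna) >= 1L),
      "at least one DNA sample per sex")
  chk(all(c(cfg$n_males_rna, cfg$n_females_rna) >= 2L),
      "at least two RNA samples per sex")
  chk(cfg$mean_depth > 0, "mean_depth must be > 0")
  chk(cfg$expr_mean > 0, "expr_mean must be > 0")
  chk(cfg$expr_dispersion >= 0, "expr_dispersion must be >= 0")
  for (p in c("p_low_qual", "p_low_dp", "p_missing_gt", "p_triallelic"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must lie in [0, 1]"))
  # saturation guard: expected pairwise proposal divergence to the outgroup
  if (2 * cfg$t_outgroup > 1.5)
    stop("invalid sim_config: expected divergence exceeds the saturation ",
         "guard (2 * t_outgroup > 1.5); the counting estimator is not ",
         "usable at that distance", call. = FALSE)
  invisible(cfg)
}

# deterministic per-stage seed substream; stays well below 2^31
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, vcf = 211L, coverage = 307L,
            expression = 401L, pipeline = 503L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 100000L) * 20011L + offs[[stage]]
}
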