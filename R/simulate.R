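## Codon-level gametolog-evolution simulator.
##
## One ancestral coding sequence per gene evolves along a three-taxon
## topology: (outgroup, (Z, W)). Substitutions are proposed at a uniform
## per-site rate with a kappa-weighted transition bias, accepted with
## probability 1 when synonymous and probability omega_<lineage> when
## non-synonymous; proposals creating stop codons are rejected. On the Z
## branch only, A/T -> G/C proposals are up-weighted by gc_bias_Z. Every
## accepted substitution is recorded, so realized per-lineage dN and dS are
## known exactly and serve as the oracle for the counting estimator.
##
## Internally sequences are integer base codes (A=1, C=2, G=3, T=4) and
## codons are ids 1..64 with ((b1-1)*4 + (b2-1))*4 + b3, so the inner loop
## is pure integer arithmetic.

# codon strings in codon-id order (b1 outermost, b3 innermost)
codons_by_cid <- function() {
  if (is.null(.codon_cache$by_cid)) {
    g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                     stringsAsFactors = FALSE)
    .codon_cache$by_cid <- paste0(g$b1, g$b2, g$b3)
  }
  .codon_cache$by_cid
}

# amino-acid ids by codon id; 0 marks a stop codon
aa_by_cid <- function() {
  if (is.null(.codon_cache$aa_cid)) {
    aa <- genetic_code()[codons_by_cid()]
    ids <- as.integer(factor(aa, levels = setdiff(unique(aa), "*")))
    ids[aa == "*"] <- 0L
    .codon_cache$aa_cid <- ids
  }
  .codon_cache$aa_cid
}

# NG86 synonymous site fraction by codon id (NA for stops)
s_sites_by_cid <- function() {
  if (is.null(.codon_cache$s_cid)) {
    cods <- codons_by_cid()
    stop_c <- genetic_code()[cods] == "*"
    s <- rep(NA_real_, 64L)
    s[!stop_c] <- vapply(cods[!stop_c],
                         function(cc) ng86_sites(cc)[["S"]], 0)
    .codon_cache$s_cid <- s
  }
  .codon_cache$s_cid
}

seq_to_int <- function(seq_chars) match(seq_chars, .BASES)
int_to_seq <- function(s) paste(.BASES[s], collapse = "")

# codon ids of an integer-coded sequence
cids_of <- function(s) {
  L <- length(s)
  i <- seq(1L, L, 3L)
  ((s[i] - 1L) * 4L + (s[i + 1L] - 1L)) * 4L + s[i + 2L]
}

# evolve one lineage for branch length t (expected proposals/site * rate);
# returns the evolved integer sequence plus accepted substitution counts
evolve_branch <- function(s, t, omega, kappa, gc_bias = 1, rate = 1) {
  L <- length(s)
  aa <- aa_by_cid()
  n_prop <- stats::rpois(1L, L * t * rate)
  nd <- 0L
  sd <- 0L
  if (n_prop == 0L) return(list(seq = s, nd = nd, sd = sd))
  # per current base: the 3 alternative bases and their proposal weights
  altm <- vapply(1:4, function(b) which(1:4 != b), integer(3))
  wm <- matrix(1, 3L, 4L)
  for (b in 1:4) {
    a <- altm[, b]
    ts <- (b %in% c(1L, 3L)) == (a %in% c(1L, 3L))   # both purines or both pyrimidines
    wm[ts, b] <- kappa
    if (gc_bias != 1 && b %in% c(1L, 4L))            # A or T losing to G/C
      wm[a %in% c(2L, 3L), b] <- wm[a %in% c(2L, 3L), b] * gc_bias
  }
  cw <- apply(wm, 2L, cumsum)
  pos <- sample.int(L, n_prop, replace = TRUE)
  u_pick <- stats::runif(n_prop)
  u_acc <- stats::runif(n_prop)
  mult <- c(16L, 4L, 1L)
  for (k in seq_len(n_prop)) {
    p <- pos[k]
    cur <- s[p]
    r <- u_pick[k] * cw[3L, cur]
    j <- 1L + (r >= cw[1L, cur]) + (r >= cw[2L, cur])
    new <- altm[j, cur]
    off <- (p - 1L) %% 3L
    cs <- p - off
    cid_old <- ((s[cs] - 1L) * 4L + (s[cs + 1L] - 1L)) * 4L + s[cs + 2L]
    cid_new <- cid_old + (new - cur) * mult[off + 1L]
    an <- aa[cid_new]
    if (an == 0L) next                               # stop codons rejected
    if (an == aa[cid_old]) {
      s[p] <- new
      sd <- sd + 1L
    } else if (u_acc[k] < omega) {
      s[p] <- new
      nd <- nd + 1L
    }
  }
  list(seq = s, nd = nd, sd = sd)
}

#' Simulate a set of gametolog gene truths
#'
#' Draws an ancestral CDS per gene (ATG followed by sense codons), evolves
#' the outgroup lineage for `t_outgroup`, the shared proto-gametolog for
#' `t_outgroup - t_sexlinked`, then Z and W independently for `t_sexlinked`
#' under the codon proposal-acceptance model (see package docs). Realized
#' Z-W divergence is recorded from the accepted substitution events, the
#' NG86 site counts of the proto-gametolog at the split serving as
#' denominators. A `w_loss_fraction` of genes has the W copy deleted
#' (`seq_W = NA`). The target female/male expression ratio is
#' `1 - beta_link * min(true_dN_ZW / d_cap, 1) / 2` for W-present genes and
#' exactly 0.5 (one Z copy, no compensation) for W-deleted genes.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` (one row per gene) with columns `gene_id`,
#'   `w_present`, `true_dN_ZW`, `true_dS_ZW`, `female_expr_ratio`, `rate`,
#'   per-branch event counts (`nd_Z`, `sd_Z`, `nd_W`, `sd_W`), ancestral
#'   site counts (`N_sites_anc`, `S_sites_anc`) and the sequences
#'   `seq_outgroup`, `seq_Z`, `seq_W` as strings.
#' @examples
#' genes <- simulate_gene_set(sim_config(n_genes = 3, codons_per_gene = 30))
#' genes$true_dS_ZW
#' @export
simulate_gene_set <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "simulate"))
  n <- config$n_genes
  sense_cids <- which(aa_by_cid() != 0L)
  s_tab <- s_sites_by_cid()
  atg <- seq_to_int(c("A", "T", "G"))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rate <- if (is.finite(config$rate_shape))
      stats::rgamma(1L, shape = config$rate_shape, rate = config$rate_shape)
    else 1
    cids <- sample(sense_cids, config$codons_per_gene - 1L, replace = TRUE)
    anc <- c(atg, rbind((cids - 1L) %/% 16L + 1L,
                        ((cids - 1L) %/% 4L) %% 4L + 1L,
                        (cids - 1L) %% 4L + 1L))
    og <- evolve_branch(anc, config$t_outgroup, config$omega_Z, config$kappa,
                        1, rate)
    shared <- evolve_branch(anc, config$t_outgroup - config$t_sexlinked,
                            config$omega_Z, config$kappa, 1, rate)
    z <- evolve_branch(shared$seq, config$t_sexlinked, config$omega_Z,
                       config$kappa, config$gc_bias_Z, rate)
    w <- evolve_branch(shared$seq, config$t_sexlinked, config$omega_W,
                       config$kappa, 1, rate)
    s_anc <- s_tab[cids_of(shared$seq)]
    S_anc <- sum(s_anc)
    N_anc <- 3 * length(s_anc) - S_anc
    out[[i]] <- data.frame(
      gene_id = sprintf("g%04d", i),
      rate = rate,
      nd_Z = z$nd, sd_Z = z$sd, nd_W = w$nd, sd_W = w$sd,
      N_sites_anc = N_anc, S_sites_anc = S_anc,
      true_dN_ZW = (z$nd + w$nd) / N_anc,
      true_dS_ZW = (z$sd + w$sd) / S_anc,
      seq_outgroup = int_to_seq(og$seq),
      seq_Z = int_to_seq(z$seq),
      seq_W = int_to_seq(w$seq),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, out)
  n_loss <- round(config$w_loss_fraction * n)
  lost <- if (n_loss > 0L) sample.int(n, n_loss) else integer(0)
  genes$w_present <- !(seq_len(n) %in% lost)
  genes$seq_W[!genes$w_present] <- NA_character_
  genes$female_expr_ratio <- ifelse(
    genes$w_present,
    1 - config$beta_link * pmin(genes$true_dN_ZW / config$d_cap, 1) * 0.5,
    0.5
  )
  genes
}
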