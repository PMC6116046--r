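## Independent oracles used across the suite. These deliberately do not
## share code paths with the package implementation.

# small, fast simulation config
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 6L, codons_per_gene = 40L, seed = 11L), list(...))
  do.call(sim_config, args)
}

## ---- Z/W truth-table oracle -------------------------------------------
## Brute-force restatement of the allele-assignment rules for a clean
## biallelic SNV (quality filters already passed), by direct enumeration
## over male/female base multisets.
oracle_zw <- function(ref, alt, gts, sexes) {
  bases <- function(g)
    sort(c(ref, alt)[as.integer(strsplit(g, "/")[[1L]]) + 1L])
  prs <- lapply(gts, bases)
  if (length(unique(unlist(prs))) > 2L) return(c(z = "N", w = "N"))
  mp <- prs[sexes == "M"]
  fp <- prs[sexes == "F"]
  all_same <- function(lst) all(vapply(lst, identical, TRUE, lst[[1L]]))
  m_hom <- all(vapply(mp, function(p) p[1L] == p[2L], TRUE))
  m_one <- m_hom && length(unique(vapply(mp, `[`, "", 1L))) == 1L
  if (all_same(fp)) {
    f1 <- fp[[1L]]
    if (m_one) {
      a <- mp[[1L]][1L]
      if (f1[1L] != f1[2L]) {                       # females identically het
        if (a %in% f1) return(c(z = a, w = f1[f1 != a][1L]))
        return(c(z = "N", w = "N"))
      }
      return(c(z = a, w = f1[1L]))                  # females homozygous
    }
    return(c(z = "N", w = "N"))
  }
  # females disagree: W unknowable; Z by majority vote of male alleles plus
  # alleles of homozygous females
  votes <- unlist(mp)
  for (p in fp) if (p[1L] == p[2L]) votes <- c(votes, p[1L])
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(c(z = winners, w = "N"))
  c(z = "N", w = "N")
}

## ---- counting dN/dS oracle --------------------------------------------
## Exhaustive path enumeration with explicit recursion; NG86 site fractions
## recomputed from scratch against the standard genetic code.
.ocode <- Biostrings::GENETIC_CODE

oracle_codon_sites <- function(codon) {
  s <- 0
  for (i in 1:3) {
    syn <- 0L
    ok <- 0L
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, i, i) == b) next
      mut <- codon
      substr(mut, i, i) <- b
      if (.ocode[[mut]] == "*") next
      ok <- ok + 1L
      if (.ocode[[mut]] == .ocode[[codon]]) syn <- syn + 1L
    }
    if (ok > 0L) s <- s + syn / ok
  }
  s
}

# all substitution paths cur -> tgt; rows of the result are (nd, sd) per
# path; strict mode refuses to step onto a stop codon
oracle_walk <- function(cur, tgt, strict) {
  if (cur == tgt) return(matrix(c(0, 0), 1L))
  acc <- NULL
  for (i in 1:3) {
    if (substr(cur, i, i) == substr(tgt, i, i)) next
    nxt <- cur
    substr(nxt, i, i) <- substr(tgt, i, i)
    if (strict && .ocode[[nxt]] == "*") next
    step <- if (.ocode[[nxt]] == .ocode[[cur]]) c(0, 1) else c(1, 0)
    tails <- oracle_walk(nxt, tgt, strict)
    if (is.null(tails)) next
    acc <- rbind(acc, sweep(tails, 2L, step, "+"))
  }
  acc
}

oracle_pair_dnds <- function(s1, s2) {
  sp <- function(s) substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  c1 <- sp(s1)
  c2 <- sp(s2)
  S <- 0
  nd <- 0
  sd <- 0
  for (k in seq_along(c1)) {
    S <- S + (oracle_codon_sites(c1[k]) + oracle_codon_sites(c2[k])) / 2
    if (c1[k] != c2[k]) {
      paths <- oracle_walk(c1[k], c2[k], TRUE)
      if (is.null(paths)) paths <- oracle_walk(c1[k], c2[k], FALSE)
      m <- colMeans(paths)
      nd <- nd + m[1L]
      sd <- sd + m[2L]
    }
  }
  N <- 3 * length(c1) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S_sites = S, N_sites = N, Sd = sd, Nd = nd,
       pS = sd / S, pN = nd / N, dS = jc(sd / S), dN = jc(nd / N))
}

# random pair of sense-codon sequences with scattered differences
random_codon_pair <- function(n_codons, p_diff = 0.5) {
  sense <- names(.ocode)[.ocode != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  flip <- runif(n_codons) < p_diff
  b[flip] <- sample(sense, sum(flip), replace = TRUE)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

## ---- misc helpers ------------------------------------------------------
mini_vcf_header <- function(samples = c("M1", "M2", "F1", "F2"),
                            contig = "ctg", len = 1000L) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

mini_vcf_rec <- function(pos, ref, alt, qual, gts, dps, contig = "ctg") {
  paste(c(contig, pos, ".", ref, alt, qual, ".", ".", "GT:DP",
          paste0(gts, ":", dps)), collapse = "\t")
}
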