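## Counting (NG86-style) estimator of codon-level divergence with
## Jukes-Cantor correction, codon masking, GC statistics and the
## transcript-selection filters applied before divergence analysis.

# permutations of a small integer vector (<= 3 elements needed here)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(.perms(v[-i]), function(p) c(v[i], p))))
}

#' Drop codon columns containing N, gaps or stops
#'
#' Aligned, equal-length sequences are scanned codon by codon; every codon
#' column where any sequence carries an ambiguous base (N), a gap, or a stop
#' codon is removed from all sequences, so downstream counting only ever
#' sees clean sense codons.
#'
#' @param seqs Named character vector (or list) of equal-length nucleotide
#'   strings whose length is divisible by 3.
#' @return List with `seqs` (cleaned strings, names preserved),
#'   `n_retained` and `n_dropped` codon counts.
#' @export
mask_codons <- function(seqs) {
  seqs <- toupper(unlist(seqs))
  if (length(seqs) < 1L) stop("no sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have unequal lengths")
  if (L %% 3L != 0L) stop("alignment length not divisible by 3")
  ncod <- L %/% 3L
  sense <- sense_codons()
  keep <- rep(TRUE, ncod)
  cods <- lapply(seqs, seq_codons)
  for (cv in cods) keep <- keep & cv %in% sense
  cleaned <- vapply(cods, function(cv) paste(cv[keep], collapse = ""), "")
  list(seqs = cleaned, n_retained = sum(keep), n_dropped = sum(!keep))
}

# average (nonsyn, syn) change counts over minimal substitution paths
# between two codons; paths through stop codons are excluded. If every path
# passes through a stop (possible for triple differences), fall back to
# averaging over all paths, scoring a step into/out of a stop by amino-acid
# identity.
codon_path_counts <- function(c1, c2, allow_stop = FALSE) {
  gc <- genetic_code()
  b1 <- strsplit(c1, "")[[1L]]
  b2 <- strsplit(c2, "")[[1L]]
  dif <- which(b1 != b2)
  if (length(dif) == 0L) return(c(nd = 0, sd = 0))
  paths <- .perms(dif)
  nd_tot <- 0
  sd_tot <- 0
  n_ok <- 0L
  for (ord in paths) {
    cur <- b1
    nd <- 0L
    sd <- 0L
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b2[p]
      aa_from <- gc[[paste(cur, collapse = "")]]
      aa_to <- gc[[paste(nxt, collapse = "")]]
      if (!allow_stop && (aa_to == "*" || aa_from == "*")) {
        ok <- FALSE
        break
      }
      if (aa_to == aa_from) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) {
      nd_tot <- nd_tot + nd
      sd_tot <- sd_tot + sd
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) {
    if (allow_stop) stop("path enumeration failed for ", c1, " -> ", c2)
    return(codon_path_counts(c1, c2, allow_stop = TRUE))
  }
  c(nd = nd_tot / n_ok, sd = sd_tot / n_ok)
}

.jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise dN and dS by codon counting
#'
#' NG86-style counting on a pre-masked pair of coding sequences: site counts
#' from [ng86_sites()] averaged over the two sequences; differences counted
#' per codon, with multi-hit codons resolved by averaging over all minimal
#' substitution paths (paths through stop codons excluded); proportions
#' corrected with the Jukes-Cantor formula
#' `d = -3/4 * log(1 - 4p/3)`. A proportion at or above 0.75 sets the
#' `saturated` flag and leaves the rate `NA`.
#'
#' @param seq1,seq2 Equal-length coding sequences of clean sense codons
#'   (run [mask_codons()] first).
#' @param gene_id,pair Optional labels carried into the output row.
#' @return One-row data frame: codon and site counts (`S_sites`,
#'   `N_sites`), difference counts (`Sd`, `Nd`), proportions (`pS`, `pN`),
#'   corrected rates (`dS`, `dN`), `omega` with an `omega_undefined` flag
#'   (dS = 0) and the `saturated` flag.
#' @examples
#' a <- strrep("TTT", 10)
#' b <- paste0("TTC", strrep("TTT", 9))
#' pairwise_dnds(a, b) # dN = 0, dS = -0.75 * log(0.6)
#' @export
pairwise_dnds <- function(seq1, seq2, gene_id = NA_character_,
                          pair = NA_character_) {
  seq1 <- toupper(seq1)
  seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences have unequal lengths")
  c1 <- seq_codons(seq1)
  c2 <- seq_codons(seq2)
  if (length(c1) == 0L) stop("empty alignment")
  tab <- ng86_table()
  if (!all(c(c1, c2) %in% rownames(tab)))
    stop("sequences contain non-sense codons; mask with mask_codons() first")
  S_sites <- (sum(tab[c1, "S"]) + sum(tab[c2, "S"])) / 2
  N_sites <- (sum(tab[c1, "N"]) + sum(tab[c2, "N"])) / 2
  dif <- which(c1 != c2)
  nd <- 0
  sd <- 0
  for (i in dif) {
    cnt <- codon_path_counts(c1[i], c2[i])
    nd <- nd + cnt[["nd"]]
    sd <- sd + cnt[["sd"]]
  }
  pN <- nd / N_sites
  pS <- sd / S_sites
  dN <- .jc_correct(pN)
  dS <- .jc_correct(pS)
  saturated <- pN >= 0.75 || pS >= 0.75
  omega_undefined <- !saturated && dS == 0
  omega <- if (saturated || omega_undefined) NA_real_ else dN / dS
  data.frame(gene_id = gene_id, pair = pair, n_codons = length(c1),
             S_sites = S_sites, N_sites = N_sites, Sd = sd, Nd = nd,
             pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
             omega_undefined = omega_undefined, saturated = saturated,
             stringsAsFactors = FALSE)
}

#' GC content of a masked gametolog alignment
#'
#' Percent G+C over the retained alignment columns of each sequence, plus
#' the Z/W GC ratio (the degeneration contrast: the non-recombining W loses
#' GC relative to the recombining Z).
#'
#' @param seqs Named character vector with elements `Z`, `W` and optionally
#'   `outgroup` (already masked to common clean codons).
#' @param gene_id Optional label.
#' @return One-row data frame with `gc_Z`, `gc_W`, `gc_outgroup` (NA when
#'   absent) and `gc_ratio_ZW` (NA with a flag when `gc_W` is 0).
#' @export
gc_stats <- function(seqs, gene_id = NA_character_) {
  seqs <- toupper(unlist(seqs))
  if (!all(c("Z", "W") %in% names(seqs)))
    stop("seqs must contain elements named 'Z' and 'W'")
  if (any(nchar(seqs) == 0L)) stop("empty alignment")
  pct <- function(s) {
    b <- strsplit(s, "")[[1L]]
    100 * mean(b %in% c("G", "C"))
  }
  gz <- pct(seqs[["Z"]])
  gw <- pct(seqs[["W"]])
  go <- if ("outgroup" %in% names(seqs)) pct(seqs[["outgroup"]]) else NA_real_
  data.frame(gene_id = gene_id, gc_Z = gz, gc_W = gw, gc_outgroup = go,
             gc_ratio_ZW = if (gw > 0) gz / gw else NA_real_,
             gc_ratio_undefined = gw == 0,
             stringsAsFactors = FALSE)
}

#' Transcript selection filters for divergence analysis
#'
#' Drops transcripts whose retained (masked) alignment is shorter than
#' `min_len` base pairs or whose Z-W dS is below `min_ds` (counting
#' estimates need some silent divergence to be meaningful); when a gene has
#' several transcripts, the longest retained one is kept.
#'
#' @param tbl Data frame with columns `gene_id`, `transcript_id`,
#'   `retained_bp` and `dS`.
#' @param min_len Minimum retained alignment length in bp (default 500).
#' @param min_ds Minimum Z-W dS (default 0.01); transcripts with `dS` below
#'   this (or NA/saturated) are dropped.
#' @return List with `kept`, `removed` (with a `filter` reason column) and
#'   a named `counts` vector per filter.
#' @export
select_transcripts <- function(tbl, min_len = 500, min_ds = 0.01) {
  need <- c("gene_id", "transcript_id", "retained_bp", "dS")
  if (!all(need %in% names(tbl)))
    stop("tbl must have columns: ", paste(need, collapse = ", "))
  reason <- rep(NA_character_, nrow(tbl))
  reason[tbl$retained_bp < min_len] <- "short"
  bad_ds <- is.na(reason) & (is.na(tbl$dS) | tbl$dS < min_ds)
  reason[bad_ds] <- "low_ds"
  # longest transcript per gene among survivors
  surv <- which(is.na(reason))
  if (length(surv)) {
    ord <- surv[order(-tbl$retained_bp[surv], tbl$transcript_id[surv])]
    dup <- ord[duplicated(tbl$gene_id[ord])]
    reason[dup] <- "shorter_transcript"
  }
  kept <- tbl[is.na(reason), , drop = FALSE]
  removed <- cbind(tbl[!is.na(reason), , drop = FALSE],
                   filter = reason[!is.na(reason)])
  counts <- c(short = sum(reason == "short", na.rm = TRUE),
              low_ds = sum(reason == "low_ds", na.rm = TRUE),
              shorter_transcript = sum(reason == "shorter_transcript",
                                       na.rm = TRUE),
              kept = nrow(kept))
  list(kept = kept, removed = removed, counts = counts)
}

#' Paired Z-vs-W contrast against the outgroup
#'
#' Because Z and W split from each other after the outgroup split, both are
#' equally distant from the outgroup in the absence of selection; an excess
#' of non-synonymous divergence on the W-to-outgroup side therefore
#' indicates functional degeneration of W. Builds the per-gene paired table
#' of dN and dS to the outgroup and runs paired t-tests on both.
#'
#' @param div Data frame of [pairwise_dnds()] rows with `pair` labels
#'   `"Z-outgroup"` and `"W-outgroup"`.
#' @return List with the paired `table`, `t_dN` and `t_dS` (statistic, p,
#'   df, mean difference W - Z) and `n_excluded` (genes lacking one side or
#'   with NA rates).
#' @export
outgroup_contrast <- function(div) {
  zo <- div[div$pair == "Z-outgroup", c("gene_id", "dN", "dS")]
  wo <- div[div$pair == "W-outgroup", c("gene_id", "dN", "dS")]
  m <- merge(zo, wo, by = "gene_id", suffixes = c("_Z_out", "_W_out"))
  full <- stats::complete.cases(m[, -1L])
  n_excluded <- length(unique(div$gene_id)) - sum(full)
  m <- m[full, , drop = FALSE]
  tidy_t <- function(x, y) {
    if (nrow(m) < 2L || stats::sd(y - x) == 0)
      return(data.frame(statistic = NA_real_, p = NA_real_, df = NA_real_,
                        mean_diff = if (nrow(m)) mean(y - x) else NA_real_,
                        n = nrow(m)))
    tt <- stats::t.test(y, x, paired = TRUE)
    data.frame(statistic = unname(tt$statistic), p = tt$p.value,
               df = unname(tt$parameter), mean_diff = unname(tt$estimate),
               n = nrow(m))
  }
  list(table = m,
       t_dN = tidy_t(m$dN_Z_out, m$dN_W_out),
       t_dS = tidy_t(m$dS_Z_out, m$dS_W_out),
       n_excluded = n_excluded)
}

# full divergence + GC panel for one gene (Z, W, optional outgroup)
gene_divergence <- function(z, w, outgroup = NULL, gene_id = NA_character_) {
  seqs <- c(Z = z, W = w)
  if (!is.null(outgroup)) seqs <- c(seqs, outgroup = outgroup)
  mk <- mask_codons(seqs)
  if (mk$n_retained == 0L)
    return(list(div = NULL, gc = NULL, n_retained = 0L,
                n_dropped = mk$n_dropped))
  s <- mk$seqs
  div <- pairwise_dnds(s[["Z"]], s[["W"]], gene_id, "Z-W")
  if (!is.null(outgroup)) {
    div <- rbind(div,
                 pairwise_dnds(s[["Z"]], s[["outgroup"]], gene_id,
                               "Z-outgroup"),
                 pairwise_dnds(s[["W"]], s[["outgroup"]], gene_id,
                               "W-outgroup"))
  }
  list(div = div, gc = gc_stats(s, gene_id), n_retained = mk$n_retained,
       n_dropped = mk$n_dropped)
}
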