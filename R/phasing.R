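## Z/W phasing from sex-labelled diploid genotypes.
##
## Females are the heterogametic sex (ZW), males ZZ. At each variant site
## the male/female allele configuration either determines the Z and W
## alleles, determines only Z (with W masked), or is ambiguous and masked.
## Masking rules are applied in a fixed order; every call carries the id of
## the truth-table row that fired, so phased sequences are fully auditable.

.MASK_REASONS <- c("none", "low_qual", "low_depth", "missing_gt",
                   "multiallelic", "indel", "ambiguous", "female_discordant",
                   "z_tie", "no_record")

#' Construct a variant site
#'
#' @param ref Reference allele string.
#' @param alts Character vector of alternate alleles (may be empty for
#'   monomorphic records).
#' @param qual Phred-scaled site quality.
#' @param gt Character vector of unphased genotypes over allele indices
#'   (`"0/0"`, `"0/1"`, ... or `"./."`/`NA` when missing), one per sample.
#' @param dp Numeric vector of per-sample read depths.
#' @param sex Character vector of sample sexes, `"M"` or `"F"`.
#' @param contig,pos Optional coordinates, used in error messages.
#' @return A list of class `variant_site`.
#' @export
variant_site <- function(ref, alts = character(0), qual, gt, dp, sex,
                         contig = NA_character_, pos = NA_integer_) {
  alts <- alts[!is.na(alts) & alts != "."]
  sex <- toupper(sex)
  if (length(gt) != length(sex) || length(dp) != length(sex))
    stop("gt, dp and sex must have one entry per sample")
  if (!all(sex %in% c("M", "F")))
    stop("sex labels must be 'M' or 'F'")
  if (sum(sex == "M") < 1L || sum(sex == "F") < 1L)
    stop("need at least one male and one female sample")
  structure(list(ref = ref, alts = alts, qual = qual, gt = gt, dp = dp,
                 sex = sex, contig = contig, pos = pos),
            class = "variant_site")
}

site_call <- function(z, w, rule, reason, span = 1L) {
  list(z_allele = z, w_allele = w, rule_id = rule, mask_reason = reason,
       span = span)
}

#' Classify one variant site into Z and W alleles
#'
#' Applies the phasing truth table in order:
#' \enumerate{
#'   \item site QUAL < threshold, any sample depth < threshold, or any
#'     genotype missing: both alleles `N`;
#'   \item any allele longer than one base (indel): both `N` over a
#'     reference-length span;
#'   \item more than two distinct alleles observed among the samples: both
#'     `N`;
#'   \item every sample homozygous reference: `Z = W = ref`;
#'   \item all males homozygous for one allele `a` and all females
#'     identically heterozygous `a/b`: `Z = a`, `W = b` (both orientations);
#'   \item females not identical: `W = N`, `Z` from the consensus of rule 7;
#'   \item Z consensus: most common allele among male alleles plus alleles
#'     of homozygous females (whose W is determined); a tie masks `Z`;
#'   \item every sample homozygous for the same alternate: `Z = W = alt`;
#'     males homozygous `a`, females homozygous `b`: `Z = a`, `W = b`;
#'   \item anything else: both `N` (ambiguous).
#' }
#'
#' @param site A [variant_site()].
#' @param min_qual_depth Joint QUAL/DP threshold (default 20).
#' @return A list (`z_allele`, `w_allele`, `rule_id`, `mask_reason`,
#'   `span`); both alleles are single bases or `"N"`.
#' @examples
#' s <- variant_site("A", "G", qual = 50, gt = c("0/0", "0/0", "0/1", "0/1"),
#'                   dp = rep(30, 4), sex = c("M", "M", "F", "F"))
#' classify_site(s) # Z = reference A, W = variant G
#' @export
classify_site <- function(site, min_qual_depth = 20) {
  stopifnot(inherits(site, "variant_site"))
  span <- nchar(site$ref)
  maskall <- function(rule, reason) site_call("N", "N", rule, reason, span)

  # rule 1: joint quality/depth/missing filter
  if (is.na(site$qual) || site$qual < min_qual_depth)
    return(maskall("R1", "low_qual"))
  if (any(is.na(site$dp) | site$dp < min_qual_depth))
    return(maskall("R1", "low_depth"))
  gt <- site$gt
  if (any(is.na(gt) | gt %in% c("./.", ".", ".|.")))
    return(maskall("R1", "missing_gt"))

  # rule 2: indels mask a reference-length span
  if (any(nchar(c(site$ref, site$alts)) != 1L))
    return(maskall("R2", "indel"))

  sp <- strsplit(gt, "[/|]")
  if (any(lengths(sp) != 2L))
    stop("malformed genotype at ", site$contig, ":", site$pos, ": ",
         paste(gt[lengths(sp) != 2L], collapse = " "))
  idx <- suppressWarnings(matrix(as.integer(unlist(sp)), nrow = 2L))
  if (any(is.na(idx)))
    stop("malformed genotype encoding at ", site$contig, ":", site$pos)
  alleles <- c(site$ref, site$alts)
  if (any(idx + 1L > length(alleles)))
    stop("genotype allele index out of range at ", site$contig, ":", site$pos)
  A <- matrix(alleles[idx + 1L], nrow = 2L)
  obs <- unique(as.vector(A))

  # rule 3: tri-allelic (or worse) among the samples
  if (length(obs) > 2L)
    return(maskall("R3", "multiallelic"))

  male <- site$sex == "M"
  mA <- A[, male, drop = FALSE]
  fA <- A[, !male, drop = FALSE]
  hom <- A[1L, ] == A[2L, ]

  # rules 4 / 8a: everyone homozygous for one and the same allele
  if (all(hom) && length(obs) == 1L)
    return(site_call(obs, obs, if (obs == site$ref) "R4" else "R8a", "none",
                     span))

  f_keys <- apply(fA, 2L, function(a) paste(sort(a), collapse = "/"))
  f_identical <- length(unique(f_keys)) == 1L
  m_hom_same <- all(hom[male]) && length(unique(as.vector(mA))) == 1L

  if (f_identical) {
    f_hom <- fA[1L, 1L] == fA[2L, 1L]
    if (m_hom_same && !f_hom) {
      # rule 5: males homozygous a, females het a/b (either orientation)
      a <- mA[1L, 1L]
      pair <- fA[, 1L]
      if (a %in% pair)
        return(site_call(a, setdiff(pair, a), "R5", "none", span))
      return(maskall("R9", "ambiguous"))
    }
    if (m_hom_same && f_hom && fA[1L, 1L] != mA[1L, 1L]) {
      # rule 8b: males homozygous a, females homozygous b
      return(site_call(mA[1L, 1L], fA[1L, 1L], "R8b", "none", span))
    }
    return(maskall("R9", "ambiguous"))
  }

  # rules 6 + 7: discordant females -> W masked, Z by consensus vote.
  # Only alleles with a determined W contribute: all male alleles, plus one
  # allele per homozygous female. Ties mask Z.
  votes <- as.vector(mA)
  fhom <- which(fA[1L, ] == fA[2L, ])
  votes <- c(votes, fA[1L, fhom])
  tt <- table(votes)
  top <- names(tt)[tt == max(tt)]
  if (length(top) == 1L)
    return(site_call(top, "N", "R6", "female_discordant", span))
  site_call("N", "N", "R6", "z_tie", span)
}

# read a sample sex map: named vector ("M"/"F") or two-column file
read_sex_map <- function(sex) {
  if (is.character(sex) && length(sex) == 1L && file.exists(sex)) {
    df <- utils::read.table(sex, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    sex <- stats::setNames(toupper(df[[2L]]), df[[1L]])
  }
  sex
}

# read BED (0-based half-open, name column = transcript id)
read_bed <- function(bed) {
  if (is.character(bed) && length(bed) == 1L) {
    bed <- utils::read.table(bed, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  bed
}

#' Phase transcripts into Z and W sequences from a VCF
#'
#' Classifies every record with [classify_site()] and concatenates the calls
#' over the exon positions of each transcript (BED intervals, 0-based
#' half-open, name column = transcript id). Positions without a VCF record
#' are masked as `N`; indel records mask a reference-length span without
#' shifting coordinates.
#'
#' @param vcf Path to a VCF file (or a `vcfR` object).
#' @param bed Path to a BED file or a data frame with columns
#'   chrom/start/end/name.
#' @param sex Sample sex map: named `"M"`/`"F"` vector or path to a
#'   two-column (sample, sex) TSV.
#' @param min_qual_depth Joint QUAL/DP threshold passed to
#'   [classify_site()].
#' @return Named list of `phased_gametolog` objects: `transcript_id`,
#'   `z_seq`, `w_seq`, `n_sites_called`, `n_sites_masked`, an `audit` count
#'   table by mask reason and the per-site `calls` data frame.
#' @export
phase_transcripts <- function(vcf, bed, sex, min_qual_depth = 20) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  sex <- read_sex_map(sex)
  bed <- read_bed(bed)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  samples <- colnames(gt)
  if (!all(samples %in% names(sex)))
    stop("sex map is missing samples: ",
         paste(setdiff(samples, names(sex)), collapse = ", "))
  sexv <- unname(sex[samples])
  if (sum(sexv == "M") < 1L || sum(sexv == "F") < 1L)
    stop("need at least one male and one female sample")

  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  altstr <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  nrec <- length(pos)

  zc <- character(nrec)
  wc <- character(nrec)
  rule <- character(nrec)
  reason <- character(nrec)
  spanv <- rep(1L, nrec)

  gt_miss <- is.na(gt) | gt == "./." | gt == "." | gt == ".|."
  bad_q <- is.na(qual) | qual < min_qual_depth
  bad_d <- rowSums(is.na(dp) | dp < min_qual_depth) > 0L
  bad_g <- rowSums(gt_miss) > 0L

  # vectorized rule 1 (precedence: qual, depth, missing genotype)
  r1 <- bad_q | bad_d | bad_g
  zc[r1] <- "N"
  wc[r1] <- "N"
  rule[r1] <- "R1"
  reason[r1] <- ifelse(bad_q[r1], "low_qual",
                       ifelse(bad_d[r1], "low_depth", "missing_gt"))
  spanv[r1] <- nchar(ref[r1])   # low-quality indels still mask their span

  # vectorized rule 4: clean monomorphic hom-ref records
  no_alt <- is.na(altstr) | altstr == "."
  all_ref <- rowSums(gt != "0/0") == 0L
  r4 <- !r1 & no_alt & nchar(ref) == 1L & all_ref
  zc[r4] <- ref[r4]
  wc[r4] <- ref[r4]
  rule[r4] <- "R4"
  reason[r4] <- "none"

  # vectorized single-alt SNVs using only allele indices 0/1: classify each
  # distinct genotype pattern once on a template site, then map ref/alt back
  todo <- which(!r1 & !r4)
  if (length(todo)) {
    snv <- todo[nchar(ref[todo]) == 1L & !is.na(altstr[todo]) &
                  nchar(altstr[todo]) == 1L]
    if (length(snv)) {
      only01 <- snv[rowSums(matrix(!(gt[snv, , drop = FALSE] %in%
                                       c("0/0", "0/1", "1/0", "1/1")),
                                   nrow = length(snv))) == 0L]
      if (length(only01)) {
        key <- apply(gt[only01, , drop = FALSE], 1L, paste, collapse = " ")
        uk <- unique(key)
        calls <- lapply(strsplit(uk, " "), function(g) {
          classify_site(variant_site("A", "G", qual = 99,
                                     gt = g, dp = rep(99, length(g)),
                                     sex = sexv),
                        min_qual_depth)
        })
        ki <- match(key, uk)
        tz <- vapply(calls, `[[`, "", "z_allele")[ki]
        tw <- vapply(calls, `[[`, "", "w_allele")[ki]
        map <- function(t, i) ifelse(t == "A", ref[i],
                                     ifelse(t == "G", altstr[i], "N"))
        zc[only01] <- map(tz, only01)
        wc[only01] <- map(tw, only01)
        rule[only01] <- vapply(calls, `[[`, "", "rule_id")[ki]
        reason[only01] <- vapply(calls, `[[`, "", "mask_reason")[ki]
        todo <- setdiff(todo, only01)
      }
    }
    # remaining records (multi-allelic, indels, odd encodings): full path
    for (i in todo) {
      alts <- strsplit(ifelse(is.na(altstr[i]), ".", altstr[i]), ",")[[1L]]
      s <- variant_site(ref[i], alts, qual[i], gt[i, ], dp[i, ], sexv,
                        contig = fix[i, "CHROM"], pos = pos[i])
      cl <- classify_site(s, min_qual_depth)
      zc[i] <- cl$z_allele
      wc[i] <- cl$w_allele
      rule[i] <- cl$rule_id
      reason[i] <- cl$mask_reason
      spanv[i] <- cl$span
    }
  }

  out <- list()
  for (tr in unique(bed$name)) {
    ex <- bed[bed$name == tr, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    tpos <- unlist(lapply(seq_len(nrow(ex)),
                          function(j) (ex$start[j] + 1L):ex$end[j]))
    n <- length(tpos)
    z_seq <- rep("N", n)
    w_seq <- rep("N", n)
    rsn <- rep("no_record", n)
    rl <- rep(NA_character_, n)
    hit <- match(tpos, pos)
    got <- !is.na(hit)
    z_seq[got] <- zc[hit[got]]
    w_seq[got] <- wc[hit[got]]
    rsn[got] <- reason[hit[got]]
    rl[got] <- rule[hit[got]]
    # multi-base (indel) spans mask downstream positions too
    wide <- which(spanv > 1L & pos %in% tpos)
    for (i in wide) {
      cover <- which(tpos %in% pos[i]:(pos[i] + spanv[i] - 1L))
      z_seq[cover] <- "N"
      w_seq[cover] <- "N"
      rsn[cover] <- reason[i]
      rl[cover] <- rule[i]
    }
    called <- z_seq != "N" & w_seq != "N"
    audit <- table(factor(rsn, levels = .MASK_REASONS))
    out[[tr]] <- structure(
      list(transcript_id = tr,
           z_seq = paste(z_seq, collapse = ""),
           w_seq = paste(w_seq, collapse = ""),
           n_sites_called = sum(called),
           n_sites_masked = sum(!called),
           audit = audit,
           calls = data.frame(pos = tpos, z = z_seq, w = w_seq, rule = rl,
                              mask_reason = rsn, stringsAsFactors = FALSE)),
      class = "phased_gametolog")
  }
  out
}

#' @export
print.phased_gametolog <- function(x, ...) {
  cat(sprintf("<phased_gametolog> %s: %d sites (%d called, %d masked)\n",
              x$transcript_id, nchar(x$z_seq), x$n_sites_called,
              x$n_sites_masked))
  invisible(x)
}

#' Write phased gametologs as FASTA
#'
#' Headers are `<transcript_id>|Z` and `<transcript_id>|W`.
#'
#' @param phased List returned by [phase_transcripts()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_phased_fasta <- function(phased, path) {
  seqs <- character(0)
  for (p in phased) {
    seqs[paste0(p$transcript_id, "|Z")] <- p$z_seq
    seqs[paste0(p$transcript_id, "|W")] <- p$w_seq
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
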