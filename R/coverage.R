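## Coverage-based detection of W-gametolog loss. A female carries Z + W; if
## the W copy is gone she is hemizygous and her reads over that gene drop to
## half the male expectation, so transcripts where female coverage falls
## below 70% of the male coverage are flagged as W-absent.

#' Library-size multipliers from total aligned reads
#'
#' Each sample's counts are scaled up to the largest library:
#' `factor_i = max(total) / total_i`, so the largest library gets 1.0.
#'
#' @param totals Named numeric vector of total aligned reads per sample.
#' @return Named numeric vector of multipliers.
#' @examples
#' library_size_factors(c(a = 100, b = 80, c = 50, d = 100))
#' @export
library_size_factors <- function(totals) {
  totals <- unlist(totals)
  if (any(is.na(totals) | totals <= 0))
    stop("all library totals must be positive")
  max(totals) / totals
}

#' Per-transcript normalized coverage and female/male ratio
#'
#' Per-exon depth is `factor * count / exon_length`; the transcript value is
#' the unweighted mean over its exons; sex means average the samples of each
#' sex. `w_absent` flags transcripts whose female mean is below `threshold`
#' (strictly) times the male mean.
#'
#' @param counts Data frame with columns `sample`, `exon_id`,
#'   `transcript_id`, `count`, `exon_length`.
#' @param factors Named library-size multipliers from
#'   [library_size_factors()].
#' @param sex Named `"M"`/`"F"` vector over samples.
#' @param threshold Female/male ratio below which the W copy is deemed
#'   absent (default 0.7).
#' @return Data frame with one row per transcript: sex means, `fm_ratio`,
#'   `w_absent`.
#' @export
transcript_coverage <- function(counts, factors, sex, threshold = 0.7) {
  need <- c("sample", "exon_id", "transcript_id", "count", "exon_length")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  if (!all(counts$sample %in% names(factors)))
    stop("missing library-size factors for some samples")
  if (!all(counts$sample %in% names(sex)))
    stop("missing sex labels for some samples")
  depth <- factors[counts$sample] * counts$count / counts$exon_length
  # unweighted mean over exons per transcript x sample
  key <- paste(counts$transcript_id, counts$sample, sep = "\r")
  agg <- tapply(depth, key, mean)
  ks <- strsplit(names(agg), "\r", fixed = TRUE)
  tr <- vapply(ks, `[[`, "", 1L)
  sm <- vapply(ks, `[[`, "", 2L)
  sx <- sex[sm]
  trs <- unique(counts$transcript_id)
  female_mean <- tapply(agg[sx == "F"], tr[sx == "F"], mean)[trs]
  male_mean <- tapply(agg[sx == "M"], tr[sx == "M"], mean)[trs]
  if (any(is.na(female_mean)) || any(is.na(male_mean)))
    stop("every transcript needs counts for both sexes ",
         "(transcript with zero exons?)")
  fm <- unname(female_mean / male_mean)
  data.frame(transcript_id = trs,
             female_mean = unname(female_mean),
             male_mean = unname(male_mean),
             fm_ratio = fm,
             w_absent = fm < threshold,
             stringsAsFactors = FALSE)
}

#' Filter transcripts lacking a W gametolog
#'
#' Removes transcripts whose female/male coverage ratio is strictly below
#' the threshold; a ratio exactly at the threshold is retained.
#'
#' @param records Output of [transcript_coverage()].
#' @param threshold Removal threshold on `fm_ratio` (default 0.7).
#' @return List with `retained` and `removed` transcript ids and the
#'   decision `table`.
#' @export
filter_w_absent <- function(records, threshold = 0.7) {
  if (nrow(records) == 0L)
    return(list(retained = character(0), removed = character(0),
                table = cbind(records, removed = logical(0))))
  rm <- records$fm_ratio < threshold
  list(retained = records$transcript_id[!rm],
       removed = records$transcript_id[rm],
       table = cbind(records, removed = rm))
}
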