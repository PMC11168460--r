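## Targeted-MS quantification rules: reference-peptide normalization within
## sample pairs, paired log2 ratios, and gel-section protein normalization
## of ubiquitylation-site intensities.

#' Normalize modified-peptide PRM intensities by five reference peptides
#'
#' Within each sample, every modified (GG-remnant) peptide intensity is
#' divided by the sum of the intensities of five unmodified reference
#' peptides measured in the same sample. The reference set is fixed at
#' exactly five peptides; a missing or zero reference peptide aborts with
#' the offending sample and peptide named — the set is never silently
#' renormalized over a subset, which would bias the paired ratios.
#'
#' @param records long-format data.frame with columns \code{peptide_id},
#'   \code{modified} (logical), \code{sample_id}, \code{intensity} (and
#'   typically \code{site}, \code{pair_id}, \code{condition}).
#' @param referencePeptides character vector of exactly 5 unmodified
#'   reference peptide ids.
#' @return the records of modified peptides with an added
#'   \code{normalized_intensity} column (raw / per-sample reference sum).
#' @examples
#' tab <- simulatePrmTable(seed = 7)
#' head(normalizePrmPair(tab, paste0("ref", 1:5)))
#' @export
normalizePrmPair <- function(records, referencePeptides) {
  if (length(referencePeptides) != 5L)
    stop("exactly five reference peptides are required, got ",
         length(referencePeptides))
  records <- as.data.frame(records)
  stopifnot(all(c("peptide_id", "modified", "sample_id", "intensity") %in%
                  names(records)))
  if (any(!is.finite(records$intensity)) || any(records$intensity < 0))
    stop("intensities must be finite and >= 0")
  if (anyDuplicated(records[c("peptide_id", "sample_id")]))
    stop("(peptide_id, sample_id) pairs must be unique")
  samples <- unique(records$sample_id)
  refSum <- vapply(samples, function(s) {
    sub <- records[records$sample_id == s &
                     records$peptide_id %in% referencePeptides, ]
    missing <- setdiff(referencePeptides, sub$peptide_id)
    if (length(missing))
      stop("sample '", s, "' is missing reference peptide(s): ",
           paste(missing, collapse = ", "))
    zero <- sub$peptide_id[sub$intensity <= 0]
    if (length(zero))
      stop("sample '", s, "' has zero-intensity reference peptide(s): ",
           paste(zero, collapse = ", "))
    sum(sub$intensity)
  }, numeric(1))
  names(refSum) <- samples
  out <- records[records$modified, , drop = FALSE]
  out$normalized_intensity <- out$intensity / refSum[out$sample_id]
  rownames(out) <- NULL
  out
}

#' Paired log2 ratios of normalized intensities
#'
#' For each (pair, peptide), the log2 ratio of the wild-type-condition
#' normalized intensity over the control-condition one. Records with a
#' missing or zero normalized value in either condition are excluded from
#' the ratio table with a reason, never silently imputed. Peptides are kept
#' as separate rows even when two peptides cover the same site; site-level
#' aggregation is a deliberate, separate step for the caller.
#'
#' @param normalized output of [normalizePrmPair()] (must contain
#'   \code{pair_id} and \code{condition}).
#' @param numerator,denominator the condition labels forming the ratio
#'   (defaults \code{"wt"} over \code{"C221A"}).
#' @return data.frame with \code{pair_id}, \code{peptide_id}, \code{site},
#'   per-condition normalized intensities and \code{log2_ratio}; attribute
#'   \code{"excluded"} lists dropped records with reasons.
#' @export
log2PairRatio <- function(normalized, numerator = "wt",
                          denominator = "C221A") {
  df <- as.data.frame(normalized)
  stopifnot(all(c("pair_id", "peptide_id", "condition",
                  "normalized_intensity") %in% names(df)))
  keys <- unique(df[c("pair_id", "peptide_id")])
  rows <- list(); dropped <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$pair_id == keys$pair_id[i] &
                df$peptide_id == keys$peptide_id[i], ]
    num <- sub$normalized_intensity[sub$condition == numerator]
    den <- sub$normalized_intensity[sub$condition == denominator]
    site <- if ("site" %in% names(sub)) sub$site[1] else NA_character_
    reason <- NULL
    if (length(num) != 1L || length(den) != 1L)
      reason <- "missing-condition"
    else if (!is.finite(num) || !is.finite(den) || num <= 0 || den <= 0)
      reason <- "zero-or-missing-intensity"
    if (is.null(reason)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = keys$pair_id[i], peptide_id = keys$peptide_id[i],
        site = site, normalized_num = num, normalized_den = den,
        log2_ratio = log2(num / den))
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        pair_id = keys$pair_id[i], peptide_id = keys$peptide_id[i],
        site = site, reason = reason)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), peptide_id = character(0),
               site = character(0), normalized_num = numeric(0),
               normalized_den = numeric(0), log2_ratio = numeric(0))
  attr(out, "excluded") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(pair_id = character(0), peptide_id = character(0),
               site = character(0), reason = character(0))
  out
}

#' Normalize site intensities by protein intensity per gel section
#'
#' Divides each ubiquitylation-site intensity by the intensity of the
#' parent protein measured in the same gel section; sections are never
#' mixed. A zero protein intensity aborts with the section named.
#'
#' @param siteTable data.frame with columns \code{site}, \code{section},
#'   \code{site_intensity}, \code{protein_intensity}.
#' @return the table with an added \code{normalized_intensity} column
#'   (site / protein, within section).
#' @export
normalizeSiteByGelSection <- function(siteTable) {
  df <- as.data.frame(siteTable)
  stopifnot(all(c("site", "section", "site_intensity",
                  "protein_intensity") %in% names(df)))
  bad <- unique(df$section[df$protein_intensity <= 0])
  if (length(bad))
    stop("zero protein intensity in gel section(s): ",
         paste(bad, collapse = ", "))
  df$normalized_intensity <- df$site_intensity / df$protein_intensity
  df
}
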