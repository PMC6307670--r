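## Expression triage: filter transposable-element transcripts by masked
## length and divergence, then classify their TPM against the quartiles of
## a single-copy reference gene set.  "Highly expressed" means strictly
## above the reference third quartile.

#' Filter TE-containing transcripts
#'
#' Retains transcripts with at least `min_masked_bp` of masked (TE-derived)
#' sequence and divergence from the repeat library consensus at most
#' `max_divergence`.  Order is preserved and the filter is idempotent.
#'
#' @param records data.frame with at least `masked_bp` and `divergence`
#'   columns (fractions in `[0,1]`).
#' @param min_masked_bp minimum masked length in nt (default 200).
#' @param max_divergence maximum divergence (default 0.20, inclusive).
#' @return the retained rows of `records`.
#' @export
filter_te_transcripts <- function(records, min_masked_bp = 200,
                                  max_divergence = 0.20) {
  stopifnot(is.data.frame(records),
            all(c("masked_bp", "divergence") %in% names(records)))
  if (any(records$masked_bp < 0, na.rm = TRUE)) {
    stop("validation error: negative masked_bp")
  }
  if (any(records$divergence < 0 | records$divergence > 1, na.rm = TRUE)) {
    stop("validation error: divergence outside [0,1]")
  }
  keep <- records$masked_bp >= min_masked_bp &
    records$divergence <= max_divergence
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Reference-set expression tiers (first and third TPM quartiles)
#'
#' Quartiles use linear interpolation between closest ranks
#' (`stats::quantile` type 7), the convention documented for this package.
#'
#' @param reference_tpms numeric vector of reference-gene TPM values
#'   (length >= 4).
#' @return object of class `expression_tiers` with fields `q1`, `q3`, `n`.
#' @export
expression_tiers <- function(reference_tpms) {
  reference_tpms <- reference_tpms[!is.na(reference_tpms)]
  if (length(reference_tpms) < 4) {
    stop("validation error: need >= 4 reference TPM values")
  }
  if (any(reference_tpms < 0)) stop("validation error: negative TPM")
  q <- stats::quantile(reference_tpms, c(0.25, 0.75), names = FALSE,
                       type = 7)
  structure(list(q1 = q[1], q3 = q[2], n = length(reference_tpms)),
            class = "expression_tiers")
}

#' Classify a TPM value against reference tiers
#'
#' `high` means strictly greater than the third quartile, `low` strictly
#' less than the first; values equal to a threshold are `mid`.
#'
#' @param tpm numeric vector of TPM values (>= 0).
#' @param tiers an [expression_tiers()] object.
#' @return character vector in `{low, mid, high}`.
#' @export
classify_expression <- function(tpm, tiers) {
  stopifnot(inherits(tiers, "expression_tiers"))
  if (any(tpm < 0, na.rm = TRUE)) stop("validation error: negative TPM")
  ifelse(tpm > tiers$q3, "high", ifelse(tpm < tiers$q1, "low", "mid"))
}

#' Band TE transcripts by their TE-sequence fraction
#'
#' Chimera triage: transcripts mostly (>= 90%) composed of TE sequence are
#' likely genuine TE transcripts; low fractions (< 60%) suggest chimeras or
#' misassemblies.
#'
#' @param records data.frame with `masked_bp` and `transcript_length`.
#' @return data.frame of counts and fractions per band
#'   (`<60%`, `60-90%`, `>=90%`).
#' @export
te_fraction_bands <- function(records) {
  frac <- records$masked_bp / records$transcript_length
  band <- cut(frac, c(-Inf, 0.6, 0.9, Inf),
              labels = c("<60%", "60-90%", ">=90%"), right = FALSE)
  tab <- table(band)
  data.frame(band = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab))
}
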