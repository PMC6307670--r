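## Insertion-time dating: calibrate a per-lineage neutral substitution rate
## from ortholog Ks and a known divergence time, date each genomic copy
## against the species consensus (ancestral proxy) with T = k/2r, and
## profile proliferation bursts and quiescence gaps along the age axis.

#' Calibrate a lineage neutral rate from mean Ks and a divergence time
#'
#' r = mean_ks / (2 * divergence_time_my * 1e6), substitutions per site per
#' year.  The result carries its unit tag; downstream dating refuses a bare
#' number, so a per-My rate can never be fed where a per-year rate is
#' expected.
#'
#' @param mean_ks mean synonymous divergence of the calibration gene set
#'   against the counterpart lineage (> 0).
#' @param divergence_time_my divergence time of that species pair in My
#'   (> 0).
#' @param lineage label for the lineage.
#' @param saturated propagate a saturation flag from the Ks stage.
#' @return object of class `neutral_rate`: `lineage`, `r`, `unit`,
#'   `mean_ks`, `divergence_time_my`, `saturated`.
#' @export
neutral_rate <- function(mean_ks, divergence_time_my, lineage = "lineage",
                         saturated = FALSE) {
  if (!is.finite(mean_ks) || mean_ks <= 0) {
    stop("validation error: mean_ks must be > 0")
  }
  if (!is.finite(divergence_time_my) || divergence_time_my <= 0) {
    stop("validation error: divergence_time_my must be > 0")
  }
  structure(list(lineage = lineage,
                 r = mean_ks / (2 * divergence_time_my * 1e6),
                 unit = "substitutions/site/year",
                 mean_ks = mean_ks,
                 divergence_time_my = divergence_time_my,
                 saturated = isTRUE(saturated)),
            class = "neutral_rate")
}

#' Per-site divergence of one copy against the consensus (JC-corrected)
#' @noRd
nt_divergence <- function(copy, consensus) {
  if (nchar(copy) == nchar(consensus)) {
    p <- p_distance(copy, consensus)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(copy)),
      Biostrings::DNAString(toupper(consensus)), type = "global-local",
      substitutionMatrix = dna_submat(),
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ok <- pa %in% BASES & sa %in% BASES
    if (!any(ok)) return(NA_real_)
    p <- mean(pa[ok] != sa[ok])
  }
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Date genomic copies against the species consensus
#'
#' k is the synonymous divergence (Ks) of the copy against the consensus,
#' or the whole-element JC nucleotide distance for copies without an intact
#' ORF (`mode = "nucleotide"`, flagged in the output).  T = k / (branches
#' * r), reported in My.  The default `branches = 2` is the convention of
#' the dating literature (copy and counterpart both diverging from their
#' common ancestor); `branches = 1` treats the consensus as the ancestral
#' state itself, so divergence accrues on a single branch.
#'
#' @param copies named character vector of copy sequences (coding, in
#'   frame, for `mode = "ks"`).
#' @param species_consensus consensus sequence (same frame for
#'   `mode = "ks"`).
#' @param rate a [neutral_rate()] object (a bare number is refused).
#' @param mode `"ks"` or `"nucleotide"`.
#' @param branches 2 (default) or 1; see above.
#' @param min_codons minimum codons for the Ks mode.
#' @return data.frame of class `copy_age_table`: copy, k, T_my, mode,
#'   branches; skipped copies carry `NA` k with a note.
#' @export
copy_ages <- function(copies, species_consensus, rate,
                      mode = c("ks", "nucleotide"), branches = 2,
                      min_codons = 10) {
  if (!inherits(rate, "neutral_rate")) {
    stop("unit error: `rate` must be a neutral_rate object ",
         "(substitutions/site/year), not a bare number")
  }
  mode <- match.arg(mode)
  stopifnot(branches %in% c(1, 2))
  ids <- if (is.null(names(copies))) paste0("copy", seq_along(copies)) else
    names(copies)
  k <- numeric(length(copies))
  note <- character(length(copies))
  for (i in seq_along(copies)) {
    res <- tryCatch({
      if (mode == "ks") {
        aln <- codon_align(copies[[i]], species_consensus)
        rec <- ks_ng86(aln, min_codons = min_codons)
        if (rec$flag != "ok") stop("Ks flag: ", rec$flag)
        rec$ks
      } else {
        kv <- nt_divergence(copies[[i]], species_consensus)
        if (is.na(kv)) stop("saturated or unalignable")
        kv
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      k[i] <- NA_real_
      note[i] <- conditionMessage(res)
    } else {
      k[i] <- res
      note[i] <- ""
    }
  }
  out <- data.frame(copy = ids, k = k,
                    T_my = k / (branches * rate$r) / 1e6,
                    mode = mode, branches = branches, note = note)
  class(out) <- c("copy_age_table", class(out))
  out
}

#' Entry-time summary for one species
#'
#' The invasion date is bounded by the oldest copy.  Divergence from the
#' consensus (ancestral proxy) accrues on a single branch, so the entry
#' estimate uses k / r regardless of the per-copy dating convention.
#' `"p95"` (default) takes the robust 95th percentile of per-copy
#' divergence, appropriate when transposition continued after arrival;
#' `"max"` takes the oldest copy outright; `"mean"` averages all copies
#' and is the efficient choice when proliferation is burst-on-arrival, so
#' that every copy dates the invasion itself (per-copy Poisson noise then
#' cancels instead of inflating the upper quantiles).
#'
#' @param age_table a [copy_ages()] result.
#' @param rate the [neutral_rate()] used to build it.
#' @param method `"p95"` (default), `"max"` or `"mean"`.
#' @return entry time estimate in My.
#' @export
estimate_entry_time <- function(age_table, rate,
                                method = c("p95", "max", "mean")) {
  stopifnot(inherits(age_table, "copy_age_table"),
            inherits(rate, "neutral_rate"))
  method <- match.arg(method)
  k <- age_table$k[is.finite(age_table$k)]
  if (!length(k)) stop("validation error: no dated copies")
  kk <- switch(method, p95 = stats::quantile(k, 0.95, names = FALSE),
               max = max(k), mean = mean(k))
  kk / rate$r / 1e6
}

#' Proliferation bursts and quiescence gaps along the age axis
#'
#' Ages are clustered by single linkage: any inter-age spacing of at least
#' `gap_threshold_my` splits bursts and is reported as a quiescence gap.
#'
#' @param ages numeric copy ages in My (>= 5 values).
#' @param gap_threshold_my minimum gap width (default 0.1 My).
#' @return list with `bursts` (start, end, n, fraction; youngest first) and
#'   `gaps` (from, to, width).
#' @export
proliferation_profile <- function(ages, gap_threshold_my = 0.1) {
  ages <- ages[is.finite(ages)]
  if (length(ages) < 5) stop("validation error: need >= 5 ages")
  a <- sort(ages)
  gaps_w <- diff(a)
  cut_at <- which(gaps_w >= gap_threshold_my)
  starts <- c(1L, cut_at + 1L)
  ends <- c(cut_at, length(a))
  bursts <- data.frame(
    start = a[starts], end = a[ends],
    n = ends - starts + 1L,
    fraction = (ends - starts + 1L) / length(a))
  gaps <- if (length(cut_at)) {
    data.frame(from = a[cut_at], to = a[cut_at + 1L],
               width = a[cut_at + 1L] - a[cut_at])
  } else {
    data.frame(from = numeric(0), to = numeric(0), width = numeric(0))
  }
  list(bursts = bursts, gaps = gaps)
}
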