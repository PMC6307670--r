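## Neutral sequence evolution under Jukes-Cantor (uniform rates among
## sites).  Substitution events are Poisson on the branch; each event
## replaces the current base by one of the other three, uniformly.  Coding
## mode rejects events that would create an in-frame stop codon, which
## emulates restricting downstream Ks analysis to intact open reading
## frames.

#' Evolve a non-coding DNA string along one branch
#'
#' @param seq DNA character string.
#' @param rate substitutions per site per year.
#' @param years branch duration in years.
#' @return evolved DNA character string.
#' @noRd
evolve_noncoding <- function(seq, rate, years) {
  L <- nchar(seq)
  if (L == 0 || rate <= 0 || years <= 0) return(seq)
  m <- stats::rpois(1, L * rate * years)
  if (m == 0) return(seq)
  ob <- codon_tables()$other_bases
  bases <- strsplit(seq, "")[[1]]
  pos <- sample.int(L, m, replace = TRUE)
  pick <- sample.int(3L, m, replace = TRUE)
  for (i in seq_len(m)) {
    p <- pos[i]
    alt <- ob[[bases[p]]]
    if (is.null(alt)) next                  # N or gap: leave untouched
    bases[p] <- alt[pick[i]]
  }
  paste(bases, collapse = "")
}

#' Evolve an in-frame coding sequence, rejecting stop-creating events
#'
#' Events whose three alternative target bases all create a stop codon are
#' dropped (does not occur for sense codons under the standard code at any
#' single position, but guarded anyway).
#' @noRd
evolve_coding <- function(codon_idx, rate, years) {
  tb <- codon_tables()
  nc <- length(codon_idx)
  L <- 3L * nc
  if (L == 0 || rate <= 0 || years <= 0) return(codon_idx)
  m <- stats::rpois(1, L * rate * years)
  if (m == 0) return(codon_idx)
  alt_tab <- tb$alt_nonstop
  sites <- sample.int(L, m, replace = TRUE)
  u <- stats::runif(m)
  for (i in seq_len(m)) {
    s <- sites[i]
    cod <- (s - 1L) %/% 3L + 1L
    p <- s - 3L * (cod - 1L)
    alt <- alt_tab[[(codon_idx[cod] - 1L) * 3L + p]]
    na <- length(alt)
    if (na == 0L) next
    codon_idx[cod] <- alt[1L + as.integer(u[i] * na)]
  }
  codon_idx
}

#' Evolve a coding DNA string (wrapper over codon indices)
#' @noRd
evolve_coding_seq <- function(seq, rate, years) {
  idx <- codon_index(seq_to_codons(seq))
  idx <- evolve_coding(idx, rate, years)
  paste(codon_tables()$codons[idx], collapse = "")
}

#' Evolve a structured TE sequence
#'
#' The ORF region evolves in stop-avoiding coding mode; everything outside
#' it (TIRs, spacers) evolves as plain neutral DNA.
#' @param te list with fields seq, orf_start, orf_end (1-based, inclusive,
#'   orf length divisible by 3).
#' @noRd
evolve_te_seq <- function(seq, orf_start, orf_end, rate, years) {
  left <- if (orf_start > 1) substr(seq, 1, orf_start - 1) else ""
  orf <- substr(seq, orf_start, orf_end)
  right <- if (orf_end < nchar(seq)) substr(seq, orf_end + 1, nchar(seq)) else ""
  paste0(
    evolve_noncoding(left, rate, years),
    evolve_coding_seq(orf, rate, years),
    evolve_noncoding(right, rate, years)
  )
}

#' Proportion of differing sites between two equal-length strings
#' @noRd
p_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  ok <- x %in% BASES & y %in% BASES
  if (!any(ok)) return(NA_real_)
  mean(x[ok] != y[ok])
}
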