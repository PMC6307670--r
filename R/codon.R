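## Codon bookkeeping shared by the simulator, the Ks engine and the ORF
## scanner.  All tables are built once per session from the standard genetic
## code and cached in a package environment.

.ate_env <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' @noRd
codon_tables <- function() {
  if (!is.null(.ate_env$codons)) {
    return(as.list(.ate_env))
  }
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)                      # 64 codons, TTT..GGG order
  aa <- unname(gc_map)
  is_stop <- aa == "*"
  sense <- which(!is_stop)

  ## codon index after substituting base b at position p: [64, 3, 4]
  split_mat <- do.call(rbind, strsplit(codons, ""))
  mut <- array(0L, dim = c(64L, 3L, 4L))
  for (p in 1:3) {
    for (b in 1:4) {
      tmp <- split_mat
      tmp[, p] <- BASES[b]
      mut[, p, b] <- match(paste0(tmp[, 1], tmp[, 2], tmp[, 3]), codons)
    }
  }

  ## NG86 synonymous site count per codon (changes to stop codons count as
  ## nonsynonymous; each position contributes syn/3)
  syn_sites <- numeric(64)
  for (ci in sense) {
    s <- 0
    for (p in 1:3) {
      alt <- setdiff(mut[ci, p, ], ci)
      s <- s + sum(aa[alt] == aa[ci] & !is_stop[alt]) / 3
    }
    syn_sites[ci] <- s
  }

  ## non-stop alternative codons per (codon, position), for the mutation
  ## event loop: alt_nonstop[[(codon - 1) * 3 + pos]]
  alt_nonstop <- vector("list", 64L * 3L)
  for (ci in 1:64) {
    for (p in 1:3) {
      alt <- setdiff(mut[ci, p, ], ci)
      alt_nonstop[[(ci - 1L) * 3L + p]] <- alt[!is_stop[alt]]
    }
  }
  other_bases <- lapply(1:4, function(b) BASES[-b])
  names(other_bases) <- BASES

  .ate_env$codons <- codons
  .ate_env$aa <- aa
  .ate_env$is_stop <- is_stop
  .ate_env$sense <- sense
  .ate_env$mut <- mut
  .ate_env$syn_sites <- syn_sites
  .ate_env$split_mat <- split_mat
  .ate_env$alt_nonstop <- alt_nonstop
  .ate_env$other_bases <- other_bases
  as.list(.ate_env)
}

#' @noRd
codon_index <- function(codon_strings) {
  tb <- codon_tables()
  idx <- match(toupper(codon_strings), tb$codons)
  if (anyNA(idx)) {
    stop("non-ACGT codon encountered: ",
         paste(unique(codon_strings[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Split an in-frame DNA string into codon strings
#' @noRd
seq_to_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  n <- n - n %% 3
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Pathway-averaged NG86 difference counts for one codon pair.
#'
#' Enumerates every ordering of the differing positions, discards pathways
#' passing through stop codons (falling back to all pathways when none
#' survive), and averages the per-step synonymous/nonsynonymous counts.
#' Returns c(sd, nd).
#' @noRd
ng86_pair_counts <- function(ci, cj) {
  tb <- codon_tables()
  if (ci == cj) return(c(0, 0))
  pos <- which(tb$split_mat[ci, ] != tb$split_mat[cj, ])
  orders <- switch(length(pos),
    list(pos),
    list(pos, rev(pos)),
    {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  walk <- function(order) {
    cur <- ci
    sd <- nd <- 0
    ok <- TRUE
    for (p in order) {
      tgt_base <- match(tb$split_mat[cj, p], BASES)
      nxt <- tb$mut[cur, p, tgt_base]
      if (tb$is_stop[nxt]) ok <- FALSE
      if (tb$aa[nxt] == tb$aa[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, ok)
  }
  res <- vapply(orders, walk, numeric(3))
  keep <- res[3, ] == 1
  if (!any(keep)) keep <- rep(TRUE, ncol(res))  # all paths stop-blocked
  c(mean(res[1, keep]), mean(res[2, keep]))
}

#' Full 64 x 64 pathway-averaged difference tables, cached.
#' @noRd
ng86_tables <- function() {
  if (!is.null(.ate_env$sd_tab)) {
    return(list(sd = .ate_env$sd_tab, nd = .ate_env$nd_tab))
  }
  tb <- codon_tables()
  sd_tab <- nd_tab <- matrix(NA_real_, 64, 64)
  for (ci in tb$sense) {
    sd_tab[ci, ci] <- nd_tab[ci, ci] <- 0
    for (cj in tb$sense) {
      if (cj <= ci) next
      cnt <- ng86_pair_counts(ci, cj)
      sd_tab[ci, cj] <- sd_tab[cj, ci] <- cnt[1]
      nd_tab[ci, cj] <- nd_tab[cj, ci] <- cnt[2]
    }
  }
  .ate_env$sd_tab <- sd_tab
  .ate_env$nd_tab <- nd_tab
  list(sd = sd_tab, nd = nd_tab)
}

#' Translate an in-frame DNA string (standard code), "*" for stops
#' @noRd
translate_codons <- function(seq) {
  tb <- codon_tables()
  cods <- seq_to_codons(seq)
  if (!length(cods)) return("")
  paste(tb$aa[codon_index(cods)], collapse = "")
}

#' Reverse complement of a DNA character string
#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Draw a random in-frame coding sequence with no internal stops
#' @noRd
random_coding <- function(n_codons) {
  tb <- codon_tables()
  idx <- sample(tb$sense, n_codons, replace = TRUE)
  paste(tb$codons[idx], collapse = "")
}

#' Random DNA of length n
#' @noRd
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}
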