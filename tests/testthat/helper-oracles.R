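# Independent oracles used by the test suite.  These re-derive expected
# values through routes deliberately different from the package internals:
# recursive pathway enumeration for NG86, direct numerical integration for
# the studentized-range CDF, and naive scans for ORFs and distances.

GENCODE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GENCODE)[GENCODE != "*"]

random_sense_codons <- function(n) {
  sample(SENSE_CODONS, n, replace = TRUE)
}

# Mutate a codon vector: per-codon substitution prob per position, skipping
# mutations that create stops (mirrors intact-ORF sampling).
mutate_codons <- function(cods, per_site_p) {
  for (i in seq_along(cods)) {
    for (p in 1:3) {
      if (stats::runif(1) < per_site_p) {
        cur <- strsplit(cods[i], "")[[1]]
        for (b in sample(setdiff(c("A", "C", "G", "T"), cur[p]))) {
          cand <- cur; cand[p] <- b
          cand <- paste(cand, collapse = "")
          if (GENCODE[[cand]] != "*") { cods[i] <- cand; break }
        }
      }
    }
  }
  cods
}

# --- NG86 brute-force oracle -------------------------------------------

# Fraction of synonymous sites in one codon (stop targets nonsynonymous).
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- GENCODE[[codon]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      alt <- ch; alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (GENCODE[[alt]] != "*" && GENCODE[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Recursive enumeration of substitution pathways between two codons,
# discarding those visiting a stop codon (fall back to all if none valid).
oracle_pair_diffs <- function(ca, cb) {
  if (ca == cb) return(c(0, 0))
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, blocked)
      return(invisible(NULL))
    }
    for (ri in seq_along(remaining)) {
      p <- remaining[ri]
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(cb, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      syn <- GENCODE[[nxt]] == GENCODE[[cur]] && GENCODE[[nxt]] != "*"
      recurse(nxt, remaining[-ri],
              sd + as.numeric(syn), nd + as.numeric(!syn),
              blocked || GENCODE[[nxt]] == "*")
    }
  }
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  recurse(ca, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  valid <- m[, 3] == 0
  if (!any(valid)) valid <- rep(TRUE, nrow(m))
  c(mean(m[valid, 1]), mean(m[valid, 2]))
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  dif <- mapply(function(a, b) oracle_pair_diffs(a, b),
                codons_a, codons_b)
  Sd <- sum(dif[1, ]); Nd <- sum(dif[2, ])
  pS <- Sd / S; pN <- Nd / N
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       ks = if (pS < 0.75) -0.75 * log(1 - 4 * pS / 3) else NA_real_,
       ka = if (pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA_real_)
}

# --- studentized range CDF by direct integration -----------------------

# P(Q <= q) for k groups and df degrees of freedom:
#   F(q) = int_0^inf chi_df(s) * k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1)
#          dz ds
oracle_tukey_cdf <- function(q, k, df, n_outer = 120, n_inner = 120) {
  gl <- pracma::gaussLegendre(n_inner, -8, 8)
  inner <- function(s) {
    vals <- stats::dnorm(gl$x) *
      (stats::pnorm(gl$x) - stats::pnorm(gl$x - q * s))^(k - 1)
    k * sum(gl$w * vals)
  }
  # chi distribution of s = sqrt(chi2_df / df)
  gs <- pracma::gaussLegendre(n_outer, 1e-6, 4)
  dens <- function(s) {
    exp((df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2 + log(2))
  }
  sum(gs$w * dens(gs$x) * vapply(gs$x, inner, numeric(1)))
}

# --- naive six-frame ORF scan ------------------------------------------

oracle_orfs <- function(seq, min_len_nt) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") seq else rc
    L <- nchar(w)
    for (f in 0:2) {
      i <- f + 1
      run_start <- i
      while (i + 2 <= L) {
        cod <- substr(w, i, i + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (i - run_start >= min_len_nt) {
            out[[length(out) + 1L]] <- c(strand = strand,
                                         start = run_start - 1,
                                         end = i - 1)
          }
          run_start <- i + 3
        }
        i <- i + 3
      }
      last_end <- f + 3 * ((L - f) %/% 3)
      if (last_end + 1 - run_start >= min_len_nt) {
        out[[length(out) + 1L]] <- c(strand = strand, start = run_start - 1,
                                     end = last_end)
      }
    }
  }
  if (!length(out)) return(NULL)
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  # map minus-strand working coordinates back to the input
  L <- nchar(seq)
  minus <- df$strand == "-"
  s <- df$start; e <- df$end
  df$start[minus] <- L - e[minus]
  df$end[minus] <- L - s[minus]
  df[order(df$start, df$end, df$strand), ]
}

# brute-force mean pairwise distance (p model, pairwise deletion)
oracle_pi_p <- function(seqs) {
  n <- length(seqs)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      tot <- tot + mean(a[ok] != b[ok]); cnt <- cnt + 1
    }
  }
  tot / cnt
}

# small fixed-seed simulated world shared across tests
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ## four carrier species whose transfer order conflicts with the
      ## species topology, plus one never-invaded species (Dfic)
      cfg <- simulation_config(
        seed = 42,
        species_tree = paste0("(((Sinv:20,Aech:20):15,Mrot:35):15,",
                              "(Dgri:40,Dfic:40):10);"),
        rates = c(Sinv = 3.5e-9, Aech = 3.5e-9, Mrot = 3.5e-9,
                  Dgri = 3.5e-9, Dfic = 3.5e-9),
        n_nuclear_genes = 40, gene_length_codons = 150,
        htt_events = data.frame(
          recipient = c("Sinv", "Dgri", "Aech", "Mrot"),
          time_my = c(2.5, 2.0, 1.2, 0.7),
          lambda = c(2.2, 2.0, 2.5, 3.5)),
        genome_length = 3e5, max_copies = 80, n_reference_genes = 120)
      cache <<- list(config = cfg, world = simulate_world(cfg))
    }
    cache
  }
})
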