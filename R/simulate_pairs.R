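## Brother-pair genomes for the insertion-polymorphism survey: each family
## is a pair of haploid brothers sharing maternal haplotypes in IBD blocks
## (near-zero SNP density) and differing elsewhere; non-reference element
## insertions carry target-site duplications and are supported by junction
## reads from both sides of the breakpoint.

#' Simulate brother-pair SNP tables, insertion truth and junction reads
#'
#' @param config a [simulation_config()].
#' @return list with `snps` (chrom, pos, family), `reads` (BED-like junction
#'   read table), `reference` (reference pseudochromosome sequence),
#'   `windows_per_family`, and `truth` (insertion truth table, realized IBD
#'   fractions, effective genomes surveyed).
#' @export
simulate_brother_pairs <- function(config) {
  validate_config(config)
  if (config$n_families < 1) stop("configuration error: n_families >= 1")
  set.seed(child_seed(config$seed, "brothers"))
  win_bp <- 10000L
  n_win <- max(1L, as.integer(config$genome_length %/% win_bp))
  chrom <- "chr1"
  fams <- paste0("F", seq_len(config$n_families))

  if (config$ibd_fraction == 1 && config$snp_rate_nonibd > 0) {
    warning("ibd_fraction = 1: no non-IBD SNPs emitted")
  }

  ## IBD block structure: alternating geometric blocks with mean IBD block
  ## 30 windows (300 kb), non-IBD mean chosen to hit the target fraction
  mean_ibd <- 30
  f <- config$ibd_fraction
  mean_non <- if (f >= 1) 0 else if (f <= 0) 1e9 else mean_ibd * (1 - f) / f

  snps <- list(); states <- list()
  for (fam in fams) {
    st <- logical(0)                       # TRUE = IBD
    cur <- stats::runif(1) < f
    while (length(st) < n_win) {
      len <- if (cur) {
        1L + stats::rgeom(1, 1 / mean_ibd)
      } else if (mean_non == 0) 0L else 1L + stats::rgeom(1, 1 / mean_non)
      if (f >= 1) { st <- rep(TRUE, n_win); break }
      if (f <= 0) { st <- rep(FALSE, n_win); break }
      st <- c(st, rep(cur, len))
      cur <- !cur
    }
    st <- st[seq_len(n_win)]
    counts <- stats::rpois(n_win,
                           ifelse(st, config$snp_rate_ibd,
                                  config$snp_rate_nonibd))
    pos <- unlist(lapply(which(counts > 0), function(w) {
      (w - 1L) * win_bp + sample.int(win_bp, counts[w])
    }))
    snps[[fam]] <- data.frame(
      chrom = chrom,
      pos = if (length(pos)) sort(as.integer(pos)) else integer(0),
      family = fam)
    states[[fam]] <- st
  }
  snp_tbl <- do.call(rbind, snps)
  rownames(snp_tbl) <- NULL

  reference <- random_dna(config$genome_length)

  ## insertion loci: family-specific (one family) and common (>= 2 families)
  t <- config$tsd_len
  n_common <- if (config$n_families >= 2) 6L else 0L
  n_fs_per_fam <- pmax(2L, stats::rpois(config$n_families,
                                        config$insertions_per_family))
  loci <- list(); k <- 0L
  used <- integer(0)
  draw_pos <- function() {
    repeat {
      p <- sample.int(config$genome_length - 200L, 1) + 100L
      if (!length(used) || min(abs(used - p)) > 500) return(p)
    }
  }
  for (i in seq_len(n_common)) {
    k <- k + 1L
    p <- draw_pos(); used <- c(used, p)
    carriers <- sample(fams, sample(2:config$n_families, 1))
    loci[[k]] <- list(id = paste0("L", k), pos = p, families = carriers,
                      class = "common")
  }
  for (j in seq_along(fams)) {
    for (i in seq_len(n_fs_per_fam[j])) {
      k <- k + 1L
      p <- draw_pos(); used <- c(used, p)
      loci[[k]] <- list(id = paste0("L", k), pos = p, families = fams[j],
                        class = "family_specific")
    }
  }

  reads <- list(); rid <- 0L
  excised <- character(0)
  for (lc in loci) {
    for (fam in lc$families) {
      inds <- paste0(fam, c("_a", "_b"))
      carriers <- if (lc$class == "common") inds else {
        sample(list(inds, inds[1], inds[2]), 1)[[1]]
      }
      for (ind in carriers) {
        for (side in c("left", "right")) {
          n_r <- 2L + stats::rpois(1, 6)
          anchor <- round(stats::runif(n_r, 30, 70))
          if (side == "left") {
            s <- lc$pos + t - anchor; e <- rep(lc$pos + t, n_r)
          } else {
            s <- rep(lc$pos, n_r); e <- lc$pos + anchor
          }
          rid <- rid + n_r
          reads[[length(reads) + 1L]] <- data.frame(
            chrom = chrom, start = as.integer(s), end = as.integer(e),
            read_id = paste0("r", rid - n_r + seq_len(n_r)),
            mapq = sample(20:60, n_r, replace = TRUE), strand = "+",
            side = side, family = fam, individual = ind, te = "TE_active")
        }
      }
    }
  }
  ## one somatic-excision locus: TE-absent spanning reads in one carrier
  fs <- Filter(function(l) l$class == "family_specific", loci)
  if (length(fs)) {
    lc <- fs[[1]]
    ind <- paste0(lc$families[1], "_b")
    n_r <- 4L
    rid <- rid + n_r
    reads[[length(reads) + 1L]] <- data.frame(
      chrom = chrom, start = as.integer(lc$pos - 40L),
      end = as.integer(lc$pos + t + 40L),
      read_id = paste0("r", rid - n_r + seq_len(n_r)),
      mapq = sample(20:60, n_r, replace = TRUE), strand = "+",
      side = "absent", family = lc$families[1], individual = ind,
      te = "TE_active")
    excised <- lc$id
  }
  read_tbl <- do.call(rbind, reads)
  ## 5% noise: random single-side reads, some below the mapq floor
  n_noise <- ceiling(0.05 * nrow(read_tbl))
  noise_pos <- sample.int(config$genome_length - 100L, n_noise)
  rid <- rid + n_noise
  noise <- data.frame(
    chrom = chrom, start = as.integer(noise_pos),
    end = as.integer(noise_pos + round(stats::runif(n_noise, 30, 70))),
    read_id = paste0("n", seq_len(n_noise)),
    mapq = sample(c(0:9, 20:60), n_noise, replace = TRUE), strand = "+",
    side = sample(c("left", "right"), n_noise, replace = TRUE),
    family = sample(fams, n_noise, replace = TRUE),
    individual = "noise", te = "TE_active")
  read_tbl <- rbind(read_tbl, noise)
  rownames(read_tbl) <- NULL

  truth_ins <- data.frame(
    id = vapply(loci, `[[`, character(1), "id"),
    chrom = chrom,
    pos = vapply(loci, `[[`, numeric(1), "pos"),
    tsd_len = t,
    families = vapply(loci, function(l) paste(l$families, collapse = ","),
                      character(1)),
    class = vapply(loci, `[[`, character(1), "class"))
  realized_ibd <- vapply(states, mean, numeric(1))
  list(
    snps = snp_tbl, reads = read_tbl, reference = reference,
    window_bp = win_bp, n_windows = n_win,
    ibd_states = states,
    truth = list(
      insertions = truth_ins,
      excised_locus = excised,
      ibd_fraction_config = config$ibd_fraction,
      ibd_fraction_realized = realized_ibd,
      n_individuals = 2L * config$n_families,
      effective_genomes = 2 * config$n_families * config$ibd_fraction))
}
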