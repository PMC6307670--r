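## Forward simulator of a DNA-transposon life cycle across a host clade:
## nuclear genes diverge neutrally along a dated species tree, a mariner-like
## element enters recipient lineages by horizontal transfer from an unsampled
## donor lineage, and proliferates within each recipient under a
## master-element birth process.  Every input the analysis pipeline consumes
## can be regenerated from (config, seed), together with a ground-truth
## record for parameter-recovery tests.

#' Build a simulation configuration
#'
#' Defaults describe the study system: five insect species (two ants, a bee
#' and two *Drosophila*) with TimeTree divergence times, per-lineage neutral
#' rates calibrated from single-copy orthologs, and a mariner-like element
#' (1,324 bp, 1,059 bp transposase ORF, terminal inverted repeats, TA target
#' duplication) entering each lineage at its estimated invasion date.
#'
#' @param seed master seed; all child seeds derive from it deterministically.
#' @param species_tree ultrametric Newick string, branch lengths in My.
#' @param rates named per-species neutral substitution rates
#'   (substitutions/site/year).
#' @param n_nuclear_genes,gene_length_codons nuclear ortholog panel size.
#' @param htt_events data.frame with columns `recipient`, `time_my`
#'   (entry time, Mya) and `lambda` (transposition events per copy per My).
#' @param burst_schedule list of `c(start_mya, end_mya)` active windows
#'   (start > end); empty list means always active.
#' @param burst_on_arrival_my if set, overrides `burst_schedule` with one
#'   active window per recipient covering the first this-many My after its
#'   own entry (the classic invasion burst); proliferation stops afterwards.
#' @param te_length,tir_length,orf_length element anatomy in nt
#'   (`orf_length` divisible by 3).
#' @param tsd_len target-site duplication length (2-10 nt).
#' @param n_families number of brother pairs for the polymorphism survey.
#' @param insertions_per_family mean family-specific insertions planted per
#'   family (Poisson around this mean, minimum 2).
#' @param ibd_fraction expected fraction of a brother pair's genome that is
#'   identical by descent.
#' @param snp_rate_nonibd,snp_rate_ibd SNPs per 10 kb window.
#' @param genome_length nt per pseudochromosome.
#' @param n_reference_genes size of the single-copy reference expression set.
#' @param tpm_lognormal_params `c(meanlog, sdlog)` for reference-gene TPM.
#' @param vertical_te if `TRUE` the element is inherited vertically from the
#'   clade ancestor (null model for the horizontal-transfer tests) instead
#'   of entering by transfer.
#' @param n_te_ancestral copies per species in the vertical null model.
#' @param donor_rate substitution rate of the unsampled donor lineage
#'   carrying the element between transfer events; defaults to the mean of
#'   `rates`.
#' @param fragment_prob,fragment_range probability that an emitted genomic
#'   copy is truncated, and the surviving length fraction range.
#' @param max_copies hard cap on copies per recipient.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    species_tree = "(((Sinv:91,Aech:91):71,Mrot:162):163,(Dgri:50,Dfic:50):275);",
    rates = c(Sinv = 3.53e-9, Aech = 3.53e-9, Mrot = 1.02e-8,
              Dgri = 5.17e-9, Dfic = 5.17e-9),
    n_nuclear_genes = 200L,
    gene_length_codons = 300L,
    htt_events = data.frame(
      recipient = c("Sinv", "Aech", "Mrot", "Dgri", "Dfic"),
      time_my = c(2.45, 5.07, 0.62, 0.23, 0.53),
      lambda = c(2.76, 0.80, 1.12, 19.2, 8.0)),
    burst_schedule = list(),
    burst_on_arrival_my = NULL,
    te_length = 1324L,
    tir_length = 28L,
    orf_length = 1059L,
    tsd_len = 2L,
    n_families = 7L,
    insertions_per_family = 4,
    ibd_fraction = 0.62,
    snp_rate_nonibd = 30,
    snp_rate_ibd = 0.3,
    genome_length = 2e6,
    n_reference_genes = 500L,
    tpm_lognormal_params = c(meanlog = 3.97, sdlog = 0.72),
    vertical_te = FALSE,
    n_te_ancestral = 20L,
    donor_rate = NULL,
    fragment_prob = 0.15,
    fragment_range = c(0.2, 0.6),
    max_copies = 1500L) {
  if (missing(htt_events) && !missing(species_tree)) {
    ## default transfer events only apply to the species they name
    tips <- ape::read.tree(text = species_tree)$tip.label
    htt_events <- htt_events[htt_events$recipient %in% tips, , drop = FALSE]
  }
  cfg <- list(
    seed = as.integer(seed), species_tree = species_tree, rates = rates,
    n_nuclear_genes = as.integer(n_nuclear_genes),
    gene_length_codons = as.integer(gene_length_codons),
    htt_events = htt_events, burst_schedule = burst_schedule,
    burst_on_arrival_my = burst_on_arrival_my,
    te_length = as.integer(te_length), tir_length = as.integer(tir_length),
    orf_length = as.integer(orf_length), tsd_len = as.integer(tsd_len),
    n_families = as.integer(n_families),
    insertions_per_family = insertions_per_family,
    ibd_fraction = ibd_fraction,
    snp_rate_nonibd = snp_rate_nonibd, snp_rate_ibd = snp_rate_ibd,
    genome_length = genome_length,
    n_reference_genes = as.integer(n_reference_genes),
    tpm_lognormal_params = tpm_lognormal_params,
    vertical_te = isTRUE(vertical_te),
    n_te_ancestral = as.integer(n_te_ancestral),
    donor_rate = if (is.null(donor_rate)) mean(rates) else donor_rate,
    fragment_prob = fragment_prob, fragment_range = fragment_range,
    max_copies = as.integer(max_copies))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  tree <- ape::read.tree(text = cfg$species_tree)
  if (is.null(tree)) stop("configuration error: unparsable species tree")
  sp <- tree$tip.label
  if (!all(sp %in% names(cfg$rates))) {
    stop("configuration error: every species needs a rate")
  }
  if (any(cfg$rates < 0) || cfg$donor_rate < 0) {
    stop("configuration error: rates must be >= 0")
  }
  if (cfg$ibd_fraction < 0 || cfg$ibd_fraction > 1) {
    stop("configuration error: ibd_fraction must lie in [0,1]")
  }
  if (cfg$orf_length %% 3 != 0) {
    stop("configuration error: orf_length must be divisible by 3")
  }
  if (cfg$te_length < 2 * cfg$tir_length + cfg$orf_length + 3) {
    stop("configuration error: te_length too short for TIRs + ORF")
  }
  if (cfg$tsd_len < 0 || cfg$tsd_len > 10) {
    stop("configuration error: tsd_len must lie in [0,10]")
  }
  ev <- cfg$htt_events
  if (nrow(ev)) {
    if (any(ev$time_my < 0) || any(ev$lambda < 0)) {
      stop("configuration error: HTT times and lambdas must be >= 0")
    }
    if (!all(ev$recipient %in% sp)) {
      stop("configuration error: unknown HTT recipient")
    }
    term_len <- terminal_branch_my(tree)
    bad <- ev$time_my > term_len[ev$recipient] & !cfg$vertical_te
    if (any(bad)) {
      stop("configuration error: HTT time older than recipient lineage root (",
           paste(ev$recipient[bad], collapse = ", "), ")")
    }
  }
  invisible(cfg)
}

#' Terminal branch length (My) per tip
#' @noRd
terminal_branch_my <- function(tree) {
  idx <- match(seq_along(tree$tip.label), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}

#' Deterministic child seed for one simulator component
#' @noRd
child_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Per-edge substitution rate: tip rate for terminal edges, mean of
#' descendant tip rates for internal edges
#' @noRd
edge_rates <- function(tree, rates) {
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  vapply(tree$edge[, 2], function(n) mean(rates[desc_tips(n)]), numeric(1))
}

#' Evolve a set of coding genes along the species tree
#'
#' @return list per tip label: character vector of gene sequences.
#' @noRd
evolve_genes_along_tree <- function(tree, rates, n_genes, n_codons) {
  tb <- codon_tables()
  root_idx <- sample(tb$sense, n_genes * n_codons, replace = TRUE)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  er <- edge_rates(tree, rates)
  node_seq <- vector("list", max(tree$edge))
  node_seq[[root]] <- root_idx
  ## preorder: parents always precede children in ape's cladewise edge order
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    chi <- tree$edge[e, 2]
    yrs <- tree$edge.length[e] * 1e6
    node_seq[[chi]] <- evolve_coding(node_seq[[par]], er[e], yrs)
  }
  out <- vector("list", ntip)
  names(out) <- tree$tip.label
  for (i in seq_len(ntip)) {
    idx <- node_seq[[i]]
    m <- matrix(tb$codons[idx], nrow = n_codons)
    out[[i]] <- apply(m, 2, paste, collapse = "")
  }
  out
}

#' Construct the ancestral (source) element sequence
#' @noRd
make_source_te <- function(te_length, tir_length, orf_length) {
  tb <- codon_tables()
  tir <- random_dna(tir_length)
  non_orf <- te_length - orf_length - 3L - 2L * tir_length
  if (non_orf < 2) stop("configuration error: te_length too short")
  sp1 <- non_orf %/% 2
  sp2 <- non_orf - sp1
  internal <- sample(setdiff(tb$sense, which(tb$codons == "ATG")),
                     orf_length / 3 - 1, replace = TRUE)
  orf <- paste0("ATG", paste(tb$codons[internal], collapse = ""))
  seq <- paste0(tir, random_dna(sp1), orf, "TAA", random_dna(sp2),
                revcomp(tir))
  orf_start <- tir_length + sp1 + 1L
  list(seq = seq, orf_start = orf_start,
       orf_end = orf_start + orf_length - 1L, tir_length = tir_length)
}

#' Birth times (Mya) of a master-element proliferation process
#'
#' Linear birth process at rate `lambda` per extant copy per My, restricted
#' to the active windows of `schedule` (list of c(start, end) in Mya).
#' The founding insertion at `t_h` is always included.
#' @noRd
proliferate <- function(t_h, lambda, schedule, max_copies) {
  if (length(schedule) == 0) schedule <- list(c(t_h, 0))
  ## clip windows to (0, t_h), order old -> young
  win <- lapply(schedule, function(w) c(min(w[1], t_h), max(w[2], 0)))
  win <- Filter(function(w) w[1] > w[2], win)
  win <- win[order(-vapply(win, `[`, numeric(1), 1))]
  births <- t_h
  n <- 1L
  for (w in win) {
    t <- min(w[1], t_h)
    while (n < max_copies) {
      dt <- stats::rexp(1, n * lambda)
      t <- t - dt
      if (t <= w[2]) break
      births <- c(births, t)
      n <- n + 1L
    }
    if (n >= max_copies) break
  }
  births
}

#' Truncate a copy to a random contiguous fragment
#' @noRd
maybe_fragment <- function(seq, prob, range) {
  if (stats::runif(1) >= prob) {
    return(list(seq = seq, frag = FALSE, offset = 0L))
  }
  L <- nchar(seq)
  keep <- max(50L, round(L * stats::runif(1, range[1], range[2])))
  start <- sample.int(L - keep + 1L, 1)
  list(seq = substr(seq, start, start + keep - 1L), frag = TRUE,
       offset = start - 1L)
}

#' Simulate a full world: genes, element copies, genomes, expression
#'
#' Realizes the scenario the pipeline is designed to detect: nuclear genes
#' diverge along the species tree at per-lineage neutral rates; the element
#' exists only in lineages that experienced a transfer event; each genomic
#' copy diverges from the source sequence for exactly its age.  With
#' `vertical_te = TRUE` the element instead descends from the clade
#' ancestor, giving the null expectation of gene-like interspecies
#' divergence.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_world`: fields `config`, `tree`,
#'   `species`, `genes`, `source_te`, `te` (per species: `copies`, `ages`,
#'   `fragmented`, `coords`), `genomes`, `hits`, `expression`, `truth`.
#' @export
simulate_world <- function(config) {
  validate_config(config)
  tree <- ape::read.tree(text = config$species_tree)
  tree$tip.label <- as.character(tree$tip.label)
  species <- sort(tree$tip.label)

  set.seed(child_seed(config$seed, "genes"))
  genes <- evolve_genes_along_tree(tree, config$rates,
                                   config$n_nuclear_genes,
                                   config$gene_length_codons)

  set.seed(child_seed(config$seed, "source"))
  src <- make_source_te(config$te_length, config$tir_length,
                        config$orf_length)

  te <- stats::setNames(vector("list", length(species)), species)
  truth_events <- list()
  if (config$vertical_te) {
    set.seed(child_seed(config$seed, "te_vertical"))
    ## each ancestral copy evolves along the species tree like a gene
    per_copy <- lapply(seq_len(config$n_te_ancestral), function(i) {
      evolve_te_along_tree(tree, config$rates, src)
    })
    for (sp in species) {
      cps <- vapply(per_copy, function(x) x[[sp]], character(1))
      te[[sp]] <- list(copies = cps,
                       ages = rep(NA_real_, length(cps)),
                       fragmented = rep(FALSE, length(cps)))
    }
    truth_events <- list(mode = "vertical",
                         n_ancestral = config$n_te_ancestral)
  } else if (nrow(config$htt_events)) {
    ev <- config$htt_events[order(-config$htt_events$time_my), , drop = FALSE]
    set.seed(child_seed(config$seed, "donor"))
    donor_seq <- src$seq
    t_prev <- ev$time_my[1]
    entry_seqs <- character(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      donor_seq <- evolve_te_seq(donor_seq, src$orf_start, src$orf_end,
                                 config$donor_rate,
                                 (t_prev - ev$time_my[i]) * 1e6)
      t_prev <- ev$time_my[i]
      entry_seqs[i] <- donor_seq
    }
    for (i in seq_len(nrow(ev))) {
      sp <- ev$recipient[i]
      set.seed(child_seed(config$seed, paste0("te_", sp)))
      schedule <- if (!is.null(config$burst_on_arrival_my)) {
        list(c(ev$time_my[i],
               max(0, ev$time_my[i] - config$burst_on_arrival_my)))
      } else {
        config$burst_schedule
      }
      births <- proliferate(ev$time_my[i], ev$lambda[i],
                            schedule, config$max_copies)
      r <- config$rates[[sp]]
      copies <- character(length(births))
      frag <- logical(length(births))
      for (j in seq_along(births)) {
        full <- evolve_te_seq(entry_seqs[i], src$orf_start, src$orf_end,
                              r, births[j] * 1e6)
        fr <- maybe_fragment(full, config$fragment_prob,
                             config$fragment_range)
        copies[j] <- fr$seq
        frag[j] <- fr$frag
      }
      te[[sp]] <- list(copies = copies, ages = births, fragmented = frag,
                       entry_seq = entry_seqs[i])
      truth_events[[sp]] <- list(t_h = ev$time_my[i], lambda = ev$lambda[i],
                                 n_copies = length(births))
    }
  }

  set.seed(child_seed(config$seed, "genomes"))
  genomes <- stats::setNames(vector("list", length(species)), species)
  hits <- stats::setNames(vector("list", length(species)), species)
  for (sp in species) {
    pl <- place_copies(config$genome_length,
                       if (is.null(te[[sp]])) character(0) else te[[sp]]$copies,
                       chrom = paste0(sp, "_chr1"))
    genomes[[sp]] <- pl$genome
    hits[[sp]] <- hits_from_placement(pl$coords, te[[sp]], src, sp)
    if (!is.null(te[[sp]])) te[[sp]]$coords <- pl$coords
  }

  set.seed(child_seed(config$seed, "expression"))
  expression <- simulate_expression(config)

  world <- list(
    config = config, tree = tree, species = species, genes = genes,
    source_te = src, te = te, genomes = genomes, hits = hits,
    expression = expression,
    truth = list(mode = if (config$vertical_te) "vertical" else "htt",
                 events = truth_events, rates = config$rates,
                 donor_rate = config$donor_rate,
                 copy_ages = lapply(te, function(x) x$ages)))
  class(world) <- "simulated_world"
  world
}

#' Evolve one whole element along the species tree (vertical null)
#' @noRd
evolve_te_along_tree <- function(tree, rates, src) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  er <- edge_rates(tree, rates)
  node_seq <- vector("list", max(tree$edge))
  node_seq[[root]] <- src$seq
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    chi <- tree$edge[e, 2]
    node_seq[[chi]] <- evolve_te_seq(node_seq[[par]], src$orf_start,
                                     src$orf_end, er[e],
                                     tree$edge.length[e] * 1e6)
  }
  stats::setNames(node_seq[seq_len(ntip)], tree$tip.label)
}

#' Place copies at random non-overlapping positions on one pseudochromosome
#' @noRd
place_copies <- function(genome_length, copies, chrom) {
  n <- length(copies)
  lens <- if (n) nchar(copies) else integer(0)
  bg_len <- genome_length - sum(lens)
  if (bg_len < 0.1 * genome_length) {
    stop("configuration error: genome_length too small for the copy load")
  }
  if (n == 0) {
    return(list(genome = random_dna(genome_length),
                coords = data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), strand = character(0),
                                    copy = integer(0))))
  }
  gaps <- sort(sample.int(bg_len - 1L, n))
  gaps <- c(gaps[1], diff(gaps), bg_len - gaps[n])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  pieces <- character(2 * n + 1)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2 * i - 1] <- random_dna(gaps[i])
    pos <- pos + gaps[i]
    starts[i] <- pos                       # 0-based start of the copy
    pieces[2 * i] <- if (strand[i] == "+") copies[i] else revcomp(copies[i])
    pos <- pos + lens[i]
  }
  pieces[2 * n + 1] <- random_dna(gaps[n + 1])
  list(genome = paste(pieces, collapse = ""),
       coords = data.frame(chrom = chrom, start = starts,
                           end = starts + lens, strand = strand,
                           copy = seq_len(n)))
}

#' BLAST-outfmt6-like hit table derived from the placement truth
#' @noRd
hits_from_placement <- function(coords, te_sp, src, species) {
  if (is.null(te_sp) || nrow(coords) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      identity = numeric(0), aln_len = integer(0),
                      coverage = numeric(0)))
  }
  L <- nchar(src$seq)
  ident <- vapply(seq_len(nrow(coords)), function(i) {
    cp <- te_sp$copies[coords$copy[i]]
    if (nchar(cp) == L) 1 - p_distance(cp, src$seq) else {
      ## fragment: align by recorded offset is unavailable here; report
      ## identity against the matching source window length-wise
      1 - p_distance(cp, substr(src$seq, 1, nchar(cp)))
    }
  }, numeric(1))
  aln <- nchar(te_sp$copies[coords$copy])
  data.frame(query = "TE_consensus", subject = coords$chrom,
             qstart = 1L, qend = aln,
             sstart = coords$start, send = coords$end,
             identity = ident, aln_len = aln, coverage = aln / L)
}

#' Reference-gene and TE transcript expression tables
#'
#' Reference TPM values are log-normal; the focal active element sits above
#' the reference 90th percentile in every sample, decoy elements are high in
#' at most one sample, fossils are low everywhere.
#' @noRd
simulate_expression <- function(config) {
  samples <- c("MO", "PO", "MT")
  ml <- config$tpm_lognormal_params[[1]]
  sl <- config$tpm_lognormal_params[[2]]
  ref <- lapply(samples, function(s) {
    stats::rlnorm(config$n_reference_genes, ml, sl)
  })
  names(ref) <- samples
  te_names <- c("TE_active", paste0("TE_decoy", 1:2), paste0("TE_fossil", 1:3))
  te_tbl <- lapply(samples, function(s) {
    q90 <- stats::quantile(ref[[s]], 0.90)
    q20 <- stats::quantile(ref[[s]], 0.20)
    tpm <- c(q90 * stats::runif(1, 1.5, 3),
             ifelse(s == "MO", q90 * 1.5, q20 * stats::runif(1, 0.5, 1)),
             ifelse(s == "MT", q90 * 1.5, q20 * stats::runif(1, 0.5, 1)),
             q20 * stats::runif(3, 0.1, 0.8))
    data.frame(
      transcript_id = paste0(te_names, "_", s),
      masked_bp = round(stats::runif(6, 400, 1300)),
      divergence = stats::runif(6, 0.005, 0.15),
      te_name = te_names,
      te_class = "DNA",
      superfamily = "IS630-Tc1-mariner",
      transcript_length = round(stats::runif(6, 1300, 2000)),
      tpm = tpm)
  })
  names(te_tbl) <- samples
  list(samples = samples, reference = ref, te = te_tbl)
}
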