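#' Generate a random genome with fixed GC content
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`,
#' mirroring the GC-matched random-sequence model used for the motif null.
#' All generators in this module are pure functions of their seed.
#'
#' @param length Genome length in bases.
#' @param gc GC fraction (default 0.69, the organism's genome composition).
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @return A one-row tibble with columns `id`, `seq`, `length` (the same
#'   shape [read_fasta()] returns).
#' @export
generate_genome <- function(length, gc = 0.69, seed = 1, id = "synthetic_chr") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  bg <- background_from_gc(gc)
  seq <- withr::with_seed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = bg), collapse = "")
  })
  tibble(id = id, seq = seq, length = as.integer(length))
}

#' Plant motif instances into a genome
#'
#' Writes `n_sites` motif instances, sampled independently from the motif's
#' column distributions, into non-overlapping genome positions on random
#' strands. A minus-strand site is inserted as the reverse complement of its
#' sampled instance, so orienting the genome slice by the recorded strand
#' recovers `instance_seq`.
#'
#' @param genome One-row genome tibble.
#' @param motif An `nap_motif`.
#' @param n_sites Number of sites to plant.
#' @param min_spacing Minimum gap in bases between planted sites.
#' @param seed Integer seed.
#' @param site_strength Relative enrichment multiplier (>= 1) recorded per
#'   site; scalar recycled or vector of length `n_sites`.
#' @return A list with `genome` (modified one-row tibble) and `sites`
#'   (tibble `position` (0-based start), `strand`, `instance_seq`,
#'   `site_strength`, sorted by position).
#' @export
plant_sites <- function(genome, motif, n_sites, min_spacing = 100, seed = 1,
                        site_strength = 1) {
  rec <- as_genome_record(genome)
  w <- motif$width
  L <- nchar(rec$seq)
  if (n_sites == 0) {
    return(list(genome = genome, sites = tibble(
      position = integer(), strand = character(),
      instance_seq = character(), site_strength = numeric()
    )))
  }
  if (n_sites * (w + min_spacing) > L) {
    abort("cannot pack sites: n_sites * (width + min_spacing) exceeds genome length")
  }
  site_strength <- rep_len(site_strength, n_sites)
  if (any(site_strength < 1)) abort("site_strength must be >= 1")

  res <- withr::with_seed(seed, {
    positions <- integer(0)
    tries <- 0L
    while (length(positions) < n_sites) {
      tries <- tries + 1L
      if (tries > 1000L * n_sites) {
        abort("cannot place non-overlapping sites; reduce n_sites or min_spacing")
      }
      cand <- sample.int(L - w + 1L, 1L) - 1L
      if (all(abs(cand - positions) >= w + min_spacing)) {
        positions <- c(positions, cand)
      }
    }
    positions <- sort(positions)
    strands <- sample(c("+", "-"), n_sites, replace = TRUE)
    instances <- vapply(seq_len(n_sites), function(i) {
      paste(vapply(seq_len(w), function(j) {
        sample(DNA_BASES, 1L, prob = motif$probs[j, ])
      }, character(1)), collapse = "")
    }, character(1))
    list(positions = positions, strands = strands, instances = instances)
  })

  seq <- rec$seq
  for (i in seq_len(n_sites)) {
    ins <- if (res$strands[i] == "+") res$instances[i] else
      reverse_complement(res$instances[i])
    substr(seq, res$positions[i] + 1L, res$positions[i] + w) <- ins
  }
  genome$seq <- seq
  list(
    genome = genome,
    sites = tibble(
      position = res$positions, strand = res$strands,
      instance_seq = res$instances, site_strength = site_strength
    )
  )
}

#' Simulate paired IP and input ChIP coverage
#'
#' Per-position coverage expectation model: input coverage is Poisson around
#' `mean_depth`; IP coverage is Poisson around `mean_depth` times a site
#' enrichment profile. Around each planted site the profile rises linearly
#' from 1 at the edges of a window of one mean fragment length to
#' `enrichment_at_sites * site_strength` at the site center (a triangular
#' taper mimicking fragment pileup around a point source). Calling twice
#' with different seeds yields independent replicates.
#'
#' @param genome One-row genome tibble (only its length is used).
#' @param sites Sites tibble from [plant_sites()] (may be empty).
#' @param mean_depth Mean background read depth per position.
#' @param fragment_len_range Sonication fragment length range in bases
#'   (default 200-400); the taper half-width is half the mean.
#' @param read_len Read length in bases; recorded as metadata only (the
#'   model works at per-position fragment-pileup resolution).
#' @param enrichment_at_sites Fold enrichment at site centers (>= 1).
#' @param seed Integer seed.
#' @param motif_width Width of the planted sites in bases (used to center
#'   the taper); default 18.
#' @return List with elements `ip` and `input`, each a [coverage_track()].
#' @export
simulate_chip_coverage <- function(genome, sites, mean_depth = 30,
                                   fragment_len_range = c(200, 400),
                                   read_len = 150, enrichment_at_sites = 8,
                                   seed = 1, motif_width = 18) {
  rec <- as_genome_record(genome)
  L <- nchar(rec$seq)
  stopifnot(mean_depth > 0, enrichment_at_sites >= 1,
            fragment_len_range[1] <= fragment_len_range[2])
  half_win <- round(mean(fragment_len_range) / 2)

  mult <- rep(1, L)
  if (nrow(sites) > 0) {
    if (any(sites$position + motif_width > L)) abort("site outside genome")
    for (i in seq_len(nrow(sites))) {
      center <- sites$position[i] + round(motif_width / 2)
      peak <- enrichment_at_sites * sites$site_strength[i]
      lo <- max(0L, center - half_win)
      hi <- min(L - 1L, center + half_win)
      d <- abs(seq(lo, hi) - center)
      prof <- 1 + (peak - 1) * (1 - d / half_win)
      idx <- (lo:hi) + 1L
      mult[idx] <- pmax(mult[idx], prof)
    }
  }

  vals <- withr::with_seed(seed, {
    list(
      input = rpois(L, mean_depth),
      ip = rpois(L, mean_depth * mult)
    )
  })
  list(
    ip = coverage_track(vals$ip, seq_id = rec$id, read_len = read_len),
    input = coverage_track(vals$input, seq_id = rec$id, read_len = read_len)
  )
}

#' Simulate a gene annotation with a target intergenic fraction
#'
#' Tiles the genome with alternating genes and intergenic gaps. Gene and gap
#' lengths are drawn from gamma distributions (shape 4) around
#' `mean_gene_len` and the gap mean implied by `intergenic_fraction`; gap
#' lengths are then rescaled so the realized intergenic fraction matches the
#' request to within rounding (well inside the 2% absolute contract).
#'
#' @param genome One-row genome tibble, or a genome length in bases.
#' @param intergenic_fraction Target fraction of un-annotated sequence,
#'   strictly between 0 and 1 (default 0.10, mirroring a genome that is
#'   less than 10% intergenic).
#' @param mean_gene_len Mean gene length in bases.
#' @param seed Integer seed.
#' @return Annotation tibble in the [read_gff()] schema (0-based half-open,
#'   `feature_type = "gene"`).
#' @export
simulate_annotation <- function(genome, intergenic_fraction = 0.10,
                                mean_gene_len = 1000, seed = 1) {
  L <- if (is.numeric(genome)) as.integer(genome) else
    nchar(as_genome_record(genome)$seq)
  stopifnot(intergenic_fraction > 0, intergenic_fraction < 1)
  if (mean_gene_len >= L) abort("mean_gene_len must be smaller than the genome")
  seq_id <- if (is.numeric(genome)) "synthetic_chr" else
    as_genome_record(genome)$id

  mean_gap <- mean_gene_len * intergenic_fraction / (1 - intergenic_fraction)
  n_est <- ceiling(L / (mean_gene_len + mean_gap)) + 10L

  out <- withr::with_seed(seed, {
    gene_len <- pmax(30, round(stats::rgamma(n_est, shape = 4,
                                             scale = mean_gene_len / 4)))
    gap_len <- pmax(1, round(stats::rgamma(n_est, shape = 4,
                                           scale = mean_gap / 4)))
    strands <- sample(c("+", "-"), n_est, replace = TRUE)
    list(gene_len = gene_len, gap_len = gap_len, strands = strands)
  })

  # walk the tiling once to find how many gene/gap pairs fit
  used <- cumsum(out$gene_len + out$gap_len)
  k <- which(used >= L)[1]
  if (is.na(k)) k <- n_est
  gene_len <- out$gene_len[1:k]
  gap_len <- out$gap_len[1:k]
  # rescale gaps so total gap length hits the target fraction of L
  target_gap <- intergenic_fraction * L
  gap_len <- round(gap_len * target_gap / sum(gap_len))
  gene_len <- round(gene_len * (L - sum(gap_len)) / sum(gene_len))

  starts <- integer(k)
  ends <- integer(k)
  pos <- 0L
  rows <- 0L
  for (i in seq_len(k)) {
    g_start <- pos + gap_len[i] %/% 2L   # split each gap around the gene
    g_end <- g_start + gene_len[i]
    pos <- pos + gap_len[i] + gene_len[i]
    if (g_end > L) { g_end <- L }
    if (g_start >= L || g_end <= g_start) break
    rows <- rows + 1L
    starts[rows] <- g_start
    ends[rows] <- g_end
  }
  idx <- seq_len(rows)
  tibble(
    seq_id = seq_id,
    source = "napscan_sim",
    feature_type = "gene",
    start = starts[idx],
    end = ends[idx],
    strand = out$strands[idx],
    attributes = lapply(idx, function(i) c(ID = sprintf("gene%05d", i)))
  )
}

#' Extract the genome slice for a planted site, oriented by strand
#'
#' @param genome One-row genome tibble or string.
#' @param position 0-based start.
#' @param width Site width in bases.
#' @param strand `"+"` or `"-"`.
#' @return The site sequence as it reads on its own strand.
#' @export
site_slice <- function(genome, position, width, strand = "+") {
  rec <- as_genome_record(genome)
  s <- substr(rec$seq, position + 1L, position + width)
  if (strand == "-") reverse_complement(s) else s
}
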