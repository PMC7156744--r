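#' Position-probability motif model
#'
#' Constructs a fixed-width motif from a per-position nucleotide probability
#' table. Scoring is log-odds in bits against a 0-order background, the
#' standard PWM formulation for ungapped fixed-width motifs (for such motifs
#' a profile HMM built from the same probability table assigns identical
#' likelihoods, so a PWM scan is the equivalent computation).
#'
#' @param probs Numeric matrix, `width` rows by 4 columns in A,C,G,T order;
#'   each row must sum to 1 (tolerance 1e-9).
#' @param background Length-4 background probability vector over A,C,G,T;
#'   default a GC-parameterized background at 50% GC. See
#'   [background_from_gc()].
#' @param half_site_width,spacer Direct-repeat geometry bookkeeping (bases);
#'   `NA` for motifs not built as direct repeats.
#' @return An object of class `nap_motif`.
#' @seealso [build_direct_repeat_motif()], [scan_sequence()]
#' @export
motif_matrix <- function(probs, background = background_from_gc(0.5),
                         half_site_width = NA_integer_, spacer = NA_integer_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) abort("probs must have 4 columns (A,C,G,T)")
  colnames(probs) <- DNA_BASES
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    abort("each probability row must be non-negative and sum to 1")
  }
  background <- validate_background(background)
  structure(
    list(
      width = nrow(probs), probs = probs, background = background,
      half_site_width = half_site_width, spacer = spacer
    ),
    class = "nap_motif"
  )
}

validate_background <- function(background) {
  if (length(background) != 4 || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    abort("background must be a length-4 probability vector over A,C,G,T")
  }
  setNames(as.numeric(background), DNA_BASES)
}

#' GC-parameterized 0-order background
#'
#' @param gc GC fraction in `[0, 1]`.
#' @return Named probability vector `(A, C, G, T)` with
#'   `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#' @export
background_from_gc <- function(gc) {
  stopifnot(gc >= 0, gc <= 1)
  setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
}

#' Build a direct-repeat motif
#'
#' Two identical half-site probability blocks separated by a spacer whose
#' columns equal the background distribution: total width
#' `2 * half_site_width + spacer` (7 + 4 + 7 = 18 bases at the defaults used
#' throughout the package).
#'
#' @param half_site Probability matrix for one half-site
#'   (`half_site_width` rows by 4 columns, A,C,G,T).
#' @param spacer Spacer length in bases (>= 0).
#' @param background Background probability vector (also used for the spacer
#'   columns).
#' @return An `nap_motif` of width `2 * nrow(half_site) + spacer`.
#' @export
build_direct_repeat_motif <- function(half_site, spacer = 4,
                                      background = background_from_gc(0.69)) {
  half_site <- as.matrix(half_site)
  if (spacer < 0) abort("spacer must be >= 0")
  background <- validate_background(background)
  spacer_block <- if (spacer == 0) {
    matrix(numeric(0), nrow = 0, ncol = 4)
  } else {
    matrix(background, nrow = spacer, ncol = 4, byrow = TRUE)
  }
  probs <- rbind(half_site, spacer_block, half_site)
  motif_matrix(probs, background,
               half_site_width = nrow(half_site), spacer = as.integer(spacer))
}

#' Example direct-repeat motif (synthetic)
#'
#' A synthetic stand-in for the protein's (unpublished) binding-site
#' probability matrix: a GC-rich 7-base half-site repeated with a 4-base
#' spacer, 18 bases total. Each half-site column puts `conservation` on the
#' consensus base and splits the remainder evenly.
#'
#' @param consensus Half-site consensus string (default a GC-rich 7-mer).
#' @param conservation Probability of the consensus base per column.
#' @param spacer Spacer length in bases.
#' @param gc Background GC fraction.
#' @return An `nap_motif`.
#' @export
example_direct_repeat_motif <- function(consensus = "GCCGTCA",
                                        conservation = 0.85,
                                        spacer = 4, gc = 0.69) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% DNA_BASES), conservation > 0, conservation <= 1)
  half <- matrix((1 - conservation) / 3, nrow = length(bases), ncol = 4,
                 dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(bases)) half[i, bases[i]] <- conservation
  build_direct_repeat_motif(half, spacer = spacer,
                            background = background_from_gc(gc))
}

#' Log-odds scoring table
#'
#' Entry `(j, b)` is `log2((p[j, b] + epsilon) / background[b])`; the small
#' additive `epsilon` keeps zero-probability cells finite.
#'
#' @param motif An `nap_motif`.
#' @param epsilon Additive smoothing constant.
#' @return A `width` x 4 matrix of scores in bits.
#' @export
log_odds <- function(motif, epsilon = 0.01) {
  stopifnot(inherits(motif, "nap_motif"))
  if (any(motif$background <= 0)) abort("background must be strictly positive")
  lo <- log2(sweep(motif$probs + epsilon, 2, motif$background, "/"))
  colnames(lo) <- DNA_BASES
  lo
}

#' Score fixed-width sequences against a motif
#'
#' @param seqs Character vector of sequences, each exactly `motif$width`
#'   bases over `{A,C,G,T}`.
#' @param motif An `nap_motif`.
#' @param epsilon Smoothing passed to [log_odds()].
#' @return Numeric vector of log-odds scores in bits.
#' @export
score_sequences <- function(seqs, motif, epsilon = 0.01) {
  stopifnot(all(nchar(seqs) == motif$width))
  lo <- log_odds(motif, epsilon)
  codes <- encode_bases(seqs)
  scores <- numeric(length(seqs))
  for (j in seq_len(motif$width)) {
    scores <- scores + lo[j, ][codes[, j]]
  }
  unname(scores)
}

# Character sequences -> integer code matrix (A=1 C=2 G=3 T=4, N -> NA).
encode_bases <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  codes <- match(m, DNA_BASES)
  dim(codes) <- dim(m)
  codes
}

#' Scan a genome for motif hits on both strands
#'
#' Every window of `motif$width` bases on the forward and reverse strand is
#' scored with the log-odds table; windows overlapping an `N` are excluded
#' (no hit may overlap `N`). Overlapping hits are all reported, and hits on
#' opposite strands of the same locus count separately. Hit coordinates are
#' 0-based starts on the forward strand.
#'
#' @param genome A single sequence: a character string, or a one-row tibble
#'   from [read_fasta()]/[generate_genome()].
#' @param motif An `nap_motif`.
#' @param score_threshold Minimum score in bits for a window to be reported.
#' @param epsilon Smoothing passed to [log_odds()].
#' @param null Optional [sample_null_scores()] result; when supplied, an
#'   empirical `pvalue` column is added via [empirical_pvalue()].
#' @return Tibble with columns `seq_id`, `start`, `strand`, `width`,
#'   `score` (and `pvalue` when `null` is given), sorted by `start`.
#' @export
scan_sequence <- function(genome, motif, score_threshold, epsilon = 0.01,
                          null = NULL) {
  rec <- as_genome_record(genome)
  w <- motif$width
  if (nchar(rec$seq) < w) abort("genome shorter than motif width")
  lo <- log_odds(motif, epsilon)

  fwd <- windowed_scores(rec$seq, lo)
  rev <- windowed_scores(reverse_complement(rec$seq), lo)
  L <- nchar(rec$seq)

  keep_f <- which(!is.na(fwd) & fwd >= score_threshold)
  keep_r <- which(!is.na(rev) & rev >= score_threshold)
  hits <- tibble(
    seq_id = rec$id,
    start = c(keep_f - 1L, L - (keep_r - 1L) - w),
    strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
    width = w,
    score = c(fwd[keep_f], rev[keep_r])
  )
  hits <- arrange(hits, .data$start, .data$strand)
  if (!is.null(null)) {
    hits$pvalue <- empirical_pvalue(hits$score, null)
  }
  hits
}

# Per-window log-odds scores along one strand; NA where a window overlaps N.
windowed_scores <- function(seq, lo) {
  w <- nrow(lo)
  codes <- match(strsplit(seq, "")[[1]], DNA_BASES)
  L <- length(codes)
  n_win <- L - w + 1L
  if (n_win < 1) return(numeric(0))
  scores <- numeric(n_win)
  for (j in seq_len(w)) {
    col <- lo[j, ][codes[j:(j + n_win - 1L)]]
    scores <- scores + col  # NA propagates from N bases
  }
  unname(scores)
}

as_genome_record <- function(genome) {
  if (is.character(genome) && length(genome) == 1) {
    return(list(id = "seq", seq = toupper(genome)))
  }
  if (is.data.frame(genome)) {
    if (nrow(genome) != 1) abort("expected a single genome record")
    return(list(id = genome$id[[1]], seq = toupper(genome$seq[[1]])))
  }
  abort("genome must be a string or a one-row tibble with id/seq columns")
}

#' Monte-Carlo null score distribution
#'
#' Scores of `n` i.i.d. random sequences of the motif's width drawn from the
#' GC-matched background (`P(G) = P(C) = gc/2`), each scored on the forward
#' strand only (random sequences have no orientation). This is the empirical
#' null against which genome-scan scores are calibrated.
#'
#' @param motif An `nap_motif`.
#' @param gc GC fraction of the null sequences.
#' @param n Number of null samples.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param epsilon Smoothing passed to [log_odds()].
#' @return An object of class `nap_null`: list with sorted `scores`,
#'   `n_samples`, `gc` and `seed`.
#' @export
sample_null_scores <- function(motif, gc, n = 1e6, seed = 1, epsilon = 0.01) {
  stopifnot(n >= 1)
  lo <- log_odds(motif, epsilon)
  w <- motif$width
  bg <- background_from_gc(gc)
  scores <- withr::with_seed(seed, {
    out <- numeric(n)
    chunk <- 200000L
    done <- 0L
    while (done < n) {
      k <- min(chunk, n - done)
      codes <- matrix(sample.int(4L, k * w, replace = TRUE, prob = bg),
                      nrow = k, ncol = w)
      s <- numeric(k)
      for (j in seq_len(w)) s <- s + lo[j, ][codes[, j]]
      out[(done + 1L):(done + k)] <- s
      done <- done + k
    }
    out
  })
  structure(
    list(n_samples = as.integer(n), gc = gc, scores = sort(unname(scores)),
         seed = seed),
    class = "nap_null"
  )
}

#' @export
print.nap_null <- function(x, ...) {
  cat("Monte-Carlo motif score null: ", x$n_samples, " samples, GC ",
      x$gc, "\n  score range [", round(min(x$scores), 3), ", ",
      round(max(x$scores), 3), "] bits\n", sep = "")
  invisible(x)
}

#' Empirical p-value of a motif score
#'
#' Add-one empirical tail probability `(k + 1) / (n + 1)`, where `k` is the
#' number of null scores greater than or equal to the observed score; the
#' add-one rule guarantees `p > 0`.
#'
#' @param score Numeric vector of scores in bits.
#' @param null An `nap_null` from [sample_null_scores()].
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalue <- function(score, null) {
  stopifnot(inherits(null, "nap_null"), length(null$scores) > 0)
  n <- null$n_samples
  # findInterval with left.open counts null scores strictly below each score
  n_less <- findInterval(score, null$scores, left.open = TRUE)
  k <- n - n_less
  (k + 1) / (n + 1)
}

#' Score threshold attaining a target empirical p-value
#'
#' Smallest observed null score whose empirical p-value is at most
#' `target_p`. Errors when `target_p < 1 / (n + 1)`, which no score can
#' attain.
#'
#' @param null An `nap_null`.
#' @param target_p Target p-value in `(0, 1]`.
#' @return Score threshold in bits.
#' @export
threshold_for_pvalue <- function(null, target_p) {
  stopifnot(target_p > 0, target_p <= 1)
  n <- null$n_samples
  if (target_p < 1 / (n + 1)) {
    abort(paste0("target p-value ", target_p, " unattainable with ", n,
                 " null samples (minimum ", format(1 / (n + 1)), ")"))
  }
  cand <- unique(null$scores)
  p <- empirical_pvalue(cand, null)
  cand[which(p <= target_p)[1]]
}
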