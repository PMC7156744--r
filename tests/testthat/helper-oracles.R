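# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Enumerate every global alignment of a and b (affine gaps: a run of L gap
# columns costs gap_open + L * gap_extend, end gaps included) and return the
# maximum score. Feasible for nchar <= 4.
brute_align_best <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, cols_a, cols_b) {
    if (i > length(ca) && j > length(cb)) {
      sc <- score_gapped(cols_a, cols_b, mat, gap_open, gap_extend)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, c(cols_a, ca[i]), c(cols_b, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1, j, c(cols_a, ca[i]), c(cols_b, "-"))
    if (j <= length(cb)) rec(i, j + 1, c(cols_a, "-"), c(cols_b, cb[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

score_gapped <- function(cols_a, cols_b, mat, gap_open, gap_extend) {
  stopifnot(length(cols_a) == length(cols_b))
  sc <- 0
  run_a <- 0  # current gap-run length in a
  run_b <- 0
  for (k in seq_along(cols_a)) {
    if (cols_a[k] == "-" && cols_b[k] == "-") return(-Inf)
    if (cols_a[k] == "-") {
      run_a <- run_a + 1
      if (run_b > 0) { sc <- sc - gap_open - gap_extend * run_b; run_b <- 0 }
    } else if (cols_b[k] == "-") {
      run_b <- run_b + 1
      if (run_a > 0) { sc <- sc - gap_open - gap_extend * run_a; run_a <- 0 }
    } else {
      if (run_a > 0) { sc <- sc - gap_open - gap_extend * run_a; run_a <- 0 }
      if (run_b > 0) { sc <- sc - gap_open - gap_extend * run_b; run_b <- 0 }
      sc <- sc + mat[cols_a[k], cols_b[k]]
    }
  }
  if (run_a > 0) sc <- sc - gap_open - gap_extend * run_a
  if (run_b > 0) sc <- sc - gap_open - gap_extend * run_b
  sc
}

# Position-by-position peak finder following the stated rule directly:
# cluster above-threshold positions whose gaps are <= merge_gap, keep
# clusters at least min_width wide. Returns 0-based half-open intervals.
brute_find_peaks <- function(values, threshold, min_width, merge_gap) {
  idx <- which(values >= threshold)
  if (length(idx) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  breaks <- which(diff(idx) - 1 > merge_gap)
  cluster <- cumsum(c(1, seq_along(idx)[-1] %in% (breaks + 1)))
  out <- do.call(rbind, lapply(split(idx, cluster), function(ix) {
    data.frame(start = min(ix) - 1L, end = max(ix))
  }))
  out <- out[(out$end - out$start) >= min_width, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive per-character motif score (log2((p + eps)/bg)).
brute_motif_score <- function(seq, probs, background, epsilon = 0.01) {
  ch <- strsplit(seq, "")[[1]]
  s <- 0
  for (j in seq_along(ch)) {
    s <- s + log2((probs[j, ch[j]] + epsilon) / background[[ch[j]]])
  }
  unname(s)
}

# All DNA strings of width w.
all_kmers <- function(w) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), w))
  apply(g, 1, paste, collapse = "")
}

# O(n*m) summit-window assignment (any-overlap, inclusive bounds).
brute_assign_counts <- function(summits, hit_starts, hit_width, window) {
  vapply(summits, function(s) {
    sum(hit_starts <= s + window & hit_starts + hit_width - 1 >= s - window)
  }, numeric(1))
}

# One-sample Kolmogorov-Smirnov distance to U(0,1).
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(p - seq_len(n) / n), abs(p - (seq_len(n) - 1) / n))
}

# Apply a random rigid rotation + translation to a structure's coordinates.
rigid_transform <- function(model, seed = 1) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- rnorm(3, 0, 50)
  })
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(Q)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
}
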