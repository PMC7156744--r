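#' Per-position coverage track
#'
#' @param values Non-negative per-position read depth.
#' @param seq_id Sequence identifier.
#' @param library_size Total mapped read count used for depth normalization;
#'   defaults to the track sum.
#' @param read_len Optional read length metadata.
#' @return An object of class `nap_track`.
#' @export
coverage_track <- function(values, seq_id = "chr", library_size = sum(values),
                           read_len = NA_integer_) {
  values <- as.numeric(values)
  if (any(values < 0) || anyNA(values)) abort("coverage values must be >= 0")
  if (library_size <= 0) abort("library_size must be positive")
  structure(
    list(seq_id = seq_id, values = values, library_size = library_size,
         read_len = read_len),
    class = "nap_track"
  )
}

#' @export
print.nap_track <- function(x, ...) {
  cat("Coverage track '", x$seq_id, "': ", length(x$values),
      " positions, mean depth ", round(mean(x$values), 2),
      ", library size ", format(x$library_size), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.nap_track <- function(x, ...) {
  tibble(seq_id = x$seq_id, position = seq_along(x$values) - 1L,
         depth = x$values)
}

#' Log2 IP/input enrichment track
#'
#' Per position `i`, `log2((ip_i * s + c) / (input_i + c))`, where
#' `s = input library size / IP library size` normalizes sequencing depth
#' and `c` is a pseudocount keeping the ratio finite. A 4-fold enrichment
#' corresponds to log2 = 2, the peak-calling threshold used downstream.
#'
#' @param ip,input [coverage_track()] objects of equal length.
#' @param pseudocount Pseudocount `c` in depth units (> 0).
#' @return An object of class `nap_enrichment` with per-position
#'   `log2_ratio`.
#' @export
compute_log2_enrichment <- function(ip, input, pseudocount = 1) {
  stopifnot(inherits(ip, "nap_track"), inherits(input, "nap_track"))
  if (length(ip$values) != length(input$values)) {
    abort("IP and input tracks have different lengths")
  }
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  s <- input$library_size / ip$library_size
  structure(
    list(
      seq_id = ip$seq_id,
      log2_ratio = log2((ip$values * s + pseudocount) /
                          (input$values + pseudocount)),
      pseudocount = pseudocount
    ),
    class = "nap_enrichment"
  )
}

#' @export
print.nap_enrichment <- function(x, ...) {
  cat("Log2 enrichment track '", x$seq_id, "': ", length(x$log2_ratio),
      " positions, range [", round(min(x$log2_ratio), 2), ", ",
      round(max(x$log2_ratio), 2), "]\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.nap_enrichment <- function(x, ...) {
  tibble(seq_id = x$seq_id, position = seq_along(x$log2_ratio) - 1L,
         log2_ratio = x$log2_ratio)
}

#' Call peaks at a fold-enrichment threshold
#'
#' Peaks are maximal runs of positions whose log2 enrichment is at least
#' `threshold_log2` (default 2, i.e. 4-fold over input). Runs separated by
#' at most `merge_gap` bases are merged, then merged runs shorter than
#' `min_width` are discarded. The summit is the leftmost position of maximal
#' enrichment within the peak; peaks are ranked by `max_log2` descending
#' with coordinate ties broken by start.
#'
#' @param track An `nap_enrichment`.
#' @param threshold_log2 Log2 enrichment threshold.
#' @param min_width Minimum peak width in bases.
#' @param merge_gap Maximum sub-threshold gap to bridge, in bases.
#' @return Tibble with columns `seq_id`, `start`, `end` (0-based half-open),
#'   `summit`, `max_log2`, `rank`.
#' @export
call_peaks <- function(track, threshold_log2 = 2, min_width = 20,
                       merge_gap = 30) {
  stopifnot(inherits(track, "nap_enrichment"), is.finite(threshold_log2))
  v <- track$log2_ratio
  above <- v >= threshold_log2
  empty <- tibble(
    seq_id = character(), start = integer(), end = integer(),
    summit = integer(), max_log2 = numeric(), rank = integer()
  )
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_s <- starts[r$values]
  run_e <- ends[r$values]

  # merge runs separated by <= merge_gap
  ms <- run_s[1]
  me <- run_e[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(run_s)[-1]) {
    if (run_s[i] - me - 1L <= merge_gap) {
      me <- run_e[i]
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- run_s[i]; me <- run_e[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)

  keep <- (out_e - out_s + 1L) >= min_width
  out_s <- out_s[keep]; out_e <- out_e[keep]
  if (length(out_s) == 0) return(empty)

  summit <- integer(length(out_s))
  max_log2 <- numeric(length(out_s))
  for (i in seq_along(out_s)) {
    seg <- v[out_s[i]:out_e[i]]
    j <- which.max(seg)            # leftmost maximum
    summit[i] <- out_s[i] + j - 2L # 0-based
    max_log2[i] <- seg[j]
  }
  peaks <- tibble(
    seq_id = track$seq_id,
    start = out_s - 1L, end = out_e,
    summit = summit, max_log2 = max_log2
  )
  ord <- order(-peaks$max_log2, peaks$seq_id, peaks$start)
  peaks$rank <- integer(nrow(peaks))
  peaks$rank[ord] <- seq_len(nrow(peaks))
  arrange(peaks, .data$start)
}

#' Replicate agreement as squared Pearson correlation
#'
#' Squared Pearson correlation of per-position log2 enrichment between two
#' replicate tracks.
#'
#' @param track1,track2 `nap_enrichment` objects of equal length.
#' @return R-squared in `[0, 1]`.
#' @export
replicate_r2 <- function(track1, track2) {
  stopifnot(inherits(track1, "nap_enrichment"),
            inherits(track2, "nap_enrichment"))
  x <- track1$log2_ratio
  y <- track2$log2_ratio
  if (length(x) != length(y)) abort("tracks have different lengths")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2) abort("need at least 2 positions with finite values")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    abort("undefined correlation: zero variance in a track")
  }
  cor(x[ok], y[ok])^2
}
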