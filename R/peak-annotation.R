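#' Assign motif hits to peak summits within a window
#'
#' A hit is assigned to a peak when its footprint
#' `[start, start + width)` touches the closed window
#' `[summit - window, summit + window]` (both bounds inclusive). With
#' `anchor = "start"` only the hit start must fall in the window; with
#' `anchor = "center"` the hit center.
#'
#' @param peaks Peaks tibble (from [call_peaks()] or an external table with
#'   at least `summit`; `rank` is carried through when present).
#' @param hits Motif hits tibble (from [scan_sequence()]), needing `start`
#'   and `width`.
#' @param window Half-window in bases around the summit (default 50).
#' @param anchor Which part of the hit must fall inside the window:
#'   `"any"` (any overlap, default), `"start"` or `"center"`.
#' @return `peaks` with added columns `n_motifs` and `motif_hits` (list
#'   column of assigned-hit tibbles).
#' @export
assign_motifs_to_peaks <- function(peaks, hits, window = 50,
                                   anchor = c("any", "start", "center")) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 0)
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    lo <- s - window
    hi <- s + window
    sel <- switch(
      anchor,
      any = hits$start <= hi & (hits$start + hits$width - 1L) >= lo,
      start = hits$start >= lo & hits$start <= hi,
      center = {
        ctr <- hits$start + hits$width %/% 2L
        ctr >= lo & ctr <= hi
      }
    )
    hits[sel, , drop = FALSE]
  })
  peaks$n_motifs <- vapply(res, nrow, integer(1))
  peaks$motif_hits <- res
  peaks
}

#' Classify peaks as genic or intergenic by summit position
#'
#' A peak is intergenic when its summit overlaps no annotated interval
#' (strand-agnostic); genic otherwise. The summit, not the whole peak span,
#' is the reference point, matching its role as the anchor for motif
#' assignment.
#'
#' @param peaks Peaks tibble with a `summit` column (0-based positions).
#' @param genes Annotation tibble with 0-based half-open `start`/`end`.
#' @return `peaks` with an added `location` column (`"genic"` /
#'   `"intergenic"`).
#' @export
classify_peak_location <- function(peaks, genes) {
  if (nrow(genes) > 0 && any(genes$start >= genes$end)) {
    abort("invalid gene interval: start >= end")
  }
  if (nrow(genes) == 0) {
    peaks$location <- rep("intergenic", nrow(peaks))
    return(peaks)
  }
  gr <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
  q <- IRanges::IRanges(peaks$summit + 1L, peaks$summit + 1L)
  genic <- IRanges::overlapsAny(q, gr)
  peaks$location <- ifelse(genic, "genic", "intergenic")
  peaks
}

#' Peak report: motif association and genomic location summary
#'
#' Combines [assign_motifs_to_peaks()] and [classify_peak_location()] into
#' the summary fractions of interest: how many peaks carry at least one
#' motif within the summit window, and how many are intergenic — overall
#' and, optionally, among the top `top_n` peaks by rank.
#'
#' @param peaks Peaks tibble with `summit` (and `rank`; when absent, ranks
#'   are assigned by `max_log2` or input order).
#' @param hits Motif hits tibble.
#' @param genes Annotation tibble.
#' @param window Summit half-window in bases.
#' @param top_n Optional stratification: also summarize the `top_n`
#'   strongest peaks. Values above the peak count are clamped with a
#'   warning.
#' @param anchor Passed to [assign_motifs_to_peaks()].
#' @return An object of class `nap_peak_report`: list with `summary`
#'   (one-row tibble), `top_summary` (one-row tibble or `NULL`), `per_peak`
#'   (per-peak rows ordered by rank) and `window`.
#' @export
summarize_report <- function(peaks, hits, genes, window = 50, top_n = NULL,
                             anchor = "any") {
  if (!"rank" %in% names(peaks)) {
    peaks$rank <- if ("max_log2" %in% names(peaks)) {
      rank(-peaks$max_log2, ties.method = "first")
    } else {
      seq_len(nrow(peaks))
    }
  }
  per_peak <- assign_motifs_to_peaks(peaks, hits, window = window,
                                     anchor = anchor)
  per_peak <- classify_peak_location(per_peak, genes)
  per_peak <- arrange(per_peak, .data$rank)

  if (!is.null(top_n) && top_n > nrow(per_peak)) {
    warn(paste0("top_n (", top_n, ") exceeds number of peaks (",
                nrow(per_peak), "); clamped"))
    top_n <- nrow(per_peak)
  }

  top_summary <- NULL
  if (!is.null(top_n)) {
    top_summary <- report_counts(per_peak[seq_len(top_n), , drop = FALSE],
                                 window)
  }
  structure(
    list(
      summary = report_counts(per_peak, window),
      top_summary = top_summary,
      per_peak = per_peak,
      window = window
    ),
    class = "nap_peak_report"
  )
}

report_counts <- function(per_peak, window) {
  n <- nrow(per_peak)
  n_motif <- sum(per_peak$n_motifs > 0)
  n_inter <- sum(per_peak$location == "intergenic")
  tibble(
    n_peaks = n,
    n_with_motif = n_motif,
    motif_fraction = if (n > 0) 100 * n_motif / n else NA_real_,
    n_intergenic = n_inter,
    intergenic_fraction = if (n > 0) 100 * n_inter / n else NA_real_,
    window = window
  )
}

#' @export
print.nap_peak_report <- function(x, ...) {
  s <- x$summary
  cat("Peak report (summit window +/-", x$window, "bp)\n")
  cat(sprintf("  peaks:       %d\n", s$n_peaks))
  cat(sprintf("  with motif:  %d (%.1f%%)\n", s$n_with_motif,
              s$motif_fraction))
  cat(sprintf("  intergenic:  %d (%.1f%%)\n", s$n_intergenic,
              s$intergenic_fraction))
  if (!is.null(x$top_summary)) {
    t <- x$top_summary
    cat(sprintf("  top %d: %d with motif (%.1f%%), %d intergenic (%.1f%%)\n",
                t$n_peaks, t$n_with_motif, t$motif_fraction,
                t$n_intergenic, t$intergenic_fraction))
  }
  invisible(x)
}

#' @export
tidy.nap_peak_report <- function(x, ...) {
  out <- x$summary
  out$stratum <- "all"
  if (!is.null(x$top_summary)) {
    top <- x$top_summary
    top$stratum <- paste0("top_", top$n_peaks)
    out <- bind_rows(out, top)
  }
  out
}
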