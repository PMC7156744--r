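#' Write a per-position track as bedGraph
#'
#' Consecutive equal values are collapsed into intervals (0-based
#' half-open), the bedGraph convention.
#'
#' @param track A [coverage_track()] or `nap_enrichment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  vals <- if (inherits(track, "nap_enrichment")) track$log2_ratio else
    track$values
  r <- rle(vals)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- paste(track$seq_id, starts, ends,
                 formatC(r$values, format = "g", digits = 8), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path Path to a bedGraph file covering a single sequence.
#' @param genome_length Track length; defaults to the largest interval end.
#' @return A [coverage_track()] (uncovered positions are 0).
#' @export
read_bedgraph <- function(path, genome_length = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("seq_id", "start", "end", "value"))
  if (length(unique(d$seq_id)) != 1) {
    abort("bedGraph spans multiple sequences; expected one")
  }
  L <- if (is.null(genome_length)) max(d$end) else genome_length
  vals <- numeric(L)
  for (i in seq_len(nrow(d))) {
    vals[(d$start[i] + 1):d$end[i]] <- d$value[i]
  }
  coverage_track(vals, seq_id = d$seq_id[1])
}

#' Write peaks as BED6 plus a TSV summary
#'
#' @param peaks Peaks tibble from [call_peaks()].
#' @param bed_path Path for the BED6 file (name = `peak_<rank>`, score =
#'   `max_log2 * 100` capped at 1000).
#' @param tsv_path Optional path for a full TSV (all columns).
#' @return `bed_path`, invisibly.
#' @export
write_peaks <- function(peaks, bed_path, tsv_path = NULL) {
  lines <- paste(
    peaks$seq_id, peaks$start, peaks$end,
    paste0("peak_", peaks$rank),
    pmin(round(peaks$max_log2 * 100), 1000), ".",
    sep = "\t"
  )
  writeLines(lines, bed_path)
  if (!is.null(tsv_path)) {
    utils::write.table(peaks, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}

#' Write motif hits as BED6 plus a TSV
#'
#' @param hits Hits tibble from [scan_sequence()].
#' @param bed_path Path for the BED6 file (score = bits x 100, rounded).
#' @param tsv_path Optional path for a full TSV including p-values.
#' @return `bed_path`, invisibly.
#' @export
write_hits <- function(hits, bed_path, tsv_path = NULL) {
  lines <- paste(
    hits$seq_id, hits$start, hits$start + hits$width,
    paste0("hit_", seq_len(nrow(hits))),
    round(hits$score * 100), hits$strand,
    sep = "\t"
  )
  writeLines(lines, bed_path)
  if (!is.null(tsv_path)) {
    utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}

#' Write planted truth sites as BED6
#'
#' Score column carries `site_strength * 100`.
#'
#' @param sites Sites tibble from [plant_sites()].
#' @param path Output path.
#' @param seq_id Sequence name.
#' @param width Site width in bases.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, seq_id = "synthetic_chr",
                            width = 18) {
  lines <- paste(
    seq_id, sites$position, sites$position + width,
    paste0("site_", seq_len(nrow(sites))),
    round(sites$site_strength * 100), sites$strand,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a motif from MEME minimal format
#'
#' Reads the first motif of a MEME minimal-format file (the
#' `letter-probability matrix` block); the file's background frequencies
#' are used when present, otherwise a uniform background.
#'
#' @param path Path to a MEME minimal motif file.
#' @return An `nap_motif`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- background_from_gc(0.5)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0 && bg_i[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    freq <- as.numeric(tok[c(FALSE, TRUE)])
    names(freq) <- tok[c(TRUE, FALSE)]
    bg <- validate_background(freq[DNA_BASES] / sum(freq[DNA_BASES]))
  }
  m_i <- grep("^letter-probability matrix", lines)
  if (length(m_i) == 0) abort("no letter-probability matrix in MEME file")
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[m_i[1]]))
  rows <- lines[(m_i[1] + 1):(m_i[1] + w)]
  probs <- do.call(rbind, lapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }))
  # renormalize against MEME's 3-decimal rounding
  probs <- probs / rowSums(probs)
  motif_matrix(probs, background = bg)
}

#' Write a motif in MEME minimal format
#'
#' @param motif An `nap_motif`.
#' @param path Output path.
#' @param name Motif name for the MOTIF line.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motif, path, name = "motif1") {
  bg <- motif$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            motif$width),
    apply(motif$probs, 1, function(p) sprintf(" %.6f %.6f %.6f %.6f",
                                              p[1], p[2], p[3], p[4]))
  )
  writeLines(lines, path)
  invisible(path)
}
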