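#' Read a DNA FASTA file
#'
#' Reads a (possibly multi-record) FASTA file into a tibble of genome
#' sequences. Sequences are upper-cased on read and must consist only of
#' `A`, `C`, `G`, `T` and `N`; anything else (e.g. RNA `U`, IUPAC ambiguity
#' codes) is rejected with an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (header up to the first whitespace),
#'   `seq` (upper-case sequence) and `length` (bases), one row per record in
#'   file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "acgtACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("not a readable FASTA file: ", path))
  )
  if (length(set) == 0) {
    abort(paste0("empty FASTA file: ", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(toupper(as.character(set)))
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0(
      "record '", ids[which(bad)[1]],
      "' contains characters outside {A,C,G,T,N}"
    ))
  }
  tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `id` and `seq` (as returned by
#'   [read_fasta()] or [generate_genome()]).
#' @param path Output file path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(seqs$seq)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T). `N` bases are excluded from both
#' numerator and denominator.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_content(c("GGCC", "ATAT", "GCNN"))
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  gc <- stringr::str_count(seq, "[GC]")
  at <- stringr::str_count(seq, "[AT]")
  denom <- gc + at
  if (any(denom == 0)) {
    abort("undefined composition: sequence is empty or all-N")
  }
  gc / denom
}

#' Reverse complement
#'
#' Reversed Watson-Crick complement; `N` maps to `N`.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

check_dna <- function(seq) {
  bad <- stringr::str_detect(seq, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("invalid DNA character in sequence ", which(bad)[1]))
  }
  invisible(seq)
}

#' Read gene annotation from GFF3
#'
#' Parses a GFF3 file and converts coordinates from the file's 1-based
#' inclusive convention to the package-internal 0-based half-open
#' convention. Malformed lines are reported with their line numbers.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Optional character vector; keep only these feature
#'   types (e.g. `"gene"`). Default keeps everything.
#' @return A tibble with columns `seq_id`, `source`, `feature_type`,
#'   `start` (0-based), `end` (half-open), `strand` (`+`, `-` or `.`) and
#'   `attributes` (list column of named character vectors).
#' @export
read_gff <- function(path, feature_types = NULL) {
  if (!file.exists(path)) abort(paste0("GFF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) {
    return(tibble(
      seq_id = character(), source = character(), feature_type = character(),
      start = integer(), end = integer(), strand = character(),
      attributes = list()
    ))
  }
  # Light pre-validation so errors carry line numbers; the actual parse is
  # delegated to rtracklayer below.
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      abort(paste0("GFF line ", i, ": expected >= 8 tab-separated fields"))
    }
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) {
      abort(paste0("GFF line ", i, ": non-numeric coordinates"))
    }
    if (s > e) {
      abort(paste0("GFF line ", i, ": start (", s, ") > end (", e, ")"))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  keep_attr <- setdiff(names(mc), c("source", "type", "score", "phase"))
  attrs <- lapply(seq_along(gr), function(i) {
    vals <- vapply(keep_attr, function(k) {
      v <- mc[[k]][[i]]
      if (length(v) == 0 || all(is.na(v))) NA_character_ else paste(v, collapse = ",")
    }, character(1))
    vals[!is.na(vals)]
  })
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(mc$source),
    feature_type = as.character(mc$type),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    attributes = attrs
  )
  if (!is.null(feature_types)) {
    out <- out[out$feature_type %in% feature_types, , drop = FALSE]
  }
  out
}

#' Write gene annotation to GFF3
#'
#' Inverse of [read_gff()]: internal 0-based half-open intervals are written
#' as 1-based inclusive GFF3 lines.
#'
#' @param genes Tibble as returned by [read_gff()] or [simulate_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  attr_str <- vapply(seq_len(nrow(genes)), function(i) {
    a <- genes$attributes[[i]]
    if (length(a) == 0) "." else paste0(names(a), "=", a, collapse = ";")
  }, character(1))
  lines <- paste(
    genes$seq_id, genes$source, genes$feature_type,
    genes$start + 1L, genes$end, ".", genes$strand, ".", attr_str,
    sep = "\t"
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Fraction of a genome not covered by annotated features
#'
#' @param genes Annotation tibble with `start`/`end` columns (0-based
#'   half-open).
#' @param genome_length Genome length in bases.
#' @return Fraction of positions covered by no interval.
#' @export
intergenic_fraction <- function(genes, genome_length) {
  if (nrow(genes) == 0) return(1)
  ir <- IRanges::reduce(IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  covered <- sum(BiocGenerics::width(ir))
  1 - covered / genome_length
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment at the defaults of the classic
#' pairwise-alignment tools (BLOSUM62, gap open 10, gap extend 0.5; a gap of
#' length L costs `gap_open + L * gap_extend`). End gaps are penalized.
#' Identity and similarity percentages use the full alignment length
#' (including gap columns) as denominator; similarity counts residue pairs
#' with a positive substitution score.
#'
#' @param a,b Protein sequences (single strings, one-letter code).
#' @param substitution Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `nap_alignment`: a list with `aligned_a`,
#'   `aligned_b`, `score`, `identity_pct`, `similarity_pct` plus the
#'   parameters used. `tidy()` returns a one-row tibble summary.
#' @examples
#' global_align("MKVLA", "MKILA")
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) abort("empty protein sequence")
  mat <- substitution_matrix(substitution)
  letters_ok <- rownames(mat)
  for (s in c(a, b)) {
    res <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(res, letters_ok)
    if (length(bad) > 0) {
      abort(paste0("unknown residue letter(s): ", paste(bad, collapse = ", ")))
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aa <- as.character(Biostrings::alignedPattern(aln))
  bb <- as.character(Biostrings::alignedSubject(aln))
  stats <- alignment_stats(aa, bb, mat)
  structure(
    list(
      aligned_a = aa, aligned_b = bb,
      score = Biostrings::score(aln),
      identity_pct = stats$identity_pct,
      similarity_pct = stats$similarity_pct,
      substitution = substitution,
      gap_open = gap_open, gap_extend = gap_extend
    ),
    class = "nap_alignment"
  )
}

substitution_matrix <- function(name) {
  env <- new.env()
  ok <- tryCatch(
    {
      utils::data(list = name, package = "Biostrings", envir = env)
      TRUE
    },
    warning = function(w) FALSE, error = function(e) FALSE
  )
  if (!ok || !exists(name, envir = env)) {
    abort(paste0("unknown substitution matrix: ", name))
  }
  get(name, envir = env)
}

# identity = identical pairs / alignment length; similarity additionally
# counts non-identical residue pairs with positive substitution score.
alignment_stats <- function(aa, bb, mat) {
  ca <- strsplit(aa, "")[[1]]
  cb <- strsplit(bb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  len <- length(ca)
  resid <- ca != "-" & cb != "-"
  ident <- sum(ca == cb & resid)
  simil <- ident
  for (i in which(resid & ca != cb)) {
    if (mat[ca[i], cb[i]] > 0) simil <- simil + 1
  }
  list(identity_pct = 100 * ident / len, similarity_pct = 100 * simil / len)
}

#' @export
print.nap_alignment <- function(x, ...) {
  cat("Global alignment (", x$substitution, ", gap ", x$gap_open, "/",
      x$gap_extend, ")\n", sep = "")
  cat("  score:      ", format(x$score), "\n", sep = "")
  cat("  identity:   ", sprintf("%.1f%%", x$identity_pct), "\n", sep = "")
  cat("  similarity: ", sprintf("%.1f%%", x$similarity_pct), "\n", sep = "")
  cat("  ", x$aligned_a, "\n  ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.nap_alignment <- function(x, ...) {
  tibble(
    score = x$score,
    identity_pct = x$identity_pct,
    similarity_pct = x$similarity_pct,
    alignment_length = nchar(x$aligned_a),
    substitution = x$substitution,
    gap_open = x$gap_open,
    gap_extend = x$gap_extend
  )
}
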