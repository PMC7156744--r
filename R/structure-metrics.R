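#' Read atomic coordinates from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a flat atom table. Alternate
#' locations are resolved to the highest-occupancy conformer per
#' chain/residue/atom (first on ties).
#'
#' @param path Path to a PDB-format file.
#' @param model_index Model to read from a multi-model file (default 1).
#' @return An object of class `nap_structure`: a list with an `$atoms`
#'   tibble (`chain`, `residue_number`, `residue_name`, `atom_name`,
#'   `x`, `y`, `z`, `occupancy`).
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("cannot parse PDB file: ", path))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(paste0("no ATOM records in ", path))
  }
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    abort(paste0("model_index ", model_index, " out of range (file has ",
                 n_models, " model(s))"))
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  atoms <- tibble(
    chain = as.character(at$chain),
    residue_number = as.integer(at$resno),
    residue_name = as.character(at$resid),
    atom_name = as.character(at$elety),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o))
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("non-finite coordinates in PDB file")
  }
  # resolve altlocs: keep the highest-occupancy conformer per atom
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$residue_number, .data$atom_name) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    arrange(.data$chain, .data$residue_number, .data$atom_name)
  structure(list(atoms = select(atoms, -"altloc")), class = "nap_structure")
}

#' Write an atom table to a PDB file
#'
#' Minimal ATOM-record writer (coordinates at PDB precision, 3 decimals);
#' used mainly to build small coordinate fixtures.
#'
#' @param model An `nap_structure` or a tibble shaped like its `$atoms`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  atoms <- if (inherits(model, "nap_structure")) model$atoms else model
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    name <- atoms$atom_name[i]
    # PDB atom-name column convention: pad short names starting in col 14
    name_f <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else name
    sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, name_f, atoms$residue_name[i], atoms$chain[i],
      atoms$residue_number[i], atoms$x[i], atoms$y[i], atoms$z[i],
      if ("occupancy" %in% names(atoms)) atoms$occupancy[i] else 1, 0
    )
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

resolve_atom <- function(model, sel) {
  stopifnot(inherits(model, "nap_structure"))
  a <- model$atoms
  hit <- a$chain == sel[[1]] & a$residue_number == as.integer(sel[[2]]) &
    a$atom_name == sel[[3]]
  if (sum(hit) != 1) {
    abort(paste0(
      "selection chain ", sel[[1]], " residue ", sel[[2]], " atom ",
      sel[[3]], " resolves to ", sum(hit), " atoms (need exactly 1)"
    ))
  }
  unlist(a[hit, c("x", "y", "z")])
}

#' Euclidean distance between two selected atoms
#'
#' @param model An `nap_structure`.
#' @param sel_a,sel_b Selections `list(chain, residue_number, atom_name)`.
#' @return Distance in Angstroms.
#' @export
residue_atom_distance <- function(model, sel_a, sel_b) {
  pa <- resolve_atom(model, sel_a)
  pb <- resolve_atom(model, sel_b)
  sqrt(sum((pa - pb)^2))
}

#' Cross-dimer distance report for a tetramer
#'
#' Distances between equivalent atoms (by default the residue-12 C-alpha)
#' across the specified dimer-dimer chain pairs, plus their mean. In a
#' dimer-of-dimers this measures how far apart the two DNA-reading
#' beta-sheets sit.
#'
#' @param model An `nap_structure`.
#' @param residue_number Residue number of the equivalent residues.
#' @param atom Atom name (default `"CA"`).
#' @param dimer_pairing List of cross-dimer chain pairs, e.g.
#'   `list(c("A", "C"), c("B", "D"))`.
#' @return An object of class `nap_distance_report`: list with a
#'   `$distances` tibble (`chain_a`, `chain_b`, `distance_A`) and the
#'   `$mean` distance.
#' @export
intersheet_distance_report <- function(model, residue_number = 12,
                                       atom = "CA",
                                       dimer_pairing = list(c("A", "C"),
                                                            c("B", "D"))) {
  rows <- lapply(dimer_pairing, function(pair) {
    d <- residue_atom_distance(
      model,
      list(pair[1], residue_number, atom),
      list(pair[2], residue_number, atom)
    )
    tibble(chain_a = pair[1], chain_b = pair[2], distance_A = d)
  })
  distances <- bind_rows(rows)
  structure(
    list(distances = distances, mean = mean(distances$distance_A),
         residue_number = residue_number, atom = atom),
    class = "nap_distance_report"
  )
}

#' @export
print.nap_distance_report <- function(x, ...) {
  cat("Cross-dimer ", x$atom, " distances at residue ", x$residue_number,
      ":\n", sep = "")
  for (i in seq_len(nrow(x$distances))) {
    cat(sprintf("  %s-%s: %.2f A\n", x$distances$chain_a[i],
                x$distances$chain_b[i], x$distances$distance_A[i]))
  }
  cat(sprintf("  mean: %.2f A\n", x$mean))
  invisible(x)
}

#' Synthetic tetramer coordinate fixture
#'
#' Builds a minimal dimer-of-dimers C-alpha model: two two-chain dimers
#' (chains A/B and C/D) translated so that the residue-12 C-alpha atoms of
#' equivalent chains across the dimers sit exactly `separation_A`
#' Angstroms apart. This is a synthetic stand-in used to exercise the
#' distance machinery; it is not a deposited structure.
#'
#' @param separation_A Cross-dimer separation in Angstroms.
#' @param n_residues C-alpha atoms per chain.
#' @return An `nap_structure`.
#' @export
synthetic_tetramer_structure <- function(separation_A = 35, n_residues = 20) {
  one_chain <- function(chain, y0, z0) {
    tibble(
      chain = chain,
      residue_number = seq_len(n_residues),
      residue_name = "ALA",
      atom_name = "CA",
      x = 3.8 * (seq_len(n_residues) - 1),  # extended-chain CA spacing
      y = y0, z = z0, occupancy = 1
    )
  }
  atoms <- bind_rows(
    one_chain("A", 0, 0),
    one_chain("B", 5, 0),
    one_chain("C", 0, separation_A),
    one_chain("D", 5, separation_A)
  )
  structure(list(atoms = atoms), class = "nap_structure")
}
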