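# Synthetic data: random chains with planted palindromes, and
# ideal-geometry peptide structures written as valid PDB files. These are
# the fixtures that make the whole pipeline testable without downloads.

# Standard backbone internal coordinates (Angstrom / degrees).
#' @noRd
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           ca_cb = 1.530,
           ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
           ang_ca_c_o = 120.8, ang_n_ca_cb = 109.5,
           omega = 180, cb_improper = 120)  # dihedral C-N-CA-CB, L-chirality

#' Canonical backbone dihedrals for ideal conformers
#' @param conformer "helix" (phi -57, psi -47) or "strand" (phi -139, psi 135)
#' @return list with `phi` and `psi` in degrees
#' @export
ideal_conformer <- function(conformer = c("helix", "strand")) {
  switch(match.arg(conformer),
         helix = list(phi = -57, psi = -47),
         strand = list(phi = -139, psi = 135))
}

#' Build an ideal-geometry peptide structure
#'
#' Places backbone atoms (N, CA, C, O, and CB for non-glycine) by
#' sequential internal-coordinate construction with standard bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A), omega = 180 deg, and the
#' requested per-residue phi/psi. Recomputing phi/psi from the output
#' reproduces the request to well under 0.1 deg.
#'
#' @param sequence one-letter amino-acid string (standard residues only)
#' @param conformer "helix", "strand", or NULL to use `phi`/`psi`
#' @param phi,psi per-residue dihedrals in degrees (scalar, recycled)
#' @param chain_id chain identifier for the output model
#' @param pdb_id identifier stamped on the model
#' @return a `structure_model`
#' @export
build_ideal_peptide <- function(sequence, conformer = "helix",
                                phi = NULL, psi = NULL,
                                chain_id = "A", pdb_id = "SYNT") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters1)
  if (n < 2) stop("sequence must have at least 2 residues")
  if (!all(letters1 %in% AA1)) {
    stop("unsupported residue letter(s): ",
         paste(setdiff(letters1, AA1), collapse = ", "))
  }
  if (!is.null(conformer)) {
    cf <- ideal_conformer(conformer)
    if (is.null(phi)) phi <- cf$phi
    if (is.null(psi)) psi <- cf$psi
  }
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  resnames <- names(AA1)[match(letters1, AA1)]

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB$n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ],
                       BB$ca_c, BB$ang_n_ca_c, 120)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BB$c_n, BB$ang_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BB$n_ca, BB$ang_c_n_ca, BB$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BB$ca_c, BB$ang_n_ca_c, phi[i])
  }
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BB$c_o, BB$ang_ca_c_o, psi[i] + 180)
    if (resnames[i] != "GLY") {
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                            BB$ca_cb, BB$ang_n_ca_cb, BB$cb_improper)
    }
  }

  rows <- list()
  for (i in 1:n) {
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (resnames[i] != "GLY") {
      nm <- c(nm, "CB"); el <- c(el, "C"); xyz <- rbind(xyz, CB[i, ])
    }
    rows[[i]] <- data.frame(
      record = "ATOM", serial = NA_integer_, name = nm, altloc = "",
      resname = resnames[i], chain = chain_id, resno = i, icode = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
      element = el, is_hetero = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure_model(atoms, pdb_id = pdb_id,
                      classification = "SYNTHETIC PEPTIDE")
}

# Assemble a structure_model from an atom table (used by the builders).
#' @noRd
new_structure_model <- function(atoms, pdb_id = "SYNT",
                                classification = "SYNTHETIC PEPTIDE",
                                title = "", site_records = NULL) {
  res_key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
                   atoms$is_hetero)
  atoms$rid <- match(res_key, unique(res_key))
  first <- !duplicated(atoms$rid)
  residues <- data.frame(
    rid = atoms$rid[first], chain = atoms$chain[first],
    resno = atoms$resno[first], icode = atoms$icode[first],
    resname = atoms$resname[first], is_hetero = atoms$is_hetero[first],
    stringsAsFactors = FALSE)
  residues$is_water <- residues$resname %in% WATER_NAMES
  residues$one_letter <- aa_three_to_one(residues$resname)
  residues$one_letter[residues$is_hetero] <- "X"
  residues$is_complete <- residue_completeness(atoms, residues)
  empty_sites <- data.frame(site = character(0), resname = character(0),
                            chain = character(0), resno = integer(0),
                            icode = character(0), stringsAsFactors = FALSE)
  structure(list(
    pdb_id = pdb_id, classification = classification, title = title,
    compound = list(), resolution = NA_real_,
    atoms = atoms, residues = residues,
    site_records = site_records %||% empty_sites,
    dangling_sites = empty_sites, seqres = list()
  ), class = "structure_model")
}

#' Add a het atom (ligand/metal decoy) to a structure model
#'
#' @param model a `structure_model`
#' @param element element symbol (e.g. "ZN")
#' @param xyz numeric 3-vector, Angstrom
#' @param resname het residue name (defaults to the element symbol)
#' @param resno residue number (defaults past the last)
#' @param chain chain id for the het group
#' @param name atom name (defaults to the element symbol)
#' @return the modified `structure_model`
#' @export
add_het_atom <- function(model, element, xyz, resname = element,
                         resno = max(model$atoms$resno) + 1L,
                         chain = model$atoms$chain[1], name = element) {
  row <- data.frame(
    record = "HETATM", serial = max(model$atoms$serial) + 1L, name = name,
    altloc = "", resname = resname, chain = chain, resno = resno,
    icode = "", x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
    element = toupper(element), is_hetero = TRUE, stringsAsFactors = FALSE)
  atoms <- rbind(model$atoms[, names(row)], row)
  new_structure_model(atoms, pdb_id = model$pdb_id,
                      classification = model$classification,
                      title = model$title, site_records = model$site_records)
}

#' Merge several structure models into one (distinct chains expected)
#' @param ... `structure_model` objects
#' @param pdb_id identifier for the merged model
#' @return a `structure_model`
#' @export
merge_models <- function(..., pdb_id = "SYNT") {
  cols <- c("record", "serial", "name", "altloc", "resname", "chain",
            "resno", "icode", "x", "y", "z", "occ", "b", "element",
            "is_hetero")
  atoms <- do.call(rbind, lapply(list(...), function(m) m$atoms[, cols]))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure_model(atoms, pdb_id = pdb_id)
}

#' Apply a rigid transform to all atoms of a model
#' @param model a `structure_model`
#' @param rotation 3x3 rotation matrix
#' @param translation 3-vector
#' @return the transformed `structure_model`
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  model$atoms$x <- xyz[, 1] + translation[1]
  model$atoms$y <- xyz[, 2] + translation[2]
  model$atoms$z <- xyz[, 3] + translation[3]
  model
}

#' Build an ideal two-strand antiparallel sheet
#'
#' Builds one ideal strand, then places a 180-degree-flipped copy (second
#' chain) by a deterministic optimization that drives the inter-strand
#' O...N hydrogen-bond distances of paired residues toward 2.9 A — a
#' purely geometric construction criterion. Used as the strand fixture
#' for secondary-structure assignment.
#'
#' @param sequence one-letter sequence per strand (default poly-V 8-mer)
#' @return a `structure_model` with chains A and B
#' @export
build_antiparallel_sheet <- function(sequence = "VTVTVTVT") {
  s1 <- build_ideal_peptide(sequence, "strand", chain_id = "A")
  n <- nchar(sequence)
  ca1 <- backbone_coords(s1, "A", "CA")
  axis <- vunit(ca1[n, ] - ca1[1, ])
  center <- colMeans(ca1)
  perp <- vunit(vcross(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0)
                             else c(0, 1, 0)))
  # 180 deg about an in-plane perpendicular reverses the chain direction,
  # giving the antiparallel arrangement
  flip <- rotation_about_axis(perp, 180)

  bb1 <- list(O = backbone_coords(s1, "A", "O"),
              N = backbone_coords(s1, "A", "N"),
              C = backbone_coords(s1, "A", "C"))
  # amide H of each residue (none for the first)
  H1 <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    H1[i, ] <- bb1$N[i, ] + vunit(bb1$C[i - 1, ] - bb1$O[i - 1, ])
  }
  pair_i <- seq(2, n - 1, by = 2)           # hydrogen-bonded pairs
  pair_j <- n + 1 - pair_i

  # target ideal linear N-H...O=C hydrogen bonds: O...N 2.9 A, O...H 1.9 A
  objective <- function(p) {
    rot <- rotation_about_axis(axis, p[4]) %*% flip
    tr <- function(m) sweep(sweep(m, 2, center) %*% t(rot), 2,
                            center + p[1:3], "+")
    O2 <- tr(bb1$O); N2 <- tr(bb1$N); H2 <- tr(H1)
    val <- 0
    for (k in seq_along(pair_i)) {
      i <- pair_i[k]; j <- pair_j[k]
      val <- val + (vnorm(bb1$O[i, ] - N2[j, ]) - 2.9)^2 +
        (vnorm(bb1$N[i, ] - O2[j, ]) - 2.9)^2
      if (!anyNA(H2[j, ])) {
        val <- val + (vnorm(bb1$O[i, ] - H2[j, ]) - 1.9)^2
      }
      if (!anyNA(H1[i, ])) {
        val <- val + (vnorm(H1[i, ] - O2[j, ]) - 1.9)^2
      }
    }
    ca2 <- tr(ca1)
    dca <- as.matrix(stats::dist(rbind(ca1, ca2)))[1:n, n + 1:n]
    val + sum(pmax(0, 4.2 - dca)^2)
  }
  best <- NULL
  starts <- list()
  for (dir in list(perp, -perp, vcross(axis, perp), -vcross(axis, perp))) {
    for (spin in c(0, 90, 180, 270)) {
      starts[[length(starts) + 1L]] <- c(dir * 4.8, spin)
    }
  }
  for (start in starts) {
    fit <- stats::optim(start, objective, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  rot <- rotation_about_axis(axis, p[4]) %*% flip
  s2 <- transform_model(s1, diag(3), -center)
  s2 <- transform_model(s2, rot, center + p[1:3])
  s2$atoms$chain <- "B"
  merge_models(s1, s2, pdb_id = "SHEE")
}

#' @noRd
rotation_about_axis <- function(axis, angle_deg) {
  u <- vunit(axis); th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# n x 3 coordinates of one named backbone atom along a chain.
#' @noRd
backbone_coords <- function(model, chain_id, atom_name) {
  a <- model$atoms
  sel <- a$chain == chain_id & a$name == atom_name & !a$is_hetero
  as.matrix(a[sel, c("x", "y", "z")])
}

#' Write a structure model as a PDB file
#'
#' Emits HEADER, ATOM/HETATM, TER and END records with the fixed v3.3
#' column layout, preserving author numbering and insertion codes, so the
#' output round-trips through [read_structure()].
#'
#' @param model a `structure_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  hdr_id <- if (nchar(model$pdb_id) == 4) toupper(model$pdb_id) else "XXXX"
  writeLines(sprintf("HEADER    %-40s%9s   %4s",
                     toupper(model$classification), "", hdr_id), con)
  fmt_name <- function(name, element) {
    ifelse(nchar(name) >= 4, substr(name, 1, 4),
           ifelse(nchar(element) == 2 & toupper(substr(name, 1, 2)) == element,
                  sprintf("%-4s", name), sprintf(" %-3s", name)))
  }
  serial <- 0L
  emit <- function(rows) {
    for (k in seq_len(nrow(rows))) {
      serial <<- serial + 1L
      r <- rows[k, ]
      writeLines(sprintf(
        "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        r$record, serial, fmt_name(r$name, r$element), r$altloc,
        r$resname, r$chain, r$resno, ifelse(nzchar(r$icode), r$icode, " "),
        r$x, r$y, r$z, r$occ, r$b, r$element), con)
    }
  }
  poly <- a[!a$is_hetero, , drop = FALSE]
  for (ch in unique(poly$chain)) {
    rows <- poly[poly$chain == ch, , drop = FALSE]
    emit(rows)
    serial <- serial + 1L
    last <- rows[nrow(rows), ]
    writeLines(sprintf("TER   %5d      %3s %1s%4d%1s", serial, last$resname,
                       last$chain, last$resno,
                       ifelse(nzchar(last$icode), last$icode, " ")), con)
  }
  het <- a[a$is_hetero, , drop = FALSE]
  if (nrow(het)) emit(het)
  writeLines("END", con)
  invisible(path)
}

#' Generate a random chain with planted palindromes
#'
#' Draws a background sequence from the given residue frequencies, then
#' overwrites the planted palindromic windows at their stated positions.
#' A post-scan records accidental background palindromes so that recovery
#' tests can separate planted truth from chance hits.
#'
#' @param background_length chain length
#' @param planted list of `list(sequence=, position=)` with 1-based start
#'   positions; each sequence must be palindromic
#' @param residue_frequencies named 20-vector of residue probabilities
#'   (default uniform); normalised internally
#' @param seed integer seed governing the background draw
#' @param allow_overlap permit overlapping plants (default FALSE)
#' @param chain_id,pdb_id identifiers stamped on the output
#' @param min_len minimum palindrome length used by the accidental post-scan
#' @return list with `chain` (a `chain_sequence`), `truth` (data.frame of
#'   planted windows: sequence, start_index 0-based, end_index half-open,
#'   start_resno, end_resno) and `accidental` (hit table of non-planted
#'   palindromic windows)
#' @export
generate_sequence_with_palindromes <- function(background_length,
                                               planted = list(),
                                               residue_frequencies = NULL,
                                               seed = 1L,
                                               allow_overlap = FALSE,
                                               chain_id = "A",
                                               pdb_id = "SYNT",
                                               min_len = 5L) {
  if (is.null(residue_frequencies)) {
    residue_frequencies <- stats::setNames(rep(1 / 20, 20), AA1)
  }
  stopifnot(all(AA1 %in% names(residue_frequencies)))
  p <- residue_frequencies[AA1] / sum(residue_frequencies[AA1])
  intervals <- list()
  for (pl in planted) {
    s <- toupper(pl$sequence); pos <- as.integer(pl$position)
    if (!is_palindrome(s)) stop("planted sequence is not a palindrome: ", s)
    if (pos < 1 || pos + nchar(s) - 1 > background_length) {
      stop("planted sequence '", s, "' does not fit at position ", pos)
    }
    intervals[[length(intervals) + 1L]] <- c(pos, pos + nchar(s) - 1L)
  }
  if (!allow_overlap && length(intervals) > 1) {
    iv <- do.call(rbind, intervals)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      stop("planted palindromes overlap; set allow_overlap = TRUE to permit")
    }
  }
  set.seed(seed)
  letters1 <- sample(AA1, background_length, replace = TRUE, prob = p)
  truth <- list()
  for (pl in planted) {
    s <- strsplit(toupper(pl$sequence), "")[[1]]
    pos <- as.integer(pl$position)
    letters1[pos:(pos + length(s) - 1L)] <- s
    truth[[length(truth) + 1L]] <- data.frame(
      sequence = pl$sequence, start_index = pos - 1L,
      end_index = pos - 1L + length(s), start_resno = pos,
      end_resno = pos + length(s) - 1L, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sequence = character(0), start_index = integer(0),
               end_index = integer(0), start_resno = integer(0),
               end_resno = integer(0), stringsAsFactors = FALSE)
  chain <- structure(list(
    pdb_id = pdb_id, chain_id = chain_id,
    sequence = paste(letters1, collapse = ""), letters = letters1,
    resno = seq_len(background_length),
    icode = rep("", background_length),
    complete = rep(TRUE, background_length),
    rid = seq_len(background_length)
  ), class = "chain_sequence")
  hits <- enumerate_palindromes(chain, scan_config(min_len = min_len,
                                                   max_len = background_length))
  planted_key <- paste(truth$start_index, truth$end_index)
  accidental <- hits[!(paste(hits$start_index, hits$end_index) %in%
                         planted_key), , drop = FALSE]
  list(chain = chain, truth = truth, accidental = accidental)
}

#' Write a synthetic classic-format DSSP fixture
#'
#' Emits the minimal classic DSSP layout (header banner plus per-residue
#' table) that [read_dssp()] consumes; used to exercise the reader
#' round-trip without an external DSSP program.
#'
#' @param df data.frame with columns `chain`, `resno`, `icode`, `aa`, `ss`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dssp_fixture <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "==== Secondary Structure Definition, synthetic fixture ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"), con)
  for (k in seq_len(nrow(df))) {
    ss <- ifelse(df$ss[k] == "C", " ", df$ss[k])
    writeLines(sprintf("%5d%5d%1s%1s %1s  %1s",
                       k, df$resno[k],
                       ifelse(nzchar(df$icode[k]), df$icode[k], " "),
                       df$chain[k], df$aa[k], ss), con)
  }
  invisible(path)
}
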