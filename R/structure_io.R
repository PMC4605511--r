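# Structure input: PDB files into a uniform structure model, per-chain
# one-letter sequences with completeness flags, and classic DSSP output.
#
# ATOM/HETATM parsing is delegated to bio3d::read.pdb; header-level records
# that bio3d does not expose (HEADER classification, TITLE/COMPND, SITE,
# SEQRES, REMARK 2 resolution) are extracted from the raw lines here.

#' Read a PDB file into a structure model
#'
#' Parses ATOM/HETATM records (first MODEL only), resolves alternate
#' locations to the highest-occupancy conformer (ties: altloc 'A' or first
#' encountered), separates waters from other het groups, and extracts
#' HEADER classification, TITLE, COMPND molecule names, SEQRES, SITE
#' records and the REMARK 2 resolution.
#'
#' @param path path to a PDB-format file
#' @param first_model_only read only the first MODEL of multi-model files
#'   (default TRUE; the survey targets crystal structures)
#' @return an object of class `structure_model`: a list with elements
#'   `pdb_id`, `classification`, `title`, `resolution`, `compound`,
#'   `atoms` (one row per atom), `residues` (one row per residue, with
#'   `one_letter`, `is_complete`, `is_hetero`, `is_water` flags),
#'   `site_records`, `dangling_sites` and `seqres`
#' @export
read_structure <- function(path, first_model_only = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  n_atom_lines <- sum(rec %in% c("ATOM  ", "HETATM"))
  if (n_atom_lines == 0) {
    stop("empty structure: no ATOM records in ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (first_model_only && !is.null(pdb$xyz) && is.matrix(pdb$xyz) &&
      nrow(pdb$xyz) > 1) {
    at <- at[seq_len(nrow(at)), , drop = FALSE]  # bio3d already keeps model 1
  }
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad)) {
    stop("parse error in ", path, ": non-numeric coordinates at atom record ",
         bad[1], " (", at$elety[bad[1]], " ", at$resid[bad[1]], ")")
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  elem <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]

  atoms <- data.frame(
    record = at$type, serial = at$eleno, name = trimws(at$elety),
    altloc = at$alt, resname = trimws(at$resid), chain = at$chain,
    resno = at$resno, icode = at$insert,
    x = at$x, y = at$y, z = at$z, occ = at$o, b = at$b,
    element = elem, stringsAsFactors = FALSE)
  # modified polymer residues (MSE, PTR, ...) are deposited as HETATM but
  # belong to the chain; they stay polymer and map to 'X'
  atoms$is_hetero <- atoms$record == "HETATM" &
    !(atoms$resname %in% MODIFIED_RESIDUES)
  atoms <- resolve_altlocs(atoms)

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

  hdr <- parse_pdb_header(lines)
  sites <- parse_site_records(lines)
  dangling <- integer(0)
  if (nrow(sites)) {
    skey <- paste(sites$chain, sites$resno, sites$icode)
    rkey <- paste(residues$chain, residues$resno, residues$icode)
    dangling <- which(!(skey %in% rkey))
  }
  structure(list(
    pdb_id = hdr$pdb_id %||% toupper(sub("\\.(pdb|ent)$", "",
                                         basename(path), ignore.case = TRUE)),
    classification = hdr$classification,
    title = hdr$title,
    compound = hdr$compound,
    resolution = hdr$resolution,
    atoms = atoms,
    residues = residues,
    site_records = if (nrow(sites)) sites[setdiff(seq_len(nrow(sites)),
                                                  dangling), , drop = FALSE]
                   else sites,
    dangling_sites = if (length(dangling)) sites[dangling, , drop = FALSE]
                     else sites[0, , drop = FALSE],
    seqres = parse_seqres(lines)
  ), class = "structure_model")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

# Keep, per (chain, resno, icode, resname, atom name), the highest-occupancy
# altloc; ties broken toward altloc 'A' / first encountered.
#' @noRd
resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$name)
  ord <- order(match(key, unique(key)), -atoms$occ,
               atoms$altloc != "", atoms$altloc,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                   atoms$resname, atoms$name)), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' @noRd
residue_completeness <- function(atoms, residues) {
  heavy <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  vapply(seq_len(nrow(residues)), function(i) {
    expected <- EXPECTED_HEAVY[[residues$resname[i]]]
    if (is.null(expected)) return(FALSE)  # nonstandard: conservatively incomplete
    have <- heavy$name[heavy$rid == residues$rid[i]]
    all(expected %in% have)
  }, logical(1))
}

#' @noRd
parse_pdb_header <- function(lines) {
  out <- list(pdb_id = NULL, classification = "UNCLASSIFIED", title = "",
              compound = list(), resolution = NA_real_)
  hd <- lines[startsWith(lines, "HEADER")]
  if (length(hd)) {
    cls <- trimws(substr(hd[1], 11, 50))
    if (nzchar(cls)) out$classification <- cls
    id <- trimws(substr(hd[1], 63, 66))
    if (nzchar(id)) out$pdb_id <- toupper(id)
  }
  tl <- lines[startsWith(lines, "TITLE")]
  if (length(tl)) out$title <- trimws(paste(trimws(substr(tl, 11, 80)),
                                            collapse = " "))
  rem2 <- lines[startsWith(lines, "REMARK   2 RESOLUTION")]
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) out$resolution <- as.numeric(m)
  }
  out$compound <- parse_compnd(lines)
  out
}

# COMPND MOLECULE/CHAIN pairs -> list of (molecule, chains)
#' @noRd
parse_compnd <- function(lines) {
  cp <- lines[startsWith(lines, "COMPND")]
  if (!length(cp)) return(list())
  txt <- paste(trimws(substr(cp, 11, 80)), collapse = " ")
  blocks <- strsplit(txt, "MOL_ID:")[[1]]
  out <- list()
  for (b in blocks[-1][nzchar(blocks[-1])]) {
    mol <- regmatches(b, regexpr("MOLECULE:\\s*[^;]+", b))
    chn <- regmatches(b, regexpr("CHAIN:\\s*[^;]+", b))
    mol <- if (length(mol)) trimws(sub("MOLECULE:\\s*", "", mol)) else ""
    chains <- if (length(chn)) {
      trimws(strsplit(sub("CHAIN:\\s*", "", chn), ",")[[1]])
    } else character(0)
    out[[length(out) + 1L]] <- list(molecule = mol, chains = chains)
  }
  out
}

#' @noRd
parse_site_records <- function(lines) {
  st <- lines[startsWith(lines, "SITE")]
  cols <- list(c(19, 21, 23, 23, 24, 27, 28, 28),
               c(30, 32, 34, 34, 35, 38, 39, 39),
               c(41, 43, 45, 45, 46, 49, 50, 50),
               c(52, 54, 56, 56, 57, 60, 61, 61))
  rows <- list()
  for (ln in st) {
    site <- trimws(substr(ln, 12, 14))
    for (cc in cols) {
      resname <- trimws(substr(ln, cc[1], cc[2]))
      if (!nzchar(resname)) next
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, resname = resname,
        chain = substr(ln, cc[3], cc[4]),
        resno = suppressWarnings(as.integer(substr(ln, cc[5], cc[6]))),
        icode = trimws(substr(ln, cc[7], cc[8])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(site = character(0), resname = character(0),
                      chain = character(0), resno = integer(0),
                      icode = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @noRd
parse_seqres <- function(lines) {
  sr <- lines[startsWith(lines, "SEQRES")]
  if (!length(sr)) return(list())
  chains <- substr(sr, 12, 12)
  out <- list()
  for (ch in unique(chains)) {
    resnames <- unlist(strsplit(trimws(substr(sr[chains == ch], 20, 70)),
                                "\\s+"))
    out[[ch]] <- resnames[nzchar(resnames)]
  }
  out
}

#' Polymer chain identifiers of a structure model
#' @param model a `structure_model`
#' @return character vector of chain ids, in file order
#' @export
chain_ids <- function(model) {
  unique(model$residues$chain[!model$residues$is_hetero])
}

#' One-letter sequence of a chain, with completeness mask
#'
#' The sequence derives from ATOM-record polymer residues in file order
#' (not SEQRES), so every position has coordinates. Nonstandard residues
#' map to 'X'; `complete` mirrors the per-residue heavy-atom check.
#'
#' @param model a `structure_model`
#' @param chain_id chain identifier
#' @return an object of class `chain_sequence`: list with `pdb_id`,
#'   `chain_id`, `sequence` (string), `letters`, `resno`, `icode`,
#'   `complete` (parallel vectors)
#' @export
chain_sequence <- function(model, chain_id) {
  res <- model$residues[!model$residues$is_hetero, , drop = FALSE]
  if (!chain_id %in% res$chain) {
    stop("unknown chain '", chain_id, "'; available: ",
         paste(unique(res$chain), collapse = ", "))
  }
  res <- res[res$chain == chain_id, , drop = FALSE]
  structure(list(
    pdb_id = model$pdb_id, chain_id = chain_id,
    sequence = paste(res$one_letter, collapse = ""),
    letters = res$one_letter, resno = res$resno, icode = res$icode,
    complete = res$is_complete, rid = res$rid
  ), class = "chain_sequence")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$pdb_id, "-", x$classification, "\n")
  cat("  chains:", paste(chain_ids(x), collapse = ", "),
      " polymer residues:", sum(!x$residues$is_hetero),
      " het groups:", sum(x$residues$is_hetero & !x$residues$is_water),
      " waters:", sum(x$residues$is_water), "\n")
  if (!is.na(x$resolution)) cat("  resolution:", x$resolution, "A\n")
  invisible(x)
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat("<chain_sequence>", x$pdb_id, "chain", x$chain_id, "-",
      nchar(x$sequence), "residues\n  ", x$sequence, "\n")
  invisible(x)
}

#' Read classic DSSP output
#'
#' Parses the per-residue table of a classic-format DSSP file. A blank
#' structure column maps to 'C' (coil); chain-break rows ('!') are
#' skipped. Residues present in a structure but absent from the DSSP file
#' are mapped to '-' by [dssp_codes_for_chain()].
#'
#' @param path path to a DSSP file
#' @return data.frame with columns `chain`, `resno`, `icode`, `aa`, `ss`
#' @export
read_dssp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE AA STRUCTURE", lines)
  if (!length(hdr)) stop("malformed DSSP file (no residue table header): ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "C"
  data.frame(
    chain = substr(body, 12, 12),
    resno = as.integer(trimws(substr(body, 6, 10))),
    icode = trimws(substr(body, 11, 11)),
    aa = aa[keep], ss = ss, stringsAsFactors = FALSE)
}

#' Align DSSP codes to a chain sequence
#'
#' @param dssp data.frame from [read_dssp()]
#' @param chain_seq a `chain_sequence`
#' @return character vector of codes, one per chain residue; residues
#'   missing from the DSSP table get '-'
#' @export
dssp_codes_for_chain <- function(dssp, chain_seq) {
  d <- dssp[dssp$chain == chain_seq$chain_id, , drop = FALSE]
  key <- paste(d$resno, d$icode)
  idx <- match(paste(chain_seq$resno, chain_seq$icode), key)
  out <- d$ss[idx]
  out[is.na(out)] <- "-"
  out
}
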