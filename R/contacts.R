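# Neighborhood contacts and functional-interaction flags.

# Heavy-atom coordinates of a hit's residues.
#' @noRd
hit_atom_rows <- function(model, hit) {
  res <- model$residues[!model$residues$is_hetero, , drop = FALSE]
  chain_rows <- which(res$chain == hit$chain_id)
  pos <- which(res$resno[chain_rows] == hit$start_resno &
                 res$icode[chain_rows] == hit$start_icode)
  if (length(pos) != 1 || pos + hit$length - 1L > length(chain_rows)) {
    stop("hit residues ", hit$start_resno, "-", hit$end_resno,
         " not found in chain ", hit$chain_id)
  }
  rids <- res$rid[chain_rows[pos:(pos + hit$length - 1L)]]
  which(model$atoms$rid %in% rids & model$atoms$element != "H")
}

#' Count counted-once neighborhood contacts of a hit
#'
#' Partitions the structure into the hit's atoms ('target') and all other
#' polymer-residue atoms of all chains ('source'). A source residue
#' counts exactly once if any of its heavy atoms lies within `cutoff` of
#' any hit heavy atom. Hydrogens are excluded; het groups are excluded
#' unless `include_het` (they feed [functional_interactions()] instead).
#'
#' @param model a `structure_model`
#' @param hit one row of a hit table
#' @param cutoff contact distance in Angstrom (default 3.2)
#' @param include_het count het-group residues too (default FALSE)
#' @return list with `n_contact_residues`, `cutoff`, and `contacts`
#'   (data.frame chain/resno/icode/resname of each counted residue)
#' @export
count_contacts <- function(model, hit, cutoff = 3.2, include_het = FALSE) {
  stopifnot(cutoff > 0)
  tgt <- hit_atom_rows(model, hit)
  a <- model$atoms
  src <- a$element != "H" & !(seq_len(nrow(a)) %in% tgt) &
    !(a$rid %in% a$rid[tgt])
  if (!include_het) src <- src & !a$is_hetero
  src <- which(src)
  if (!length(src) || !length(tgt)) {
    return(list(n_contact_residues = 0L, cutoff = cutoff,
                contacts = model$residues[0, c("chain", "resno", "icode",
                                               "resname")]))
  }
  txyz <- as.matrix(a[tgt, c("x", "y", "z")])
  sxyz <- as.matrix(a[src, c("x", "y", "z")])
  hit_rids <- unique(a$rid[tgt])
  touching <- logical(length(src))
  for (k in seq_len(nrow(txyz))) {
    d2 <- rowSums(sweep(sxyz, 2, txyz[k, ])^2)
    touching <- touching | (d2 <= cutoff^2)
  }
  rids <- setdiff(unique(a$rid[src[touching]]), hit_rids)
  contacts <- model$residues[match(rids, model$residues$rid),
                             c("chain", "resno", "icode", "resname"),
                             drop = FALSE]
  rownames(contacts) <- NULL
  list(n_contact_residues = nrow(contacts), cutoff = cutoff,
       contacts = contacts)
}

#' @noRd
is_metal_atom <- function(atoms) {
  atoms$element %in% METAL_ELEMENTS
}

#' Functional-interaction flags of a hit
#'
#' Flags whether the palindrome is associated with (a) a ligand: any
#' non-water, non-metal het atom within `cutoff`; (b) a metal ion:
#' likewise for metal elements; (c) an annotated or catalytic site: a hit
#' residue appears in a SITE record or the user-supplied catalytic list,
#' or contacts such a residue within `cutoff`; (d) a disulphide bridge: a
#' hit cysteine SG within `ss_bond_cutoff` of another cysteine SG.
#'
#' @param model a `structure_model`
#' @param hit one row of a hit table
#' @param catalytic_list optional data.frame with columns `chain`,
#'   `resno`, `icode` naming catalytic residues
#' @param cutoff interaction distance in Angstrom (default 3.9)
#' @param ss_bond_cutoff S-S bond distance in Angstrom (default 2.3)
#' @return list of class `interaction_flags` with logical `ligand`,
#'   `metal`, `site_or_catalytic`, `disulphide` and a `provenance` note
#'   per true flag
#' @export
functional_interactions <- function(model, hit, catalytic_list = NULL,
                                    cutoff = 3.9, ss_bond_cutoff = 2.3) {
  a <- model$atoms
  tgt <- hit_atom_rows(model, hit)
  txyz <- as.matrix(a[tgt, c("x", "y", "z")])
  prov <- character(0)

  near_any <- function(rows) {
    if (!length(rows)) return(FALSE)
    xyz <- as.matrix(a[rows, c("x", "y", "z"), drop = FALSE])
    for (k in seq_len(nrow(txyz))) {
      if (any(rowSums(sweep(xyz, 2, txyz[k, ])^2) <= cutoff^2)) return(TRUE)
    }
    FALSE
  }

  het <- a$is_hetero & !(a$resname %in% WATER_NAMES) & a$element != "H"
  lig_rows <- which(het & !is_metal_atom(a))
  met_rows <- which(het & is_metal_atom(a))
  ligand <- near_any(lig_rows)
  if (ligand) prov <- c(prov, paste0("ligand het group within ", cutoff, " A"))
  metal <- near_any(met_rows)
  if (metal) prov <- c(prov, paste0("metal within ", cutoff, " A"))

  site_res <- model$site_records[, c("chain", "resno", "icode"), drop = FALSE]
  if (!is.null(catalytic_list) && nrow(catalytic_list)) {
    cl <- catalytic_list[, c("chain", "resno", "icode"), drop = FALSE]
    res_key <- paste(model$residues$chain, model$residues$resno,
                     model$residues$icode)
    missing <- !(paste(cl$chain, cl$resno, cl$icode) %in% res_key)
    if (any(missing)) {
      warning("catalytic list entries not found in structure: ",
              paste(paste0(cl$chain[missing], ":", cl$resno[missing]),
                    collapse = ", "))
    }
    site_res <- rbind(site_res, cl[!missing, , drop = FALSE])
  }
  site_or_catalytic <- FALSE
  if (nrow(site_res)) {
    skey <- paste(site_res$chain, site_res$resno, site_res$icode)
    hit_key <- paste(hit$chain_id,
                     model$residues$resno[match(unique(a$rid[tgt]),
                                                model$residues$rid)],
                     model$residues$icode[match(unique(a$rid[tgt]),
                                                model$residues$rid)])
    if (any(hit_key %in% skey)) {
      site_or_catalytic <- TRUE
      prov <- c(prov, "hit residue annotated in SITE/catalytic list")
    } else {
      res_key <- paste(model$residues$chain, model$residues$resno,
                       model$residues$icode)
      site_rids <- model$residues$rid[res_key %in% skey]
      site_rows <- which(a$rid %in% site_rids & a$element != "H")
      if (near_any(site_rows)) {
        site_or_catalytic <- TRUE
        prov <- c(prov, paste0("contacts a SITE/catalytic residue within ",
                               cutoff, " A"))
      }
    }
  }

  disulphide <- FALSE
  sg_hit <- tgt[a$name[tgt] == "SG" & a$resname[tgt] == "CYS"]
  if (length(sg_hit)) {
    sg_other <- which(a$name == "SG" & a$resname == "CYS" &
                        !(seq_len(nrow(a)) %in% tgt))
    if (length(sg_other)) {
      for (k in sg_hit) {
        d <- sqrt(rowSums(sweep(
          as.matrix(a[sg_other, c("x", "y", "z"), drop = FALSE]), 2,
          unlist(a[k, c("x", "y", "z")]))^2))
        if (any(d <= ss_bond_cutoff)) {
          disulphide <- TRUE
          prov <- c(prov, "hit CYS SG in S-S bond distance of another SG")
          break
        }
      }
    }
  }
  structure(list(ligand = ligand, metal = metal,
                 site_or_catalytic = site_or_catalytic,
                 disulphide = disulphide, provenance = prov),
            class = "interaction_flags")
}
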