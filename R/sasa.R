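# Solvent-accessible surface area by Shrake-Rupley sphere-point sampling.
# Deterministic: test points come from a golden-spiral lattice, so results
# are a pure function of coordinates, radii, probe and n_points.

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples `n_points` quasi-uniform points on each heavy atom's solvent
#' sphere (van der Waals radius + probe) and counts the fraction not
#' buried inside any neighbouring atom's sphere. The occlusion context is
#' all chains plus het groups; crystallographic waters and hydrogens are
#' excluded by default. Per-residue SASA is the sum over the residue's
#' atoms.
#'
#' @param model a `structure_model`
#' @param probe probe radius in Angstrom (default 1.4, water)
#' @param n_points sphere sample points per atom (default 960)
#' @param include_waters include waters in the occlusion context
#' @param radii named vector of per-element radii in Angstrom; defaults to
#'   C 1.70, N 1.55, O 1.52, S 1.80 (and standard values for P, Se,
#'   halogens)
#' @param fallback_radius radius for elements absent from `radii`
#'   (warning issued)
#' @return object of class `sasa_profile`: data.frame with one row per
#'   non-water residue (`chain`, `resno`, `icode`, `resname`, `sasa`),
#'   with the probe, n_points and radii set as attributes
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               include_waters = FALSE,
                               radii = VDW_RADII, fallback_radius = 1.7) {
  stopifnot(probe > 0, n_points >= 12)
  a <- model$atoms
  keep <- a$element != "H" & a$element != "D"
  if (!include_waters) keep <- keep & !(a$resname %in% WATER_NAMES)
  a <- a[keep, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- radii[a$element]
  if (any(is.na(r))) {
    warning("no radius for element(s) ",
            paste(unique(a$element[is.na(r)]), collapse = ", "),
            "; using fallback ", fallback_radius, " A")
    r[is.na(r)] <- fallback_radius
  }
  r <- unname(r) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(p[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- dj > r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  res <- model$residues
  res <- res[!res$is_water, , drop = FALSE]
  sasa <- vapply(res$rid, function(rid) sum(area[a$rid == rid]), numeric(1))
  out <- data.frame(chain = res$chain, resno = res$resno, icode = res$icode,
                    resname = res$resname, sasa = sasa,
                    stringsAsFactors = FALSE)
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  attr(out, "radii_set") <- radii
  class(out) <- c("sasa_profile", "data.frame")
  out
}

#' Average solvent accessibility of a hit
#'
#' Arithmetic mean of the per-residue SASA values over the palindrome's
#' residues: the sum of the residue values divided by the peptide length.
#'
#' @param hit one row of a hit table
#' @param profile a `sasa_profile` covering the hit's residues
#' @return average SASA in Angstrom squared
#' @export
average_sasa <- function(hit, profile) {
  idx <- match(paste(hit$chain_id,
                     seq(hit$start_resno, length.out = hit$length)),
               paste(profile$chain, profile$resno))
  # author numbering may be non-contiguous (insertion codes); fall back to
  # positional lookup within the chain
  if (any(is.na(idx))) {
    chain_rows <- which(profile$chain == hit$chain_id)
    pos <- which(profile$resno[chain_rows] == hit$start_resno &
                   profile$icode[chain_rows] == hit$start_icode)
    if (length(pos) != 1 ||
        pos + hit$length - 1L > length(chain_rows)) {
      stop("SASA profile does not cover residues ", hit$start_resno, "-",
           hit$end_resno, " of chain ", hit$chain_id)
    }
    idx <- chain_rows[pos:(pos + hit$length - 1L)]
  }
  mean(profile$sasa[idx])
}
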