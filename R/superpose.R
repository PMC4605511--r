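# Structural comparison of identical palindromes from different
# structures: optimal rigid superposition (Kabsch) of backbone atoms and
# per-position side-chain divergence after the backbone fit.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets; reflections are rejected via the SVD sign
#' correction, so `det(rotation) = +1`. The transform maps `coords_b`
#' onto `coords_a`: `b' = b R^T + t`.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (Angstrom)
#' @return object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (3-vector), `rmsd` (Angstrom over the fitted set) and
#'   `n_atoms`
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || ncol(coords_a) != 3) {
    stop("coordinate sets must be paired n x 3 matrices")
  }
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 paired atoms, got ", n)
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  sv <- svd(t(B) %*% A)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (abs(sv$d[2]) < 1e-10) {
    warning("(near-)collinear coordinates; superposition is degenerate")
  }
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(ca - cb %*% t(R)),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup a `superposition`
#' @param coords n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

# Coordinates of selected atom names for each residue of a hit, as a list
# (one matrix per position, rownames = atom names).
#' @noRd
hit_residue_coords <- function(model, hit, atom_names = NULL,
                               exclude = NULL) {
  res <- model$residues[!model$residues$is_hetero, , drop = FALSE]
  chain_rows <- which(res$chain == hit$chain_id)
  pos <- which(res$resno[chain_rows] == hit$start_resno &
                 res$icode[chain_rows] == hit$start_icode)
  if (length(pos) != 1) stop("hit not resolvable in model")
  rids <- res$rid[chain_rows[pos:(pos + hit$length - 1L)]]
  lapply(rids, function(rid) {
    rows <- model$atoms$rid == rid & model$atoms$element != "H"
    if (!is.null(atom_names)) rows <- rows & model$atoms$name %in% atom_names
    if (!is.null(exclude)) rows <- rows & !(model$atoms$name %in% exclude)
    m <- as.matrix(model$atoms[rows, c("x", "y", "z"), drop = FALSE])
    rownames(m) <- model$atoms$name[rows]
    m
  })
}

#' Superpose two identical palindromes on their backbone atoms
#'
#' @param model_a,model_b `structure_model`s containing the hits
#' @param hit_a,hit_b hit rows with identical sequences
#' @param atom_set backbone atoms used for fitting (default N, CA, C, O;
#'   use `"CA"` for CA-only fitting)
#' @return a `superposition` over the shared backbone atoms
#' @export
superpose_hits <- function(model_a, hit_a, model_b, hit_b,
                           atom_set = c("N", "CA", "C", "O")) {
  if (hit_a$sequence != hit_b$sequence) {
    stop("hits have different sequences: ", hit_a$sequence, " vs ",
         hit_b$sequence)
  }
  ra <- hit_residue_coords(model_a, hit_a, atom_names = atom_set)
  rb <- hit_residue_coords(model_b, hit_b, atom_names = atom_set)
  A <- B <- NULL
  for (i in seq_along(ra)) {
    shared <- intersect(rownames(ra[[i]]), rownames(rb[[i]]))
    A <- rbind(A, ra[[i]][shared, , drop = FALSE])
    B <- rbind(B, rb[[i]][shared, , drop = FALSE])
  }
  kabsch_superpose(A, B)
}

#' Per-position side-chain divergence after backbone superposition
#'
#' Applies the backbone transform to the second structure and reports,
#' for each palindrome position, the RMSD over the side-chain heavy atoms
#' shared by both structures (glycine and positions with no shared
#' side-chain atoms give NA).
#'
#' @param model_a,model_b `structure_model`s
#' @param hit_a,hit_b identical-sequence hit rows
#' @param superposition a `superposition` from [superpose_hits()]
#' @param threshold divergence flag threshold in Angstrom (default 1.0)
#' @return data.frame: `position`, `residue`, `n_atoms` (shared
#'   side-chain heavy atoms), `rmsd`, `divergent`
#' @export
sidechain_divergence <- function(model_a, hit_a, model_b, hit_b,
                                 superposition, threshold = 1.0) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  ra <- hit_residue_coords(model_a, hit_a, exclude = backbone)
  rb <- hit_residue_coords(model_b, hit_b, exclude = backbone)
  letters1 <- strsplit(hit_a$sequence, "")[[1]]
  out <- data.frame(position = seq_along(ra), residue = letters1,
                    n_atoms = 0L, rmsd = NA_real_, divergent = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ra)) {
    shared <- intersect(rownames(ra[[i]]), rownames(rb[[i]]))
    out$n_atoms[i] <- length(shared)
    if (!length(shared)) next
    if (length(shared) < max(nrow(ra[[i]]), nrow(rb[[i]]))) {
      attr(out, "partial_coverage") <- TRUE
    }
    bfit <- apply_superposition(superposition,
                                rb[[i]][shared, , drop = FALSE])
    out$rmsd[i] <- sqrt(mean(rowSums(
      (ra[[i]][shared, , drop = FALSE] - bfit)^2)))
    out$divergent[i] <- out$rmsd[i] > threshold
  }
  out
}
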