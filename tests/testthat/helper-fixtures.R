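# Shared fixtures and independent oracles for the test suite.

# Minimal chain_sequence built directly from a string.
make_chain <- function(seq, complete = NULL, pdb_id = "TEST",
                       chain_id = "A", resno = NULL) {
  letters1 <- strsplit(seq, "")[[1]]
  n <- length(letters1)
  structure(list(
    pdb_id = pdb_id, chain_id = chain_id, sequence = seq,
    letters = letters1,
    resno = resno %||% seq_len(n), icode = rep("", n),
    complete = complete %||% rep(TRUE, n), rid = seq_len(n)
  ), class = "chain_sequence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal probe/target sliding-search oracle: probe every window of each
# length, invert it, search the whole sequence for exact matches, and
# collapse probe<->target duplicates. A window is a palindrome hit when
# it matches its own inversion at its own position.
oracle_probe_target <- function(seq, min_len = 5, max_len = 9) {
  n <- nchar(seq)
  out <- list()
  for (L in min_len:min(max_len, n)) {
    starts <- seq_len(n - L + 1L)
    probes <- substring(seq, starts, starts + L - 1L)
    targets <- vapply(probes, function(p)
      paste(rev(strsplit(p, "")[[1]]), collapse = ""), character(1))
    for (i in starts) {
      js <- which(probes == targets[i])     # slide target over sequence
      if (i %in% js && !grepl("X", probes[i], fixed = TRUE)) {
        out[[length(out) + 1L]] <- data.frame(
          start_index = i - 1L, length = L, sequence = probes[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start_index = integer(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))        # collapse duplicates
  res <- res[order(res$start_index, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Independent filter mirroring the survey's exclusions, applied to the
# oracle's hits (CARP and duplicate removal; all test chains complete).
oracle_filter <- function(hits) {
  if (!nrow(hits)) return(hits)
  carp <- vapply(strsplit(hits$sequence, ""), function(ch)
    all(ch == ch[1]), logical(1))
  hits[!carp, , drop = FALSE]
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# Reference DSSP implementation (mdtraj, Python) run on a PDB file;
# returns the concatenated per-residue codes with mdtraj's ' ' mapped to
# 'C'.
mdtraj_dssp <- function(pdb_path) {
  code <- paste0(
    "import mdtraj as md; import sys;",
    "t = md.load(sys.argv[1]);",
    "print(''.join(md.compute_dssp(t, simplified=False)[0]).replace(' ','C'))")
  out <- system2("python", c("-c", shQuote(code), shQuote(pdb_path)),
                 stdout = TRUE, stderr = FALSE)
  out[length(out)]
}

# Brute-force rigid-superposition RMSD oracle: random-restart numerical
# minimisation over rotations (Euler angles) and translations.
oracle_min_rmsd <- function(A, B, n_starts = 40) {
  rot_from <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  obj <- function(p) {
    sqrt(mean(rowSums((Bc %*% t(rot_from(p)) - Ac)^2)))
  }
  best <- Inf
  set.seed(99)
  for (k in seq_len(n_starts)) {
    p0 <- runif(3, -pi, pi)
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Small helix/strand peptide models reused across structural tests.
helix_model <- function(n = 12) build_ideal_peptide(strrep("A", n), "helix")
sheet_model <- function() build_antiparallel_sheet("VTVTVTVT")
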