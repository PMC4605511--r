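# Secondary-structure assignment from hydrogen-bonding patterns, following
# the Kabsch-Sander scheme: an amide H is placed 1.0 A from N opposite the
# preceding carbonyl, the electrostatic bond energy
#   E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)  [kcal/mol]
# defines a hydrogen bond when E < -0.5, and n-turn / bridge patterns give
# the codes H, G, I, E, B, T, S, with C for coil and '-' for residues
# lacking backbone coordinates. Hydrogen bonds are evaluated across all
# chains of the model, so inter-chain sheets are detected.

#' Assign DSSP-style secondary structure to a chain
#'
#' @param model a `structure_model`
#' @param chain_id chain to report (patterns are computed over all chains)
#' @param dssp optional data.frame from [read_dssp()]; when supplied its
#'   codes take precedence over the built-in assigner
#' @param hbond_cutoff hydrogen-bond energy threshold in kcal/mol
#'   (default -0.5)
#' @return character vector of per-residue codes over
#'   \{H,G,I,E,B,T,S,C,-\} aligned to the chain's polymer residues
#' @export
assign_secondary_structure <- function(model, chain_id, dssp = NULL,
                                       hbond_cutoff = -0.5) {
  chain_seq <- chain_sequence(model, chain_id)
  if (!is.null(dssp)) return(dssp_codes_for_chain(dssp, chain_seq))
  full <- assign_ss_all(model, hbond_cutoff)
  full$ss[full$chain == chain_id]
}

# Assignment over all polymer residues of the model; returns data.frame
# (chain, resno, icode, ss) in file order.
#' @noRd
assign_ss_all <- function(model, hbond_cutoff = -0.5) {
  res <- model$residues[!model$residues$is_hetero, , drop = FALSE]
  n <- nrow(res)
  bb <- backbone_table(model, res)
  has_bb <- bb$has_bb
  ss <- ifelse(has_bb, "C", "-")
  if (n < 3) return(data.frame(chain = res$chain, resno = res$resno,
                               icode = res$icode, ss = ss,
                               stringsAsFactors = FALSE))

  # peptide bond i -> i+1 (same chain, C-N distance < 2.5 A)
  bonded <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (res$chain[i] == res$chain[i + 1] && has_bb[i] && has_bb[i + 1]) {
      bonded[i] <- vnorm(bb$C[i, ] - bb$N[i + 1, ]) < 2.5
    }
  }
  # amide H: 1.0 A from N along the preceding C=O direction (no H for
  # proline or stretch-initial residues)
  H <- matrix(NA_real_, n, 3)
  donor_ok <- rep(FALSE, n)
  for (i in 2:n) {
    if (bonded[i - 1] && res$resname[i] != "PRO") {
      H[i, ] <- bb$N[i, ] + vunit(bb$C[i - 1, ] - bb$O[i - 1, ])
      donor_ok[i] <- TRUE
    }
  }
  hb <- hbond_matrix(bb, H, donor_ok, has_bb, hbond_cutoff)

  turn <- list()
  for (tn in 3:5) {
    tt <- rep(FALSE, n)
    for (i in seq_len(n - tn)) {
      if (hb[i, i + tn] && all(bonded[i:(i + tn - 1)])) tt[i] <- TRUE
    }
    turn[[tn]] <- tt
  }

  assigned <- rep("", n)
  put <- function(idx, code) {
    idx <- idx[idx >= 1 & idx <= n]
    assigned[idx][assigned[idx] == ""] <<- code
  }
  # alpha helix: two consecutive 4-turns
  for (i in 2:max(2, n - 4)) {
    if (turn[[4]][i - 1] && turn[[4]][i]) put(i:(i + 3), "H")
  }
  # bridges and ladders
  br <- find_bridges(hb, bonded, n)
  if (nrow(br)) {
    ladder <- vapply(seq_len(nrow(br)), function(k) {
      any(abs(br$i - br$i[k]) == 1 & abs(br$j - br$j[k]) == 1 &
            br$anti == br$anti[k])
    }, logical(1))
    for (k in seq_len(nrow(br))) {
      code <- if (ladder[k]) "E" else "B"
      put(c(br$i[k], br$j[k]), code)
    }
  }
  # 3/10 and pi helices
  for (i in 2:max(2, n - 3)) {
    if (turn[[3]][i - 1] && turn[[3]][i]) put(i:(i + 2), "G")
  }
  for (i in 2:max(2, n - 5)) {
    if (turn[[5]][i - 1] && turn[[5]][i]) put(i:(i + 4), "I")
  }
  # turns
  for (tn in 3:5) {
    for (i in which(turn[[tn]])) put((i + 1):(i + tn - 1), "T")
  }
  # bends: CA virtual-bond angle > 70 degrees
  for (i in 3:max(3, n - 2)) {
    if (i + 2 <= n && all(bonded[(i - 2):(i + 1)])) {
      u <- bb$CA[i, ] - bb$CA[i - 2, ]
      v <- bb$CA[i + 2, ] - bb$CA[i, ]
      kappa <- acos(max(-1, min(1, sum(vunit(u) * vunit(v))))) * 180 / pi
      if (kappa > 70) put(i, "S")
    }
  }
  ss[assigned != ""] <- assigned[assigned != ""]
  ss[!has_bb] <- "-"
  data.frame(chain = res$chain, resno = res$resno, icode = res$icode,
             ss = ss, stringsAsFactors = FALSE)
}

# Backbone coordinates (N, CA, C, O) per polymer residue.
#' @noRd
backbone_table <- function(model, res) {
  a <- model$atoms
  out <- list()
  for (nm in c("N", "CA", "C", "O")) {
    m <- matrix(NA_real_, nrow(res), 3)
    sel <- a$name == nm & !a$is_hetero
    idx <- match(res$rid, a$rid[sel])
    found <- !is.na(idx)
    m[found, ] <- as.matrix(a[sel, c("x", "y", "z")])[idx[found], ,
                                                      drop = FALSE]
    out[[nm]] <- m
  }
  out$has_bb <- stats::complete.cases(cbind(out$N, out$CA, out$C, out$O))
  out
}

# hb[i, j] TRUE when the C=O of residue i accepts the N-H of residue j.
#' @noRd
hbond_matrix <- function(bb, H, donor_ok, has_bb, cutoff) {
  n <- nrow(bb$CA)
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  near <- which(has_bb)
  for (j in which(donor_ok & has_bb)) {      # donor j
    ca_d2 <- rowSums(sweep(bb$CA[near, , drop = FALSE], 2,
                           bb$CA[j, ])^2)
    for (i in near[ca_d2 < 81]) {            # acceptor i, CA within 9 A
      if (i == j) next
      d_on <- vnorm(bb$O[i, ] - bb$N[j, ])
      d_ch <- vnorm(bb$C[i, ] - H[j, ])
      d_oh <- vnorm(bb$O[i, ] - H[j, ])
      d_cn <- vnorm(bb$C[i, ] - bb$N[j, ])
      if (min(d_on, d_ch, d_oh, d_cn) < 0.5) {
        e <- -9.9
      } else {
        e <- q * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
      }
      if (e < cutoff) hb[i, j] <- TRUE
    }
  }
  hb
}

# Kabsch-Sander bridge patterns; returns one row per bridge pair (i < j).
#' @noRd
find_bridges <- function(hb, bonded, n) {
  ok_prev <- function(i) i >= 2 && bonded[i - 1]
  ok_next <- function(i) i <= n - 1 && bonded[i]
  rows <- list()
  cand <- which(rowSums(hb) + colSums(hb) > 0)
  for (i in cand) {
    for (j in cand[cand > i]) {
      if (j - i <= 2) next
      par <- (ok_prev(i) && ok_next(i) && hb[i - 1, j] && hb[j, i + 1]) ||
             (ok_prev(j) && ok_next(j) && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (ok_prev(i) && ok_next(i) && ok_prev(j) && ok_next(j) &&
                 hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) {
        rows[[length(rows) + 1L]] <- data.frame(i = i, j = j,
                                                anti = anti && !par)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(i = integer(0), j = integer(0), anti = logical(0)))
  }
  do.call(rbind, rows)
}

#' Secondary-structure string of a hit
#'
#' @param hit one row of a hit table
#' @param ss_codes per-residue codes for the hit's chain (from
#'   [assign_secondary_structure()])
#' @return string of length `hit$length`
#' @export
hit_ss_string <- function(hit, ss_codes) {
  paste(ss_codes[(hit$start_index + 1L):hit$end_index], collapse = "")
}
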