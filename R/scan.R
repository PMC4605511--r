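# Palindrome enumeration, exclusion filters, unique-sequence tallies, and
# matched non-palindrome control sampling.
#
# A PALIN is a self-palindromic window: the probe/target sliding search of
# the survey reports a window whose inversion equals itself. Windows are
# enumerated directly and the probe<->target double count never arises.

#' Scan configuration
#'
#' @param min_len minimum palindrome length (default 5, pentapeptides)
#' @param max_len maximum palindrome length (default 9; `Inf` to disable)
#' @param exclude_carp drop continuous single-amino-acid repeats (default TRUE)
#' @param require_complete drop windows containing residues with missing
#'   heavy atoms (default TRUE)
#' @param maximal_only report only palindromic windows not contained in a
#'   longer palindromic window (default FALSE: co-centered sub-palindromes
#'   are reported)
#' @param seed integer seed for control-window sampling
#' @return a list of class `scan_config`
#' @export
scan_config <- function(min_len = 5L, max_len = 9L, exclude_carp = TRUE,
                        require_complete = TRUE, maximal_only = FALSE,
                        seed = 1L) {
  min_len <- as.integer(min_len)
  if (min_len < 3L) stop("min_len must be >= 3")
  if (is.finite(max_len) && max_len < min_len) {
    stop("max_len must be >= min_len")
  }
  structure(list(min_len = min_len, max_len = max_len,
                 exclude_carp = exclude_carp,
                 require_complete = require_complete,
                 maximal_only = maximal_only, seed = as.integer(seed)),
            class = "scan_config")
}

#' Is a peptide sequence a palindrome?
#'
#' Character-exact: the sequence must equal its reversal. 'X' (unknown
#' residue) never matches itself, so any sequence containing 'X' is not
#' palindromic.
#'
#' @param seq one-letter peptide string (vectorised)
#' @return logical vector
#' @export
is_palindrome <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  vapply(seq, function(s) {
    if (grepl("X", s, fixed = TRUE)) return(FALSE)
    ch <- strsplit(s, "")[[1]]
    all(ch == rev(ch))
  }, logical(1), USE.NAMES = FALSE)
}

#' @noRd
empty_hits <- function() {
  data.frame(pdb_id = character(0), chain_id = character(0),
             start_index = integer(0), end_index = integer(0),
             length = integer(0), sequence = character(0),
             start_resno = integer(0), start_icode = character(0),
             end_resno = integer(0), end_icode = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate palindromic windows of a chain
#'
#' Slides windows of every length between `min_len` and `max_len` one
#' residue at a time and reports each self-palindromic window exactly
#' once, sorted by (start, length). No exclusion filters are applied here
#' (see [filter_hits()]); windows containing 'X' are inherently
#' non-palindromic and never emitted.
#'
#' @param chain a `chain_sequence`
#' @param cfg a `scan_config`
#' @return hit table: one row per palindromic window with 0-based
#'   half-open indices (`start_index`, `end_index`) and author residue
#'   numbers (`start_resno`/`end_resno`, 1-based inclusive)
#' @export
enumerate_palindromes <- function(chain, cfg = scan_config()) {
  letters1 <- chain$letters
  n <- length(letters1)
  rows <- list()
  lmax <- min(n, cfg$max_len)
  if (n >= cfg$min_len) {
    for (L in cfg$min_len:lmax) {
      starts <- seq_len(n - L + 1L)
      ok <- rep(TRUE, length(starts))
      for (k in seq_len(L %/% 2)) {
        ok <- ok & (letters1[starts + k - 1L] == letters1[starts + L - k])
      }
      for (k in seq_len(L)) {          # 'X' never matches itself
        ok <- ok & (letters1[starts + k - 1L] != "X")
      }
      for (s in starts[ok]) {
        rows[[length(rows) + 1L]] <- c(s, L)
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  m <- do.call(rbind, rows)
  s <- m[, 1]; L <- m[, 2]
  hits <- data.frame(
    pdb_id = chain$pdb_id, chain_id = chain$chain_id,
    start_index = s - 1L, end_index = s - 1L + L, length = L,
    sequence = vapply(seq_along(s), function(i)
      paste(letters1[s[i]:(s[i] + L[i] - 1L)], collapse = ""), character(1)),
    start_resno = chain$resno[s], start_icode = chain$icode[s],
    end_resno = chain$resno[s + L - 1L], end_icode = chain$icode[s + L - 1L],
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$start_index, hits$length), , drop = FALSE]
  if (cfg$maximal_only && nrow(hits) > 1) {
    contained <- vapply(seq_len(nrow(hits)), function(i) {
      any(hits$start_index <= hits$start_index[i] &
            hits$end_index >= hits$end_index[i] &
            hits$length > hits$length[i])
    }, logical(1))
    hits <- hits[!contained, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Apply the survey's exclusion filters to a hit table
#'
#' Removes (a) CARPs — windows whose residues are all identical; (b)
#' windows containing any residue with missing heavy atoms or an 'X'
#' letter; (c) exact positional duplicates. Order is preserved.
#'
#' @param hits hit table from [enumerate_palindromes()] on the same chain
#' @param chain the `chain_sequence` the hits were scanned from
#' @param cfg a `scan_config`
#' @return filtered hit table, with attribute `"excluded"` giving one
#'   reason per removed row (carp / incomplete / duplicate)
#' @export
filter_hits <- function(hits, chain, cfg = scan_config()) {
  if (!nrow(hits)) return(hits)
  if (any(hits$end_index > length(chain$letters)) ||
      any(hits$start_index < 0)) {
    stop("hit interval outside chain '", chain$chain_id, "'")
  }
  reason <- rep(NA_character_, nrow(hits))
  if (cfg$exclude_carp) {
    carp <- vapply(hits$sequence, function(s) {
      ch <- strsplit(s, "")[[1]]; all(ch == ch[1])
    }, logical(1))
    reason[carp] <- "carp"
  }
  if (cfg$require_complete) {
    bad <- vapply(seq_len(nrow(hits)), function(i) {
      idx <- (hits$start_index[i] + 1L):hits$end_index[i]
      any(!chain$complete[idx]) || any(chain$letters[idx] == "X")
    }, logical(1))
    reason[is.na(reason) & bad] <- "incomplete"
  }
  dup <- duplicated(paste(hits$chain_id, hits$start_index, hits$end_index))
  reason[is.na(reason) & dup] <- "duplicate"
  out <- hits[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  excluded <- hits[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  attr(out, "excluded") <- excluded
  out
}

#' Tally unique palindrome sequences by length
#'
#' A sequence observed at k locations across all chains counts once per
#' distinct string.
#'
#' @param hits a hit table (possibly spanning many chains)
#' @return list with `by_length` (data.frame: length, n_hits, n_unique)
#'   and `multiplicity` (data.frame: sequence, length, n_occurrences)
#' @export
unique_sequences <- function(hits) {
  if (!nrow(hits)) {
    return(list(
      by_length = data.frame(length = integer(0), n_hits = integer(0),
                             n_unique = integer(0)),
      multiplicity = data.frame(sequence = character(0), length = integer(0),
                                n_occurrences = integer(0))))
  }
  tab <- stats::aggregate(list(n_occurrences = hits$sequence),
                          by = list(sequence = hits$sequence,
                                    length = hits$length), FUN = length)
  tab <- tab[order(tab$length, tab$sequence), , drop = FALSE]
  rownames(tab) <- NULL
  by_len <- stats::aggregate(
    list(n_hits = tab$n_occurrences, n_unique = tab$n_occurrences),
    by = list(length = tab$length),
    FUN = length)
  by_len$n_hits <- vapply(by_len$length, function(L)
    sum(hits$length == L), integer(1))
  list(by_length = by_len, multiplicity = tab)
}

#' Sample matched non-palindrome control windows
#'
#' For each hit, draws one window of identical length uniformly at random
#' (with replacement) over all valid placements in the chain set: the
#' window must not be palindromic, must pass the same completeness
#' filter, and must not coincide positionally with any hit.
#'
#' @param chains list of `chain_sequence` objects
#' @param hits hit table whose per-length histogram the controls match
#' @param cfg a `scan_config` (its `seed` governs the draw)
#' @return control table with the same positional columns as a hit table
#'   plus `is_palindrome = FALSE`
#' @export
sample_control_windows <- function(chains, hits, cfg = scan_config()) {
  if (!nrow(hits)) {
    out <- empty_hits(); out$is_palindrome <- logical(0); return(out)
  }
  set.seed(cfg$seed)
  hit_key <- paste(hits$pdb_id, hits$chain_id, hits$start_index, hits$length)
  out <- list()
  for (L in sort(unique(hits$length))) {
    pool <- list()
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      n <- length(ch$letters)
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      ok <- rep(TRUE, length(starts))
      for (k in seq_len(L)) {
        pos <- starts + k - 1L
        ok <- ok & ch$complete[pos] & (ch$letters[pos] != "X")
      }
      pal <- rep(TRUE, length(starts))
      for (k in seq_len(L %/% 2)) {
        pal <- pal & (ch$letters[starts + k - 1L] ==
                        ch$letters[starts + L - k])
      }
      ok <- ok & !pal
      ok <- ok & !(paste(ch$pdb_id, ch$chain_id, starts - 1L, L) %in% hit_key)
      for (s in starts[ok]) pool[[length(pool) + 1L]] <- c(ci, s)
    }
    n_need <- sum(hits$length == L)
    if (!length(pool)) {
      stop("chain set too small to place length-", L, " control windows")
    }
    pick <- sample(length(pool), n_need, replace = TRUE)
    for (p in pick) {
      ci <- pool[[p]][1]; s <- pool[[p]][2]
      ch <- chains[[ci]]
      out[[length(out) + 1L]] <- data.frame(
        pdb_id = ch$pdb_id, chain_id = ch$chain_id,
        start_index = s - 1L, end_index = s - 1L + L, length = L,
        sequence = paste(ch$letters[s:(s + L - 1L)], collapse = ""),
        start_resno = ch$resno[s], start_icode = ch$icode[s],
        end_resno = ch$resno[s + L - 1L], end_icode = ch$icode[s + L - 1L],
        stringsAsFactors = FALSE)
    }
  }
  controls <- do.call(rbind, out)
  controls$is_palindrome <- FALSE
  rownames(controls) <- NULL
  controls
}

#' Scan all chains of a FASTA file for palindromes
#'
#' Sequence-only convenience entry: structure annotations are unavailable
#' for FASTA input.
#'
#' @param path FASTA file
#' @param cfg a `scan_config`
#' @return filtered hit table across all records
#' @export
scan_fasta <- function(path, cfg = scan_config()) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
  out <- list()
  for (nm in names(seqs)) {
    letters1 <- toupper(as.character(seqs[[nm]]))
    ch <- structure(list(
      pdb_id = nm, chain_id = "A",
      sequence = paste(letters1, collapse = ""), letters = letters1,
      resno = seq_along(letters1), icode = rep("", length(letters1)),
      complete = rep(TRUE, length(letters1)), rid = seq_along(letters1)
    ), class = "chain_sequence")
    out[[nm]] <- filter_hits(enumerate_palindromes(ch, cfg), ch, cfg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a hit table as TSV (author numbering, 1-based inclusive)
#' @param hits hit table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
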