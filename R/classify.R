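# Classification of annotated hits: secondary-structure category,
# occurrence modes (nested / overlapping / consecutive / repeated),
# chameleon groups, and protein-family aggregation.

#' Secondary-structure category rule
#'
#' The survey reports whole-palindrome categories: helix, strand, coil
#' (entirely 'C'), or irregular. The default rule is a strict majority
#' (> 50%) of 'H' for helix and of 'E' for strand; whether 3/10 helices
#' ('G') count toward helix and beta-bridges ('B') toward strand, and the
#' majority fraction itself, are configurable.
#'
#' @param majority required code fraction, exclusive (default 0.5)
#' @param count_g count 'G' toward helix (default FALSE)
#' @param count_b count 'B' toward strand (default FALSE)
#' @return list of class `ss_rule`
#' @export
ss_rule <- function(majority = 0.5, count_g = FALSE, count_b = FALSE) {
  structure(list(majority = majority,
                 helix_codes = c("H", if (count_g) "G"),
                 strand_codes = c("E", if (count_b) "B")),
            class = "ss_rule")
}

#' Secondary-structure category of a hit
#'
#' @param ss secondary-structure string aligned to the hit (no '-' codes;
#'   hits over residues without coordinates are excluded upstream)
#' @param rule an [ss_rule()]
#' @return one of "helix", "strand", "coil", "irregular"
#' @export
ss_category <- function(ss, rule = ss_rule()) {
  ch <- strsplit(ss, "")[[1]]
  if (!length(ch)) stop("empty secondary-structure string")
  if (mean(ch %in% rule$helix_codes) > rule$majority) return("helix")
  if (mean(ch %in% rule$strand_codes) > rule$majority) return("strand")
  if (all(ch == "C")) return("coil")
  "irregular"
}

#' Detect occurrence modes among the hits of one chain
#'
#' Pairwise within a chain: nested (interval containment), overlapping
#' (intersection without containment), consecutive (exact adjacency:
#' one window ends where the next begins), and repeated (identical
#' sequence at distinct intervals).
#'
#' @param hits hit table restricted to one chain, sorted by `start_index`
#' @return the hit table with added columns `nested_in` (row index of the
#'   smallest enclosing hit or NA), `overlaps`, `consecutive_with`
#'   (comma-separated row indices, "" if none) and `repeat_group`
#'   (shared id for same-sequence repeats, NA for singletons)
#' @export
detect_modes <- function(hits) {
  n <- nrow(hits)
  hits$nested_in <- NA_integer_
  hits$overlaps <- ""
  hits$consecutive_with <- ""
  hits$repeat_group <- NA_integer_
  if (n < 2) return(hits)
  stopifnot(length(unique(hits$chain_id)) == 1,
            !is.unsorted(hits$start_index))
  s <- hits$start_index; e <- hits$end_index
  for (i in seq_len(n)) {
    enclosing <- which(s <= s[i] & e >= e[i] &
                         (s < s[i] | e > e[i]))
    if (length(enclosing)) {
      hits$nested_in[i] <- enclosing[which.min(hits$length[enclosing])]
    }
    ov <- which(pmax(s, s[i]) < pmin(e, e[i]) &        # intersect
                  !(s <= s[i] & e >= e[i]) &           # not enclosing i
                  !(s >= s[i] & e <= e[i]) &           # not inside i
                  seq_len(n) != i)
    if (length(ov)) hits$overlaps[i] <- paste(ov, collapse = ",")
    adj <- which(e == s[i] | s == e[i])
    if (length(adj)) hits$consecutive_with[i] <- paste(adj, collapse = ",")
  }
  rep_seqs <- unique(hits$sequence[duplicated(hits$sequence)])
  for (k in seq_along(rep_seqs)) {
    hits$repeat_group[hits$sequence == rep_seqs[k]] <- k
  }
  hits
}

#' Find chameleon palindromes
#'
#' Groups hits by exact sequence across the dataset; a group is a
#' chameleon when at least two members carry different secondary-
#' structure categories.
#'
#' @param hits annotated hit table carrying `ss_category`
#' @return data.frame: `sequence`, `n_members`, `categories`
#'   (comma-separated, sorted unique), `is_chameleon`
#' @export
find_chameleons <- function(hits) {
  stopifnot("ss_category" %in% names(hits))
  if (!nrow(hits)) {
    return(data.frame(sequence = character(0), n_members = integer(0),
                      categories = character(0), is_chameleon = logical(0),
                      stringsAsFactors = FALSE))
  }
  grp <- split(hits$ss_category, hits$sequence)
  out <- data.frame(
    sequence = names(grp),
    n_members = vapply(grp, length, integer(1)),
    categories = vapply(grp, function(g)
      paste(sort(unique(g)), collapse = ","), character(1)),
    is_chameleon = vapply(grp, function(g)
      length(unique(g)) >= 2, logical(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hit counts per protein family (PDB header classification)
#'
#' @param hits hit table carrying a `classification` column (attached by
#'   the pipeline from each entry's HEADER record); missing or empty
#'   classifications are binned as "UNCLASSIFIED"
#' @return data.frame `classification`, `n_hits`, sorted by count
#' @export
family_distribution <- function(hits) {
  if (!nrow(hits)) {
    return(data.frame(classification = character(0), n_hits = integer(0),
                      stringsAsFactors = FALSE))
  }
  cls <- hits$classification
  if (is.null(cls)) cls <- rep(NA_character_, nrow(hits))
  cls[is.na(cls) | !nzchar(cls)] <- "UNCLASSIFIED"
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(classification = names(tab), n_hits = as.integer(tab),
             stringsAsFactors = FALSE)
}
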