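# Sequence-level properties: hydropathy, position frequency matrices,
# consensus sequences and logo-ready FASTA exports.

#' Average hydropathy of a peptide
#'
#' Unweighted mean of per-residue hydropathy values (Kyte-Doolittle by
#' default). Symmetric under sequence reversal, so a palindrome and its
#' reversal score identically.
#'
#' @param seq one-letter peptide string
#' @param scale named residue-to-value map (default [kyte_doolittle()])
#' @return numeric value
#' @export
average_hydrophobicity <- function(seq, scale = kyte_doolittle()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (!length(ch)) stop("empty sequence")
  unknown <- setdiff(ch, names(scale))
  if (length(unknown)) {
    stop("no hydropathy value for residue(s): ",
         paste(unknown, collapse = ", "))
  }
  mean(scale[ch])
}

#' Position frequency matrix of equal-length sequences
#'
#' @param seqs character vector of equal-length one-letter sequences
#' @return object of class `pfm`: 20 x L integer matrix of counts (rows =
#'   residues in alphabetical order, columns = positions), with
#'   `n_sequences` attribute; every column sums to `n_sequences`
#' @export
position_frequency_matrix <- function(seqs) {
  if (!length(seqs)) stop("no sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("sequences have mixed lengths: ", paste(L, collapse = ", "))
  }
  letters20 <- sort(AA1)
  mat <- matrix(0L, nrow = 20, ncol = L,
                dimnames = list(letters20, seq_len(L)))
  for (s in seqs) {
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(ch, letters20)
    if (length(bad)) stop("nonstandard letter(s): ", paste(bad, collapse = ", "))
    for (i in seq_len(L)) mat[ch[i], i] <- mat[ch[i], i] + 1L
  }
  attr(mat, "n_sequences") <- length(seqs)
  class(mat) <- c("pfm", class(mat))
  mat
}

#' Consensus sequence of a position frequency matrix
#'
#' Per-column argmax residue; ties resolved lexicographically (rows are
#' alphabetical, the first maximum wins).
#'
#' @param pfm a `pfm` from [position_frequency_matrix()]
#' @return one-letter consensus string
#' @export
consensus <- function(pfm) {
  stopifnot(attr(pfm, "n_sequences") >= 1)
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

#' Export PFM as TSV (positions x residues)
#' @param pfm a `pfm`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- as.data.frame(t(unclass(pfm)))
  df <- cbind(position = seq_len(nrow(df)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export logo-ready FASTA groups
#'
#' Partitions annotated hits by (length, secondary-structure category) and
#' writes one FASTA file per non-empty group, with deterministic record
#' ordering, for use as sequence-logo input.
#'
#' @param hits annotated hit table carrying an `ss_category` column
#' @param out_dir output directory (created if needed)
#' @return named character vector of written paths (names =
#'   "len<L>_<category>")
#' @export
export_logo_groups <- function(hits, out_dir) {
  stopifnot("ss_category" %in% names(hits))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  grp <- split(seq_len(nrow(hits)),
               paste0("len", hits$length, "_", hits$ss_category))
  for (g in names(sort(unlist(lapply(grp, function(i) i[1]))))) {
    idx <- grp[[g]]
    idx <- idx[order(hits$pdb_id[idx], hits$chain_id[idx],
                     hits$start_index[idx])]
    path <- file.path(out_dir, paste0(g, ".fasta"))
    ids <- paste0(hits$pdb_id[idx], "_", hits$chain_id[idx], "_",
                  hits$start_resno[idx], "-", hits$end_resno[idx])
    seqinr::write.fasta(as.list(hits$sequence[idx]), names = ids,
                        file.out = path, nbchar = 60)
    paths[g] <- path
  }
  paths
}
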