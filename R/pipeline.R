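# End-to-end survey pipeline: scan every chain of every input structure,
# annotate retained palindromes, classify them, sample matched controls,
# and emit the annotated hit table plus the summary tables (length
# histogram, secondary-structure composition, per-length SASA ranges,
# hydropathy distribution, unique-sequence tallies, family distribution,
# chameleon list).

#' Pipeline configuration
#'
#' Gathers every numeric constant of the survey in one audited place.
#'
#' @param pdb_files character vector of PDB file paths (alternatively set
#'   `pdb_dir`)
#' @param pdb_dir directory scanned for `*.pdb` / `*.ent` files
#' @param chain_list optional data.frame (`pdb_id`, `chain`) restricting
#'   which chains are scanned; default all chains of every entry
#' @param dssp_dir optional directory of precomputed DSSP files named
#'   `<pdb_id>.dssp` (case-insensitive); when present these codes take
#'   precedence over the built-in assigner
#' @param catalytic_list optional data.frame (`pdb_id`, `chain`, `resno`,
#'   `icode`) of catalytic residues
#' @param scan a [scan_config()]
#' @param probe SASA probe radius, Angstrom (default 1.4)
#' @param n_points SASA sphere points per atom (default 960)
#' @param contact_cutoff neighborhood contact cutoff, Angstrom (default 3.2)
#' @param interaction_cutoff functional-interaction cutoff, Angstrom
#'   (default 3.9)
#' @param rule an [ss_rule()]
#' @param seed integer seed (control sampling)
#' @param out_dir optional output directory for TSV/FASTA artifacts
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(pdb_files = NULL, pdb_dir = NULL,
                            chain_list = NULL, dssp_dir = NULL,
                            catalytic_list = NULL, scan = scan_config(),
                            probe = 1.4, n_points = 960,
                            contact_cutoff = 3.2, interaction_cutoff = 3.9,
                            rule = ss_rule(), seed = 1L, out_dir = NULL) {
  if (is.null(pdb_files)) {
    if (is.null(pdb_dir)) stop("supply pdb_files or pdb_dir")
    pdb_files <- list.files(pdb_dir, pattern = "\\.(pdb|ent)$",
                            full.names = TRUE, ignore.case = TRUE)
  }
  stopifnot(probe > 0, contact_cutoff > 0, interaction_cutoff > 0)
  structure(list(pdb_files = pdb_files, chain_list = chain_list,
                 dssp_dir = dssp_dir, catalytic_list = catalytic_list,
                 scan = scan, probe = probe, n_points = n_points,
                 contact_cutoff = contact_cutoff,
                 interaction_cutoff = interaction_cutoff, rule = rule,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the palindrome survey pipeline
#'
#' @param cfg a [pipeline_config()]
#' @param verbose print progress to stderr
#' @return list with `hits` (annotated hit table: one row per retained
#'   palindrome with positions, sequence, secondary structure, category,
#'   average SASA, contact count, hydropathy, interaction and mode
#'   flags), `controls` (annotated matched non-palindromes), `summary`
#'   (length histogram, SS composition for hits and controls, per-length
#'   SASA ranges, hydropathy distribution, unique-sequence tallies,
#'   family distribution, chameleons), `excluded` (windows removed by
#'   filters, with reasons) and `failures` (per-entry error manifest)
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  hits_all <- list(); excluded_all <- list(); failures <- list()
  chains_all <- list(); control_ctx <- list()
  say <- function(...) if (verbose) message(...)

  for (path in cfg$pdb_files) {
    entry <- tryCatch({
      model <- read_structure(path)
      say("scanning ", model$pdb_id)
      dssp <- NULL
      if (!is.null(cfg$dssp_dir)) {
        cand <- file.path(cfg$dssp_dir,
                          paste0(c(tolower(model$pdb_id),
                                   toupper(model$pdb_id)), ".dssp"))
        cand <- cand[file.exists(cand)]
        if (length(cand)) dssp <- read_dssp(cand[1])
      }
      ss_all <- if (is.null(dssp)) assign_ss_all(model) else NULL
      profile <- shrake_rupley_sasa(model, probe = cfg$probe,
                                    n_points = cfg$n_points)
      chains <- chain_ids(model)
      if (!is.null(cfg$chain_list)) {
        want <- cfg$chain_list$chain[cfg$chain_list$pdb_id == model$pdb_id]
        chains <- intersect(chains, want)
      }
      cat_list <- NULL
      if (!is.null(cfg$catalytic_list)) {
        cat_list <- cfg$catalytic_list[
          cfg$catalytic_list$pdb_id == model$pdb_id, , drop = FALSE]
        if (!nrow(cat_list)) cat_list <- NULL
      }
      entry_hits <- list()
      for (ch in chains) {
        cs <- chain_sequence(model, ch)
        chains_all[[paste(model$pdb_id, ch)]] <- cs
        hits <- enumerate_palindromes(cs, cfg$scan)
        hits <- filter_hits(hits, cs, cfg$scan)
        excl <- attr(hits, "excluded")
        if (!is.null(excl) && nrow(excl)) {
          excluded_all[[length(excluded_all) + 1L]] <- excl
        }
        if (!nrow(hits)) next
        ss_codes <- if (is.null(dssp)) ss_all$ss[ss_all$chain == ch] else
          dssp_codes_for_chain(dssp, cs)
        hits <- annotate_hits(hits, model, cs, ss_codes, profile, cat_list,
                              cfg)
        no_ss <- grepl("-", hits$ss_string, fixed = TRUE)
        if (any(no_ss)) {
          drop <- hits[no_ss, c("pdb_id", "chain_id", "start_index",
                                "end_index", "length", "sequence",
                                "start_resno", "start_icode", "end_resno",
                                "end_icode")]
          drop$reason <- "no-ss"
          excluded_all[[length(excluded_all) + 1L]] <- drop
          hits <- hits[!no_ss, , drop = FALSE]
        }
        if (nrow(hits)) entry_hits[[ch]] <- hits
      }
      control_ctx[[model$pdb_id]] <- list(model = model, ss_all = ss_all,
                                          dssp = dssp, profile = profile)
      entry_hits
    }, error = function(e) e)
    if (inherits(entry, "error")) {
      failures[[path]] <- conditionMessage(entry)
      say("FAILED ", path, ": ", conditionMessage(entry))
    } else if (length(entry)) {
      hits_all <- c(hits_all, entry)
    }
  }
  if (length(failures) == length(cfg$pdb_files)) {
    stop("all entries failed; first error: ", failures[[1]])
  }
  hits <- if (length(hits_all)) do.call(rbind, hits_all) else
    cbind(empty_hits(), annotation_columns())
  rownames(hits) <- NULL
  hits <- add_mode_flags(hits)

  controls <- annotate_controls(chains_all, hits, control_ctx, cfg)
  summary <- summarize_survey(hits, controls)
  excluded <- if (length(excluded_all)) {
    do.call(rbind, lapply(excluded_all, function(d)
      d[, c("pdb_id", "chain_id", "start_resno", "end_resno", "sequence",
            "length", "reason")]))
  } else NULL

  out <- list(hits = hits, controls = controls, summary = summary,
              excluded = excluded, failures = failures)
  if (!is.null(cfg$out_dir)) write_outputs(out, cfg)
  out
}

#' @noRd
annotation_columns <- function() {
  data.frame(description = character(0), ss_string = character(0),
             ss_category = character(0), avg_sasa = numeric(0),
             n_contacts = integer(0), avg_hydropathy = numeric(0),
             ligand = logical(0), metal = logical(0),
             site_or_catalytic = logical(0), disulphide = logical(0),
             classification = character(0), stringsAsFactors = FALSE)
}

#' @noRd
chain_description <- function(model, chain_id) {
  for (cmp in model$compound) {
    if (chain_id %in% cmp$chains && nzchar(cmp$molecule)) {
      return(cmp$molecule)
    }
  }
  model$title
}

# Structural annotation of one chain's filtered hits.
#' @noRd
annotate_hits <- function(hits, model, cs, ss_codes, profile, cat_list,
                          cfg) {
  n <- nrow(hits)
  hits$description <- chain_description(model, cs$chain_id)
  hits$ss_string <- vapply(seq_len(n), function(i)
    hit_ss_string(hits[i, ], ss_codes), character(1))
  hits$ss_category <- vapply(seq_len(n), function(i) {
    if (grepl("-", hits$ss_string[i], fixed = TRUE)) "irregular"
    else ss_category(hits$ss_string[i], cfg$rule)
  }, character(1))
  hits$avg_sasa <- vapply(seq_len(n), function(i)
    average_sasa(hits[i, ], profile), numeric(1))
  hits$n_contacts <- vapply(seq_len(n), function(i)
    count_contacts(model, hits[i, ],
                   cutoff = cfg$contact_cutoff)$n_contact_residues,
    integer(1))
  hits$avg_hydropathy <- vapply(hits$sequence, average_hydrophobicity,
                                numeric(1), USE.NAMES = FALSE)
  flags <- lapply(seq_len(n), function(i)
    functional_interactions(model, hits[i, ], catalytic_list = cat_list,
                            cutoff = cfg$interaction_cutoff))
  hits$ligand <- vapply(flags, `[[`, logical(1), "ligand")
  hits$metal <- vapply(flags, `[[`, logical(1), "metal")
  hits$site_or_catalytic <- vapply(flags, `[[`, logical(1),
                                   "site_or_catalytic")
  hits$disulphide <- vapply(flags, `[[`, logical(1), "disulphide")
  hits$classification <- model$classification
  hits
}

#' @noRd
add_mode_flags <- function(hits) {
  hits$is_nested <- FALSE; hits$has_overlap <- FALSE
  hits$is_consecutive <- FALSE; hits$is_repeated <- FALSE
  if (!nrow(hits)) return(hits)
  for (key in unique(paste(hits$pdb_id, hits$chain_id))) {
    rows <- which(paste(hits$pdb_id, hits$chain_id) == key)
    rows <- rows[order(hits$start_index[rows])]
    sub <- detect_modes(hits[rows, , drop = FALSE])
    hits$is_nested[rows] <- !is.na(sub$nested_in)
    hits$has_overlap[rows] <- nzchar(sub$overlaps)
    hits$is_consecutive[rows] <- nzchar(sub$consecutive_with)
    hits$is_repeated[rows] <- !is.na(sub$repeat_group)
  }
  hits
}

# Sample matched controls and annotate them with SS category and SASA.
#' @noRd
annotate_controls <- function(chains_all, hits, control_ctx, cfg) {
  if (!nrow(hits) || !length(chains_all)) {
    out <- empty_hits(); out$is_palindrome <- logical(0)
    out$ss_string <- character(0); out$ss_category <- character(0)
    out$avg_sasa <- numeric(0)
    return(out)
  }
  controls <- sample_control_windows(unname(chains_all), hits, cfg$scan)
  controls$ss_string <- NA_character_
  controls$ss_category <- NA_character_
  controls$avg_sasa <- NA_real_
  for (i in seq_len(nrow(controls))) {
    ctx <- control_ctx[[controls$pdb_id[i]]]
    if (is.null(ctx)) next
    cs <- chains_all[[paste(controls$pdb_id[i], controls$chain_id[i])]]
    ss_codes <- if (is.null(ctx$dssp)) {
      ctx$ss_all$ss[ctx$ss_all$chain == controls$chain_id[i]]
    } else dssp_codes_for_chain(ctx$dssp, cs)
    controls$ss_string[i] <- hit_ss_string(controls[i, ], ss_codes)
    if (!grepl("-", controls$ss_string[i], fixed = TRUE)) {
      controls$ss_category[i] <- ss_category(controls$ss_string[i],
                                             cfg$rule)
    }
    controls$avg_sasa[i] <- average_sasa(controls[i, ], ctx$profile)
  }
  controls
}

#' @noRd
summarize_survey <- function(hits, controls) {
  cat_levels <- c("helix", "strand", "coil", "irregular")
  cat_table <- function(x) {
    tab <- table(factor(x, levels = cat_levels))
    data.frame(category = cat_levels, n = as.integer(tab),
               fraction = if (sum(tab)) as.numeric(tab) / sum(tab) else
                 rep(0, 4), stringsAsFactors = FALSE)
  }
  len_hist <- function(d) {
    if (!nrow(d)) return(data.frame(length = integer(0), n = integer(0)))
    tab <- table(d$length)
    data.frame(length = as.integer(names(tab)), n = as.integer(tab))
  }
  sasa_range <- function(d) {
    if (!nrow(d) || all(is.na(d$avg_sasa))) {
      return(data.frame(length = integer(0), min_sasa = numeric(0),
                        max_sasa = numeric(0)))
    }
    agg <- stats::aggregate(list(min_sasa = d$avg_sasa,
                                 max_sasa = d$avg_sasa),
                            by = list(length = d$length),
                            FUN = function(x) x[1])
    agg$min_sasa <- vapply(agg$length, function(L)
      min(d$avg_sasa[d$length == L], na.rm = TRUE), numeric(1))
    agg$max_sasa <- vapply(agg$length, function(L)
      max(d$avg_sasa[d$length == L], na.rm = TRUE), numeric(1))
    agg
  }
  hydro <- if (nrow(hits)) hits$avg_hydropathy else numeric(0)
  breaks <- seq(-4.5, 4.5, by = 0.5)
  hyd_hist <- if (length(hydro)) {
    h <- graphics::hist(hydro, breaks = breaks, plot = FALSE)
    data.frame(bin_low = h$breaks[-length(h$breaks)],
               bin_high = h$breaks[-1], n = h$counts)
  } else data.frame(bin_low = numeric(0), bin_high = numeric(0),
                    n = integer(0))
  list(
    length_histogram = len_hist(hits),
    ss_composition_hits = cat_table(if (nrow(hits)) hits$ss_category else
      character(0)),
    ss_composition_controls = cat_table(
      controls$ss_category[!is.na(controls$ss_category)]),
    sasa_range_hits = sasa_range(hits),
    sasa_range_controls = sasa_range(controls),
    hydropathy_distribution = hyd_hist,
    n_hydropathy_negative = sum(hydro < 0),
    n_hydropathy_positive = sum(hydro > 0),
    unique_sequences = unique_sequences(hits),
    family_distribution = family_distribution(hits),
    chameleons = if (nrow(hits)) find_chameleons(hits) else NULL)
}

#' @noRd
write_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) {
    if (!is.null(d) && nrow(d)) {
      utils::write.table(d, file.path(cfg$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  w(out$hits, "hits.tsv")
  w(out$controls, "controls.tsv")
  w(out$excluded, "excluded.tsv")
  w(out$summary$length_histogram, "length_histogram.tsv")
  w(out$summary$ss_composition_hits, "ss_composition_hits.tsv")
  w(out$summary$ss_composition_controls, "ss_composition_controls.tsv")
  w(out$summary$sasa_range_hits, "sasa_range_hits.tsv")
  w(out$summary$sasa_range_controls, "sasa_range_controls.tsv")
  w(out$summary$hydropathy_distribution, "hydropathy_distribution.tsv")
  w(out$summary$unique_sequences$multiplicity, "unique_sequences.tsv")
  w(out$summary$family_distribution, "family_distribution.tsv")
  w(out$summary$chameleons, "chameleons.tsv")
  if (nrow(out$hits)) {
    export_logo_groups(out$hits, file.path(cfg$out_dir, "logo_groups"))
  }
  if (length(out$failures)) {
    writeLines(paste(names(out$failures), unlist(out$failures), sep = "\t"),
               file.path(cfg$out_dir, "failures.tsv"))
  }
  invisible(NULL)
}
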