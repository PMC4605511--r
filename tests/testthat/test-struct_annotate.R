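# Secondary-structure assignment, SASA, contacts, interaction flags.

test_that("ideal helix interior is assigned 'H' and matches reference DSSP", {
  m <- helix_model(12)
  ss <- assign_secondary_structure(m, "A")
  interior <- ss[2:11]
  expect_gte(mean(interior == "H"), 0.9)

  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  ref <- strsplit(mdtraj_dssp(path), "")[[1]]
  expect_equal(length(ref), 12L)
  core <- which(ref == "H")
  expect_gt(length(core), 0)
  expect_true(all(ss[core] == "H"))           # helix core exact
  expect_gte(mean(ss == ref), 0.9)
})

test_that("antiparallel sheet strand cores are 'E' and match reference DSSP", {
  m <- sheet_model()
  ssA <- assign_secondary_structure(m, "A")
  ssB <- assign_secondary_structure(m, "B")
  expect_true(all(ssA[3:6] == "E"))
  expect_true(all(ssB[3:6] == "E"))

  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  ref <- strsplit(mdtraj_dssp(path), "")[[1]]
  mine <- c(ssA, ssB)
  core <- which(ref == "E")
  expect_gt(length(core), 0)
  expect_true(all(mine[core] == "E"))         # strand core exact
  expect_gte(mean(mine == ref), 0.9)
})

test_that("short chains get no regular structure and DSSP files take precedence", {
  m <- build_ideal_peptide("GA", "helix")
  expect_true(all(assign_secondary_structure(m, "A") %in% c("C", "-")))

  m12 <- helix_model(12)
  dssp <- data.frame(chain = "A", resno = 1:12, icode = "",
                     aa = rep("A", 12), ss = rep("E", 12),
                     stringsAsFactors = FALSE)
  expect_equal(assign_secondary_structure(m12, "A", dssp = dssp),
               rep("E", 12))
})

test_that("lone-atom SASA matches the analytic sphere and burial gives zero", {
  at <- data.frame(record = "HETATM", serial = 1L, name = "C1",
                   altloc = "", resname = "UNL", chain = "A", resno = 1L,
                   icode = "", x = 0, y = 0, z = 0, occ = 1, b = 0,
                   element = "C", is_hetero = TRUE,
                   stringsAsFactors = FALSE)
  m <- propalin:::new_structure_model(at)
  p <- shrake_rupley_sasa(m)
  expect_lt(abs(p$sasa - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)

  # cage the atom inside a dense shell of dummy atoms
  pts <- propalin:::sphere_points(200) * 2.5
  cage <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    d <- at; d$serial <- i + 1L; d$resno <- 2L; d$name <- paste0("C", i)
    d$x <- pts[i, 1]; d$y <- pts[i, 2]; d$z <- pts[i, 3]; d
  }))
  m2 <- propalin:::new_structure_model(rbind(at, cage))
  p2 <- shrake_rupley_sasa(m2)
  expect_equal(p2$sasa[p2$resno == 1], 0)
})

test_that("total SASA is rotation-invariant and converges with n_points", {
  m <- helix_model(8)
  p1 <- shrake_rupley_sasa(m, n_points = 960)
  R <- propalin:::rotation_about_axis(c(1, 1, 0), 35)
  m2 <- transform_model(m, R, c(5, -3, 2))
  p2 <- shrake_rupley_sasa(m2, n_points = 960)
  expect_lt(abs(sum(p1$sasa) - sum(p2$sasa)) / sum(p1$sasa), 0.001)

  p4 <- shrake_rupley_sasa(m, n_points = 3840)
  expect_lt(abs(sum(p1$sasa) - sum(p4$sasa)) / sum(p4$sasa), 0.01)
})

test_that("average_sasa is the arithmetic mean and errors on missing residues", {
  profile <- data.frame(chain = "A", resno = 1:5, icode = "",
                        resname = "ALA", sasa = c(10, 0, 0, 0, 0))
  hit <- data.frame(pdb_id = "T", chain_id = "A", start_index = 0L,
                    end_index = 5L, length = 5L, sequence = "AAAAA",
                    start_resno = 1L, start_icode = "", end_resno = 5L,
                    end_icode = "")
  expect_equal(average_sasa(hit, profile), 2.0)
  profile$sasa <- 0
  expect_equal(average_sasa(hit, profile), 0)
  hit$chain_id <- "B"
  expect_error(average_sasa(hit, profile), "cover")
})

test_that("contacts follow the counted-once rule at the cutoff", {
  # hand-placed fixture: hit = 5 CA-only residues along x at 3.8 A
  # spacing; decoy residues hover above residue 3 at exact distances
  mk_atom <- function(serial, name, resname, chain, resno, xyz,
                      element = "C") {
    data.frame(record = "ATOM", serial = serial, name = name, altloc = "",
               resname = resname, chain = chain, resno = resno,
               icode = "", x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
               b = 0, element = element, is_hetero = FALSE,
               stringsAsFactors = FALSE)
  }
  resnames <- c("ALA", "LEU", "ALA", "LEU", "ALA")
  rows <- lapply(1:5, function(i)
    mk_atom(i, "CA", resnames[i], "A", i, c((i - 1) * 3.8, 0, 0)))
  rows[[6]] <- mk_atom(6L, "CA", "GLY", "B", 101L, c(7.6, 0, 2.9))
  rows[[7]] <- mk_atom(7L, "N", "GLY", "B", 101L, c(7.6, 0, 3.1), "N")
  rows[[8]] <- mk_atom(8L, "CA", "GLY", "B", 102L, c(7.6, 0, 3.5))
  rows[[9]] <- mk_atom(9L, "N", "GLY", "B", 102L, c(7.6, 0, 4.0), "N")
  m <- propalin:::new_structure_model(do.call(rbind, rows))
  hit <- enumerate_palindromes(chain_sequence(m, "A"),
                               scan_config(require_complete = FALSE))[1, ]
  expect_equal(hit$sequence, "ALALA")
  res <- count_contacts(m, hit, cutoff = 3.2)
  # residue 101 has atoms at 2.9 and 3.1 -> counts once, not twice;
  # residue 102 at 3.5 -> not counted
  expect_equal(res$n_contact_residues, 1L)
  expect_equal(res$contacts$resno, 101L)
  # monotone in cutoff: at 3.6 the second residue joins
  expect_equal(count_contacts(m, hit, cutoff = 3.6)$n_contact_residues, 2L)
  # removing all non-hit residues yields zero
  only_hit <- propalin:::new_structure_model(do.call(rbind, rows[1:5]))
  hit0 <- enumerate_palindromes(chain_sequence(only_hit, "A"),
                                scan_config(require_complete = FALSE))[1, ]
  expect_equal(count_contacts(only_hit, hit0)$n_contact_residues, 0L)
})

test_that("functional interaction flags detect metals, ligands, sites and disulphides", {
  m <- build_ideal_peptide("AGAGA", "helix")
  hit <- enumerate_palindromes(chain_sequence(m, "A"), scan_config())[1, ]
  f0 <- functional_interactions(m, hit)
  expect_false(any(unlist(f0[c("ligand", "metal", "site_or_catalytic",
                               "disulphide")])))

  ca3 <- unlist(m$atoms[m$atoms$name == "CA" & m$atoms$rid == 3,
                        c("x", "y", "z")])
  mz <- add_het_atom(m, "ZN", ca3 + c(0, 0, 2.1))
  expect_true(functional_interactions(mz, hit)$metal)
  expect_false(functional_interactions(mz, hit)$ligand)

  ml <- add_het_atom(m, "C", ca3 + c(0, 0, 3.0), resname = "LIG",
                     name = "C1")
  expect_true(functional_interactions(ml, hit)$ligand)

  msite <- m
  msite$site_records <- data.frame(site = "AC1", resname = "GLY",
                                   chain = "A", resno = 2L, icode = "",
                                   stringsAsFactors = FALSE)
  expect_true(functional_interactions(msite, hit)$site_or_catalytic)
  expect_warning(
    functional_interactions(m, hit,
                            catalytic_list = data.frame(chain = "A",
                                                        resno = 99L,
                                                        icode = "")),
    "not found")

  # two CYS SG atoms at S-S bond distance, one inside the hit
  mc <- build_ideal_peptide("ACACA", "helix")
  sg1 <- unlist(mc$atoms[mc$atoms$name == "CB" & mc$atoms$rid == 2,
                         c("x", "y", "z")])
  add_sg <- function(model, rid_resno, chain, xyz) {
    a <- model$atoms[1, ]
    a$serial <- max(model$atoms$serial) + 1L
    a$name <- "SG"; a$element <- "S"; a$resname <- "CYS"
    a$chain <- chain; a$resno <- rid_resno; a$record <- "ATOM"
    a$is_hetero <- FALSE
    a[, c("x", "y", "z")] <- xyz
    propalin:::new_structure_model(rbind(model$atoms, a),
                                   pdb_id = model$pdb_id)
  }
  mc2 <- add_sg(mc, 2L, "A", sg1 + c(0, 0, 1.0))
  mc2 <- add_sg(mc2, 50L, "B", sg1 + c(0, 0, 1.0) + c(2.05, 0, 0))
  hitc <- enumerate_palindromes(chain_sequence(mc2, "A"),
                                scan_config(require_complete = FALSE))[1, ]
  expect_true(functional_interactions(mc2, hitc)$disulphide)
})
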