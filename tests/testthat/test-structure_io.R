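# PDB / DSSP reading and chain-sequence derivation.

test_that("write_pdb / read_structure round-trips atoms, numbering and coordinates", {
  m <- build_ideal_peptide("ARGNDKW", "helix")
  m <- add_het_atom(m, "ZN", c(3.5, 1.2, -0.8))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  m2 <- read_structure(path)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(m2$atoms$resno, m$atoms$resno)
  expect_equal(m2$residues$resname, m$residues$resname)
  het <- m2$residues[m2$residues$is_hetero, ]
  expect_equal(nrow(het), 1L)
  expect_equal(m2$atoms$element[m2$atoms$is_hetero], "ZN")
})

test_that("a synthetic single-chain peptide reads back with the expected shape", {
  m <- build_ideal_peptide(strrep("A", 12), "helix")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  m2 <- read_structure(path)
  expect_equal(chain_ids(m2), "A")
  expect_equal(sum(!m2$residues$is_hetero), 12L)
  expect_equal(sum(m2$residues$is_hetero), 0L)
})

test_that("read_structure rejects missing files and structures without ATOM records", {
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    HYDROLASE", "END"), path)
  expect_error(read_structure(path), "no ATOM records")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.458   1.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  m <- read_structure(path)
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$y, 1.0)   # the occupancy-0.60 B conformer
})

test_that("chain_sequence maps residues to one letter and flags nonstandard/incomplete", {
  m <- build_ideal_peptide("ARG", "helix")   # ALA, ARG, GLY residues
  expect_equal(chain_sequence(m, "A")$sequence, "ARG")
  expect_error(chain_sequence(m, "Z"), "available")

  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.383   2.339   0.552  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "HETATM    6  N   MSE A   2       3.332   1.536  -0.690  1.00  0.00           N",
    "HETATM    7  CA  MSE A   2       4.008   2.803  -0.800  1.00  0.00           C",
    "ATOM      8  N   GLY A   3       5.332   2.536  -1.690  1.00  0.00           N",
    "ATOM      9  CA  GLY A   3       6.008   3.803  -1.800  1.00  0.00           C",
    "ATOM     10  C   GLY A   3       6.559   4.223  -2.800  1.00  0.00           C",
    "END"), path)
  m2 <- read_structure(path)
  cs <- chain_sequence(m2, "A")
  expect_equal(cs$sequence, "AXG")            # MSE -> X
  expect_equal(cs$complete, c(TRUE, FALSE, FALSE))  # MSE unknown, GLY lacks O
})

test_that("residue numbering with insertion codes survives the round trip", {
  m <- build_ideal_peptide("AAAA", "helix")
  m$atoms$resno[m$atoms$rid == 3] <- 2L
  m$atoms$icode[m$atoms$rid == 3] <- "A"
  m$residues$resno[3] <- 2L; m$residues$icode[3] <- "A"
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  m2 <- read_structure(path)
  expect_equal(m2$residues$resno, c(1L, 2L, 2L, 4L))
  expect_equal(m2$residues$icode, c("", "", "A", ""))
})

test_that("HEADER, REMARK 2 and SITE records are parsed; dangling sites reported", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HEADER    HYDROLASE                               01-JAN-00   1ABC",
    "REMARK   2 RESOLUTION.    1.74 ANGSTROMS.",
    "SITE     1 AC1  2 ALA A   1  GLY A  99",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(m$classification, "HYDROLASE")
  expect_equal(m$pdb_id, "1ABC")
  expect_equal(m$resolution, 1.74)
  expect_equal(nrow(m$site_records), 1L)     # ALA A 1 resolves
  expect_equal(nrow(m$dangling_sites), 1L)   # GLY A 99 does not
})

test_that("read_dssp round-trips a synthetic fixture and applies the code policy", {
  df <- data.frame(chain = "A", resno = 1:6, icode = "",
                   aa = strsplit("AGAGAG", "")[[1]],
                   ss = c("H", "H", "C", "E", "T", "S"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".dssp")
  write_dssp_fixture(df, path)
  back <- read_dssp(path)
  expect_equal(back[, c("chain", "resno", "icode", "aa", "ss")], df)

  # blank structure column -> 'C' is exercised by the fixture writer;
  # residues absent from DSSP -> '-'
  cs <- make_chain("AGAGAGAA", resno = 1:8)
  codes <- dssp_codes_for_chain(back, cs)
  expect_equal(codes, c("H", "H", "C", "E", "T", "S", "-", "-"))
  bad <- withr::local_tempfile()
  writeLines("not a dssp file", bad)
  expect_error(read_dssp(bad), "malformed")
})

test_that("chain-break rows in DSSP output are skipped", {
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H",
    "    2        !       ",
    "    3    5 A G  E"), path)
  d <- read_dssp(path)
  expect_equal(nrow(d), 2L)
  expect_equal(d$resno, c(1L, 5L))
})
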