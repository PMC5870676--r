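## hand-written five-residue chain plus one NAG and one water
make_basic_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HEADER    TEST ENTRY                              01-JAN-20   1ABC",
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  OG  SER A   1       2.000  -1.200   0.500  1.00 10.00           O",
    "HETATM    4  CA  SEP A   2       5.258   0.000   0.000  1.00 10.00           C",
    "HETATM    5  P   SEP A   2       6.000  -2.000   0.500  1.00 10.00           P",
    "ATOM      6  CA  GLY A   3       9.058   0.000   0.000  1.00 10.00           C",
    "ATOM      7  CA  ALA A   4      12.858   0.000   0.000  1.00 10.00           C",
    "ATOM      8  CA  GLY A   5      16.658   0.000   0.000  1.00 10.00           C",
    "HETATM    9  C1  NAG A 101      25.000   0.000   0.000  1.00 10.00           C",
    "HETATM   10  O5  NAG A 101      26.000   1.000   0.000  1.00 10.00           O",
    "HETATM   11  O   HOH A 201      40.000  40.000  40.000  1.00 10.00           O",
    "END"), path)
  path
}

test_that("PDB parsing separates polymer chains from non-polymer groups and drops water", {
  m <- parse_structure(make_basic_pdb())
  expect_s3_class(m, "structure_model")
  expect_equal(m$entry_id, "1ABC")
  expect_equal(m$source_format, "pdb")
  expect_equal(sum(m$residues$is_polymer), 5)
  expect_equal(sum(!m$residues$is_polymer), 1)   # the NAG; water excluded
  expect_false(any(m$atoms$code == "HOH"))
  ## the HETATM SEP inside the chain numbering is a polymer residue
  sep <- m$residues[m$residues$code == "SEP", ]
  expect_true(sep$is_polymer)
  expect_equal(sep$polymer_index, 1L)
  ## the NAG is not, and carries no polymer index
  nag <- m$residues[m$residues$code == "NAG", ]
  expect_false(nag$is_polymer)
  expect_true(is.na(nag$polymer_index))
})

test_that("polymer_sequence returns codes in polymer order and errors on unknown chains", {
  m <- parse_structure(make_basic_pdb())
  expect_equal(polymer_sequence(m, "A"), c("SER", "SEP", "GLY", "ALA", "GLY"))
  expect_error(polymer_sequence(m, "Z"), "no polymer chain")
  expect_error(polymer_sequence(m, ""), "no polymer chain")
})

test_that("insertion codes order residues by file position", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A  52       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  ALA A  52A      3.800   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CA  SER A  53       7.600   0.000   0.000  1.00 10.00           C",
    "END"), path)
  m <- parse_structure(path)
  expect_equal(polymer_sequence(m, "A"), c("GLY", "ALA", "SER"))
  expect_equal(nrow(m$residues), 3)
  expect_setequal(m$residues$res_uid, c("A:52", "A:52A", "A:53"))
})

test_that("a nonstandard residue outside the chain numbering stays non-polymer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00 10.00           C",
    "HETATM    3  CA  SEP A 300      30.000   0.000   0.000  1.00 10.00           C",
    "END"), path)
  m <- parse_structure(path)
  sep <- m$residues[m$residues$code == "SEP", ]
  expect_false(sep$is_polymer)
})

test_that("PDB and mmCIF renderings of one fixture parse to equivalent models", {
  spec <- fixture_spec(7L, chains = list(A = rep("GLY", 10)),
    planted = list(list(def = "disulfide", chain = "A", positions = c(2, 4),
                        distance = 2.05),
                   list(def = "phosphothreonine", chain = "A", positions = 7)))
  fx <- make_fixture(spec)
  mp <- parse_structure(fx$pdb)
  mc <- parse_structure(fx$cif)
  expect_equal(mc$source_format, "mmcif")
  key <- function(m) {
    at <- m$atoms[order(m$atoms$res_uid, m$atoms$name),
                  c("res_uid", "code", "chain", "seq_id", "name", "element",
                    "x", "y", "z", "is_polymer")]
    rownames(at) <- NULL
    at
  }
  expect_equal(key(mp), key(mc), tolerance = 1e-9)
  expect_equal(mp$entry_id, mc$entry_id)
})

test_that("parsing is deterministic", {
  p <- make_basic_pdb()
  expect_identical(parse_structure(p), parse_structure(p))
})

test_that("multi-model files contribute one selectable model", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1      10.000   0.000   0.000  1.00 10.00           C",
    "ENDMDL",
    "END"), path)
  m1 <- parse_structure(path, model = 1)
  m2 <- parse_structure(path, model = 2)
  expect_equal(m1$atoms$x, 0)
  expect_equal(m2$atoms$x, 10)
  expect_equal(m2$model_number, 2L)
  expect_error(parse_structure(path, model = 3), "model")
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  N  AGLY A   1       1.000   0.000   0.000  0.50 10.00           N",
    "ATOM      4  N  BGLY A   1       6.000   0.000   0.000  0.50 10.00           N",
    "END"), path)
  m <- parse_structure(path)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 5)   # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$name == "N"], 1)    # tie -> altloc A
})

test_that("unreadable input raises a parse or format error", {
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("this is", "not a structure"), bad)
  expect_error(parse_structure(bad))
  expect_error(parse_structure(tempfile(fileext = ".pdb")), "not found")
})
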