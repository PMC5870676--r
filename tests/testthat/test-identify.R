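## extended-chain model helper built from residue codes only
chain_model <- function(codes, chain = "A") {
  tpl <- modfinder:::.aa_templates()
  atoms <- do.call(rbind, lapply(seq_along(codes), function(i) {
    t <- tpl[[codes[i]]]
    helper_atom(ifelse(codes[i] %in% modfinder:::CANONICAL_AA, "ATOM", "HETATM"),
                t$name, t$element, codes[i], chain, i,
                3.8 * (i - 1) + t$dx, t$dy, t$dz)
  }))
  helper_structure(atoms)
}

test_that("modified residues are identified by code comparison along the sequence", {
  m <- chain_model(c("SER", "SEP", "GLY", "TPO"))
  ids <- identify_modified_residues(m)
  expect_length(ids, 2)
  expect_equal(vapply(ids, function(i) i$def_id, character(1)),
               c("phosphoserine", "phosphothreonine"))
  expect_equal(vapply(ids, function(i) i$residues$polymer_index, integer(1)),
               c(1L, 3L))
  expect_true(all(vapply(ids, function(i) nrow(i$bonds) == 0, logical(1))))

  ## all-canonical chain yields nothing
  m20 <- chain_model(modfinder:::CANONICAL_AA)
  expect_length(identify_modified_residues(m20), 0)
})

test_that("a nonstandard component outside any chain is not a modified residue", {
  atoms <- rbind(
    helper_atom("ATOM", "CA", "C", "GLY", "A", 1, 0, 0, 0),
    helper_atom("ATOM", "CA", "C", "GLY", "A", 2, 3.8, 0, 0),
    helper_atom("HETATM", "P", "P", "SEP", "A", 300, 40, 0, 0))
  m <- helper_structure(atoms)
  expect_length(identify_modified_residues(m), 0)
})

test_that("terminal-restricted definitions match only chain termini", {
  ## PCA is restricted to the N-terminus in the starter dictionary
  m_first <- chain_model(c("PCA", "GLY", "ALA"))
  expect_length(identify_modified_residues(m_first), 1)
  m_mid <- chain_model(c("GLY", "PCA", "ALA"))
  expect_length(identify_modified_residues(m_mid), 0)
})

test_that("attachments require the listed atom pair at bonding distance", {
  glyco <- function(d) {
    atoms <- rbind(
      helper_atom("ATOM", "CA", "C", "ASN", "A", 1, 0, 0, 0),
      helper_atom("ATOM", "ND2", "N", "ASN", "A", 1, 0, -3, 0),
      helper_atom("HETATM", "C1", "C", "NAG", "A", 101, 0, -3 - d, 0),
      helper_atom("HETATM", "O5", "O", "NAG", "A", 101, 0.7, -1.8 - d, 0))
    helper_structure(atoms)
  }
  ids <- identify_attachments(glyco(1.43))
  expect_length(ids, 1)
  expect_equal(ids[[1]]$def_id, "n-glycosyl-asparagine")
  expect_equal(ids[[1]]$bonds$distance, 1.43, tolerance = 1e-6)
  expect_equal(sort(ids[[1]]$residues$code), c("ASN", "NAG"))
  ## well beyond any N+C threshold
  expect_length(identify_attachments(glyco(3.2)), 0)
})

test_that("a metal ion coordinated by several residues yields one record per bonded pair", {
  atoms <- rbind(
    helper_atom("ATOM", "CA", "C", "HIS", "A", 1, 10, 10, 0),
    helper_atom("ATOM", "NE2", "N", "HIS", "A", 1, 2.0, 0, 0),
    helper_atom("ATOM", "CA", "C", "HIS", "A", 2, -10, 10, 0),
    helper_atom("ATOM", "NE2", "N", "HIS", "A", 2, -2.0, 0, 0),
    helper_atom("ATOM", "CA", "C", "CYS", "A", 3, 10, -10, 5),
    helper_atom("ATOM", "SG", "S", "CYS", "A", 3, 0, 2.2, 0),
    helper_atom("ATOM", "CA", "C", "CYS", "A", 4, -10, -10, 5),
    helper_atom("ATOM", "SG", "S", "CYS", "A", 4, 0, -2.2, 0),
    helper_atom("HETATM", "ZN", "ZN", "ZN", "A", 201, 0, 0, 0))
  m <- helper_structure(atoms)
  ids <- identify_attachments(m)
  expect_length(ids, 4)
  defs <- table(vapply(ids, function(i) i$def_id, character(1)))
  expect_equal(defs[["zinc-histidine"]], 2L)
  expect_equal(defs[["zinc-cysteine"]], 2L)
  ## all four share the single zinc group
  zn_uids <- vapply(ids, function(i)
    i$residues$res_uid[!i$residues$is_polymer], character(1))
  expect_equal(unique(zn_uids), "A:201")
})

test_that("cross-links match all involved residues without double counting", {
  disulf <- function(sg_xy) {
    n <- nrow(sg_xy)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) rbind(
      helper_atom("ATOM", "CA", "C", "CYS", "A", i, 10 * i, 20, 0),
      helper_atom("ATOM", "SG", "S", "CYS", "A", i,
                  sg_xy[i, 1], sg_xy[i, 2], 0))))
    helper_structure(atoms)
  }
  ## single pair at 2.05 A
  ids <- identify_crosslinks(disulf(rbind(c(0, 0), c(2.05, 0))))
  expect_length(ids, 1)
  expect_equal(ids[[1]]$def_id, "disulfide")
  expect_equal(nrow(ids[[1]]$residues), 2)
  expect_equal(nrow(ids[[1]]$bonds), 1)

  ## A-B 2.05, B-C 2.05, A-C 3.9: exactly (A,B) and (B,C)
  ids3 <- identify_crosslinks(
    disulf(rbind(c(0, 0), c(2.05, 0), c(3.7098, 1.2034))))
  expect_length(ids3, 2)
  sets <- sort(vapply(ids3, function(i)
    paste(sort(i$residues$res_uid), collapse = ";"), character(1)))
  expect_equal(sets, c("A:1;A:2", "A:2;A:3"))
})

test_that("isopeptide bonds are matched by their definition's atom pair", {
  atoms <- rbind(
    helper_atom("ATOM", "CA", "C", "LYS", "A", 1, 0, 10, 0),
    helper_atom("ATOM", "NZ", "N", "LYS", "A", 1, 0, 0, 0),
    helper_atom("ATOM", "CA", "C", "ASN", "A", 2, 10, 10, 0),
    helper_atom("ATOM", "CG", "C", "ASN", "A", 2, 1.33, 0, 0))
  ids <- identify_crosslinks(helper_structure(atoms))
  expect_length(ids, 1)
  expect_equal(ids[[1]]$def_id, "isopeptide-lys-asn")
  expect_equal(ids[[1]]$bonds$distance, 1.33, tolerance = 1e-6)
})

test_that("the cross-link matcher agrees with exhaustive assignment enumeration", {
  cfg <- scan_config()
  set.seed(31)
  for (rep in 1:8) {
    ## random CYS arrangement: some SG pairs bonded, some not
    n <- sample(4:7, 1)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) rbind(
      helper_atom("ATOM", "CA", "C", "CYS", "A", i, 8 * i, 30, 0),
      helper_atom("ATOM", "SG", "S", "CYS", "A", i,
                  round(runif(1, 0, 7), 3), round(runif(1, 0, 7), 3), 0))))
    m <- helper_structure(atoms)
    got <- sort(vapply(identify_crosslinks(m, cfg), function(i)
      paste(sort(i$residues$res_uid), collapse = ";"), character(1)))
    want <- helper_crosslink_oracle(m, cfg$dictionary$definitions[["disulfide"]],
                                    cfg)
    expect_equal(got, want, label = sprintf("rep %d", rep))
  }
})

test_that("identify_all unions the category scans and honours the category filter", {
  spec <- fixture_spec(21L, chains = list(A = rep("GLY", 12)),
    planted = list(
      list(def = "phosphoserine", chain = "A", positions = 2),
      list(def = "disulfide", chain = "A", positions = c(5, 7), distance = 2.05),
      list(def = "n-glycosyl-asparagine", chain = "A", positions = 10,
           distance = 1.43)))
  fx <- make_fixture(spec)
  m <- parse_structure(fx$pdb)

  rep_all <- identify_all(m)
  expect_equal(helper_report_key(rep_all), helper_truth_key(fx$truth))
  cats <- vapply(rep_all$identifications, function(i) i$category, character(1))
  expect_setequal(unique(cats), modfinder:::MOD_CATEGORIES)

  only_xl <- identify_all(m, scan_config(categories = "cross-link"))
  expect_length(only_xl$identifications, 1)
  expect_equal(only_xl$identifications[[1]]$def_id, "disulfide")

  empty <- identify_all(helper_structure(
    helper_atom("ATOM", "CA", "C", "GLY", "A", 1, 0, 0, 0)))
  expect_length(empty$identifications, 0)
})

test_that("no two records share a definition and residue set", {
  for (seed in c(3, 14, 27)) {
    fx <- make_fixture(random_fixture_spec(seed))
    rep <- identify_all(parse_structure(fx$pdb))
    keys <- vapply(rep$identifications, function(i)
      paste(i$def_id, paste(sort(i$residues$res_uid), collapse = ";")),
      character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("raising the tolerance never removes an identification", {
  fx <- make_fixture(random_fixture_spec(8))
  m <- parse_structure(fx$pdb)
  prev <- NULL
  for (tol in c(0, 0.2, 0.4, 0.6)) {
    cfg <- scan_config(bond_config = bond_config(tolerance = tol))
    keys <- vapply(identify_all(m, cfg)$identifications, function(i)
      paste(i$def_id, paste(sort(i$residues$res_uid), collapse = ";")),
      character(1))
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("record order in the input file does not change the canonical report", {
  fx <- make_fixture(random_fixture_spec(12))
  base <- identify_all(parse_structure(fx$pdb))
  for (pseed in c(1, 2)) {
    shuffled <- perturb_fixture(fx, permutation_seed = pseed)
    got <- identify_all(parse_structure(shuffled$pdb))
    expect_equal(helper_report_key(got), helper_report_key(base))
  }
})
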