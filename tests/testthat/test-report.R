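composite_fixture <- function(seed = 77L) {
  make_fixture(fixture_spec(seed, chains = list(A = rep("GLY", 12)),
    planted = list(
      list(def = "phosphoserine", chain = "A", positions = 2),
      list(def = "disulfide", chain = "A", positions = c(5, 7), distance = 2.05),
      list(def = "n-glycosyl-asparagine", chain = "A", positions = 10,
           distance = 1.43))))
}

test_that("TSV export writes one row per identification residue", {
  fx <- composite_fixture()
  rep <- identify_all(parse_structure(fx$pdb))
  path <- tempfile(fileext = ".tsv")
  write_tsv(rep, path)
  df <- parse_tsv(path)
  ## 1 (SEP) + 2 (disulfide) + 2 (ASN + NAG partner) = 5 rows
  expect_equal(nrow(df), 5)
  expect_equal(names(df), modfinder:::TSV_COLUMNS)
  ## row count = sum of per-identification residue counts
  expect_equal(nrow(df), sum(vapply(rep$identifications, function(i)
    nrow(i$residues), integer(1))))
  ## modified residues carry no partner; bonded rows print the distance
  expect_equal(df$partner_description[df$component_code == "SEP"], "-")
  expect_match(df$partner_description[df$component_code == "ASN"], "ND2-C1 1\\.43")
  ## round-trip of the identifying tuple
  expect_equal(unique(df$entry_id), rep$entry_id)
  got <- df[, c("category", "internal_id", "chain", "seq_id")]
  want <- do.call(rbind, lapply(rep$identifications, function(i)
    data.frame(category = i$category, internal_id = i$def_id,
               chain = i$residues$chain, seq_id = i$residues$seq_id,
               stringsAsFactors = FALSE)))
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("an empty report writes a header-only TSV", {
  m <- helper_structure(helper_atom("ATOM", "CA", "C", "GLY", "A", 1, 0, 0, 0))
  rep <- identify_all(m)
  path <- tempfile(fileext = ".tsv")
  write_tsv(rep, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(parse_tsv(path)), 0L)
})

test_that("identical inputs produce byte-identical TSV output", {
  fx <- composite_fixture()
  p1 <- tempfile(); p2 <- tempfile()
  write_tsv(identify_all(parse_structure(fx$pdb)), p1)
  write_tsv(identify_all(parse_structure(fx$pdb)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("JSON mirror carries the identifications and bond geometry", {
  fx <- composite_fixture()
  rep <- identify_all(parse_structure(fx$pdb))
  path <- tempfile(fileext = ".json")
  write_json(rep, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(back$entry_id, rep$entry_id)
  expect_length(back$identifications, length(rep$identifications))
  expect_equal(back$scan_summary$tolerance, 0.4)
  xl <- Filter(function(i) i$category == "cross-link", back$identifications)[[1]]
  expect_equal(xl$bonds[[1]]$distance, 2.05, tolerance = 1e-6)
})

test_that("sequence tracks mark in-chain residues of each identification", {
  fx <- composite_fixture()
  m <- parse_structure(fx$pdb)
  rep <- identify_all(m)
  tr <- sequence_track(rep, m, "A")
  expect_equal(tr$length, 12)
  ## SEP mark (n=1), two disulfide marks (n=2), ASN mark (n=1)
  expect_equal(nrow(tr$marks), 4)
  ss <- tr$marks[tr$marks$def_id == "disulfide", ]
  expect_equal(nrow(ss), 2)
  expect_equal(unique(ss$identification), ss$identification[1])
  expect_equal(unique(ss$n_residues), 2L)
  expect_equal(tr$marks$n_residues[tr$marks$def_id == "phosphoserine"], 1L)
  expect_error(sequence_track(rep, m, "Z"), "no polymer chain")

  ## chain without modifications
  m0 <- helper_structure(helper_atom("ATOM", "CA", "C", "GLY", "B", 1, 0, 0, 0))
  tr0 <- sequence_track(identify_all(m0), m0, "B")
  expect_equal(nrow(tr0$marks), 0)
})

test_that("a multi-cysteine cluster site yields one mark per bonded pair", {
  fx <- make_fixture(fixture_spec(55L, chains = list(A = rep("GLY", 14)),
    planted = list(list(def = "4fe-4s-cysteine", chain = "A",
                        positions = c(2, 5, 8, 11), distance = 2.3))))
  m <- parse_structure(fx$pdb)
  rep <- identify_all(m)
  tr <- sequence_track(rep, m, "A")
  expect_equal(nrow(tr$marks), 4)
  expect_equal(length(unique(tr$marks$identification)), 4)  # 4 distinct records
  expect_equal(unique(tr$marks$n_residues), 1L)             # one CYS per record
})

test_that("batch scan writes per-entry reports and counts entries per definition", {
  out <- tempfile("batch")
  fixtures <- lapply(c(101L, 102L, 103L), function(s) composite_fixture(s))
  paths <- vapply(fixtures, function(f) f$pdb, character(1))

  corrupt <- tempfile(fileext = ".pdb")
  writeLines("garbage content", corrupt)

  suppressMessages(
    summ <- scan_batch(c(paths, corrupt), scan_config(), out_dir = out))
  expect_equal(summ$n_entries, 3)
  expect_equal(summ$n_failures, 1)
  expect_match(names(summ$failures), "\\.pdb")

  bd <- summ$by_definition
  expect_equal(bd$n_entries[bd$def_id == "disulfide"], 3)
  expect_equal(bd$n_entries[bd$def_id == "phosphoserine"], 3)
  expect_equal(bd$n_entries[bd$def_id == "zinc-histidine"], 0)
  expect_equal(summ$by_category$n_entries,
               c(3, 3, 3))  # all three categories present in each entry

  expect_length(list.files(out, pattern = "\\.tsv$"), 4)  # 3 entries + summary
  expect_length(list.files(out, pattern = "\\.json$"), 3)
  expect_error(scan_batch(character(0), scan_config(), out))
})
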