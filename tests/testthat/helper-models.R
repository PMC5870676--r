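## Build a structure model from an in-code atom table by writing a PDB file
## and parsing it back through the real reader.
helper_structure <- function(atoms, entry_id = "TST1", format = "pdb") {
  dir <- tempfile("helper")
  dir.create(dir)
  path <- file.path(dir, paste0("model.", if (format == "pdb") "pdb" else "cif"))
  if (format == "pdb")
    modfinder:::.write_fixture_pdb(atoms, entry_id, path)
  else
    modfinder:::.write_fixture_cif(atoms, entry_id, path)
  parse_structure(path)
}

helper_atom <- function(record, name, element, code, chain, seq, x, y, z) {
  data.frame(record = record, name = name, element = element, code = code,
             chain = chain, seq = seq, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

## Random atom cloud for close-pair oracle tests: n atoms in a box, each its
## own residue so no pair is excluded by the same-residue rule.
helper_random_cloud <- function(seed, n = 200, box = 18) {
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S", "P", "FE", "ZN"), n, replace = TRUE)
  helper_atom(record = "ATOM", name = paste0("X", seq_len(n) %% 10),
              element = elements, code = "GLY", chain = "A", seq = seq_len(n),
              x = round(runif(n, 0, box), 3), y = round(runif(n, 0, box), 3),
              z = round(runif(n, 0, box), 3))
}

## Brute-force all-pairs oracle for find_close_pairs: O(n^2) over the two
## selections, applying the distance criterion directly.
helper_brute_force_pairs <- function(model, cfg, group_a, group_b) {
  at <- model$atoms
  group_a <- group_a[!at$is_hydrogen[group_a]]
  group_b <- group_b[!at$is_hydrogen[group_b]]
  grid <- expand.grid(i = group_a, j = group_b)
  r <- function(el) {
    out <- cfg$radii$radius_by_element[el]
    out[is.na(out)] <- cfg$radii$default_radius
    unname(out)
  }
  d <- sqrt((at$x[grid$i] - at$x[grid$j])^2 + (at$y[grid$i] - at$y[grid$j])^2 +
            (at$z[grid$i] - at$z[grid$j])^2)
  thr <- r(at$element[grid$i]) + r(at$element[grid$j]) + cfg$tolerance
  ok <- d >= cfg$min_distance & d <= thr &
    at$res_uid[grid$i] != at$res_uid[grid$j]
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0L) return(data.frame(a = character(), b = character(),
                                          stringsAsFactors = FALSE))
  key <- function(i) paste(at$res_uid[i], at$name[i])
  a <- key(grid$i); b <- key(grid$j)
  swap <- b < a
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  uniq <- !duplicated(paste(a, b))
  out <- data.frame(a = a[uniq], b = b[uniq], stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

## Collapse a find_close_pairs result to the oracle's comparable form.
helper_pairs_key <- function(bonds) {
  if (nrow(bonds) == 0L) return(data.frame(a = character(), b = character(),
                                           stringsAsFactors = FALSE))
  a <- paste(bonds$res_uid1, bonds$atom1)
  b <- paste(bonds$res_uid2, bonds$atom2)
  swap <- b < a
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Exhaustive assignment enumeration oracle for two-component cross-links:
## tries every ordered residue pair and checks the linkage bond directly.
helper_crosslink_oracle <- function(model, def, cfg) {
  lk <- def$linkages[[1]]
  res <- model$residues[model$residues$is_polymer, , drop = FALSE]
  c1 <- res$res_uid[res$code %in% def$components[[lk$comp1]]$codes]
  c2 <- res$res_uid[res$code %in% def$components[[lk$comp2]]$codes]
  at <- model$atoms
  found <- character(0)
  for (u in c1) for (v in c2) {
    if (u == v) next
    ai <- which(at$res_uid == u & at$name %in% lk$atoms1)
    bi <- which(at$res_uid == v & at$name %in% lk$atoms2)
    hit <- FALSE
    for (i in ai) for (j in bi)
      if (is_bonded(at[i, ], at[j, ], cfg$bond_config)) hit <- TRUE
    if (hit) found <- c(found, paste(sort(c(u, v)), collapse = ";"))
  }
  sort(unique(found))
}

## Canonical comparable form of a report: def/category/residue-set tuples.
helper_report_key <- function(report) {
  df <- summary(report)
  df$residues <- vapply(strsplit(df$residues, ";", fixed = TRUE),
                        function(r) paste(sort(r), collapse = ";"),
                        character(1))
  df <- df[order(df$def_id, df$residues), c("def_id", "category", "residues")]
  rownames(df) <- NULL
  df
}

## Comparable form of a fixture truth table.
helper_truth_key <- function(truth) {
  df <- truth[order(truth$def_id, truth$residues),
              c("def_id", "category", "residues"), drop = FALSE]
  rownames(df) <- NULL
  df
}

## A random but valid dictionary definition, for round-trip property tests.
helper_random_definition <- function(id) {
  category <- sample(modfinder:::MOD_CATEGORIES, 1)
  rand_code <- function(n = 1) vapply(seq_len(n), function(i)
    paste(sample(c(LETTERS, 0:9), sample(1:3, 1), replace = TRUE),
          collapse = ""), character(1))
  rand_atoms <- function() toupper(vapply(seq_len(sample(1:3, 1)), function(i)
    paste(sample(LETTERS, sample(1:4, 1), replace = TRUE), collapse = ""),
    character(1)))
  opt <- function(value) if (runif(1) < 0.5) value else NA_character_
  if (category == "modified-residue") {
    comps <- list(mod_component(rand_code(sample(1:2, 1)), "amino-acid",
                                sample(c("any", "n", "c"), 1)))
    links <- list()
  } else if (category == "attachment") {
    comps <- list(mod_component(rand_code(), "amino-acid"),
                  mod_component(rand_code(sample(1:3, 1)), "non-polymer"))
    links <- list(mod_linkage(1, rand_atoms(), 2, rand_atoms()))
  } else {
    k <- sample(2:3, 1)
    comps <- lapply(seq_len(k), function(i) mod_component(rand_code(), "amino-acid"))
    links <- lapply(seq_len(k - 1L), function(i)
      mod_linkage(i, rand_atoms(), i + 1L, rand_atoms()))
  }
  mod_definition(internal_id = id, category = category, components = comps,
                 linkages = links, name = paste("definition", id),
                 psimod_id = opt(sprintf("MOD:%05d", sample(1e5, 1) - 1)),
                 resid_id = opt(sprintf("AA%04d", sample(1e4, 1) - 1)),
                 description = opt("a description"),
                 systematic_name = opt("a systematic name"),
                 keywords = if (runif(1) < 0.5) c("kw1", "kw2") else character())
}
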