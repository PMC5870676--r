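## Synthetic structure fixtures: extended-chain template geometry with
## linkage atoms placed at exact requested distances.  Only the distances
## the bond criterion consults are controlled; everything else is template
## placement, not physical stereochemistry.

CANONICAL_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

## Side-chain/backbone atom templates, offsets from CA in Angstrom.
.bb <- function() data.frame(
  name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
  dx = c(-1.2, 0, 1.2, 1.2), dy = c(0.6, 0, 0.6, 1.8), dz = 0,
  stringsAsFactors = FALSE)
.sc <- function(name, element, dx, dy, dz = 0)
  data.frame(name = name, element = element, dx = dx, dy = dy, dz = dz,
             stringsAsFactors = FALSE)

.aa_templates <- function() {
  b <- .bb()
  w <- function(...) rbind(b, ...)
  list(
    GLY = b,
    ALA = w(.sc("CB", "C", 0, -1.5)),
    VAL = w(.sc("CB", "C", 0, -1.5), .sc("CG1", "C", 0.9, -2.6),
            .sc("CG2", "C", -0.9, -2.6)),
    LEU = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD1", "C", 0.9, -4.0), .sc("CD2", "C", -0.9, -4.0)),
    ILE = w(.sc("CB", "C", 0, -1.5), .sc("CG1", "C", 0.9, -2.6),
            .sc("CG2", "C", -0.9, -2.6), .sc("CD1", "C", 0.9, -4.1)),
    PRO = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", -0.9, -2.4),
            .sc("CD", "C", -1.9, -1.4)),
    PHE = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CZ", "C", 0, -5.6)),
    TRP = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("NE1", "N", 1.1, -4.0)),
    MET = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("SD", "S", 0, -4.4), .sc("CE", "C", 0, -6.0)),
    SER = w(.sc("CB", "C", 0, -1.5), .sc("OG", "O", 0, -2.9)),
    THR = w(.sc("CB", "C", 0, -1.5), .sc("OG1", "O", 0.7, -2.6),
            .sc("CG2", "C", -0.9, -2.5)),
    CYS = w(.sc("CB", "C", 0, -1.5), .sc("SG", "S", 0, -3.0)),
    ASN = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("OD1", "O", 1.1, -3.5), .sc("ND2", "N", -1.1, -3.5)),
    GLN = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD", "C", 0, -4.3), .sc("OE1", "O", 1.1, -4.9),
            .sc("NE2", "N", -1.1, -4.9)),
    ASP = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("OD1", "O", 1.1, -3.5), .sc("OD2", "O", -1.1, -3.5)),
    GLU = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD", "C", 0, -4.3), .sc("OE1", "O", 1.1, -4.9),
            .sc("OE2", "O", -1.1, -4.9)),
    HIS = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("ND1", "N", 1.1, -3.6), .sc("CD2", "C", -1.1, -3.6),
            .sc("CE1", "C", 0.7, -4.8), .sc("NE2", "N", -0.6, -4.9)),
    LYS = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD", "C", 0, -4.3), .sc("CE", "C", 0, -5.7),
            .sc("NZ", "N", 0, -7.0)),
    ARG = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD", "C", 0, -4.3), .sc("NE", "N", 0, -5.7),
            .sc("CZ", "C", 0, -7.0), .sc("NH1", "N", 1.1, -7.7),
            .sc("NH2", "N", -1.1, -7.7)),
    TYR = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CZ", "C", 0, -5.6), .sc("OH", "O", 0, -7.0)),
    ## nonstandard (modified) residues
    SEP = w(.sc("CB", "C", 0, -1.5), .sc("OG", "O", 0, -2.9),
            .sc("P", "P", 0, -4.5), .sc("O1P", "O", 1.2, -5.3),
            .sc("O2P", "O", -1.2, -5.3), .sc("O3P", "O", 0, -5.9)),
    TPO = w(.sc("CB", "C", 0, -1.5), .sc("OG1", "O", 0.7, -2.6),
            .sc("CG2", "C", -0.9, -2.5), .sc("P", "P", 0.7, -4.2),
            .sc("O1P", "O", 1.9, -5.0), .sc("O2P", "O", -0.5, -5.0)),
    PTR = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CZ", "C", 0, -5.6), .sc("OH", "O", 0, -7.0),
            .sc("P", "P", 0, -8.6)),
    HYP = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", -0.9, -2.4),
            .sc("CD", "C", -1.9, -1.4), .sc("OD1", "O", -1.1, -3.6)),
    MSE = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("SE", "SE", 0, -4.5), .sc("CE", "C", 0, -6.2)),
    ALY = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD", "C", 0, -4.3), .sc("CE", "C", 0, -5.7),
            .sc("NZ", "N", 0, -7.0), .sc("CH", "C", 1.2, -7.7),
            .sc("OH", "O", 2.2, -7.1), .sc("CH3", "C", 1.2, -9.2)),
    MLY = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD", "C", 0, -4.3), .sc("CE", "C", 0, -5.7),
            .sc("NZ", "N", 0, -7.0), .sc("CM", "C", 1.2, -7.7)),
    CSO = w(.sc("CB", "C", 0, -1.5), .sc("SG", "S", 0, -3.0),
            .sc("OD", "O", 1.2, -3.8)),
    KCX = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", 0, -2.9),
            .sc("CD", "C", 0, -4.3), .sc("CE", "C", 0, -5.7),
            .sc("NZ", "N", 0, -7.0), .sc("CX", "C", 1.2, -7.7),
            .sc("OQ1", "O", 2.3, -7.1), .sc("OQ2", "O", 1.2, -9.0)),
    PCA = w(.sc("CB", "C", 0, -1.5), .sc("CG", "C", -0.9, -2.4),
            .sc("CD", "C", -1.9, -1.4), .sc("OE", "O", -3.1, -1.8)))
}

.np_templates <- function() {
  g <- function(name, element, dx, dy, dz = 0)
    data.frame(name = name, element = element, dx = dx, dy = dy, dz = dz,
               stringsAsFactors = FALSE)
  sugar <- rbind(g("C1", "C", 0, 0), g("C2", "C", 1.5, 0),
                 g("O5", "O", 0.7, 1.2))
  cube <- 2.7
  list(
    NAG = rbind(sugar, g("N2", "N", 1.9, -1.2)),
    NDG = rbind(sugar, g("N2", "N", 1.9, -1.2)),
    GAL = sugar, MAN = sugar, BGC = sugar,
    ZN = g("ZN", "ZN", 0, 0),
    SF4 = rbind(g("FE1", "FE", 0, 0, 0), g("FE2", "FE", cube, cube, 0),
                g("FE3", "FE", cube, 0, cube), g("FE4", "FE", 0, cube, cube),
                g("S1", "S", cube, 0, 0), g("S2", "S", 0, cube, 0),
                g("S3", "S", 0, 0, cube), g("S4", "S", cube, cube, cube)),
    F3S = rbind(g("FE1", "FE", 0, 0, 0), g("FE3", "FE", cube, 0, cube),
                g("FE4", "FE", 0, cube, cube),
                g("S1", "S", cube, 0, 0), g("S2", "S", 0, cube, 0),
                g("S3", "S", 0, 0, cube), g("S4", "S", cube, cube, cube)),
    FES = rbind(g("FE1", "FE", 0, 0, 0), g("FE2", "FE", 2.7, 0, 0),
                g("S1", "S", 1.35, 1.35, 0), g("S2", "S", 1.35, -1.35, 0)))
}

## bond threshold for the first candidate atom pair of a definition's
## first linkage, resolved through the fixture templates
.linkage_elements <- function(def) {
  aat <- .aa_templates(); npt <- .np_templates()
  elem_of <- function(code, atom) {
    t <- aat[[code]] %||% npt[[code]]
    if (is.null(t)) return(NA_character_)
    t$element[match(atom, t$name)]
  }
  lk <- def$linkages[[1]]
  c1 <- def$components[[lk$comp1]]$codes[1]
  c2 <- def$components[[lk$comp2]]$codes[1]
  c(elem_of(c1, lk$atoms1[1]), elem_of(c2, lk$atoms2[1]))
}

#' Bond threshold of a definition's first linkage
#'
#' Sum of covalent radii of the first candidate atom pair plus the
#' tolerance; the distance at which planted and decoy placements straddle
#' detection.
#'
#' @param def A [mod_definition()] with at least one linkage.
#' @param tolerance Tolerance in Angstrom.
#' @param radii A [covalent_radii()] table.
#' @return Threshold distance in Angstrom.
#' @export
linkage_threshold <- function(def, tolerance = 0.4,
                              radii = default_covalent_radii()) {
  el <- .linkage_elements(def)
  sum(.radii_for(el, radii)) + tolerance
}

#' Specify a synthetic fixture
#'
#' @param seed Integer seed; fixture generation is deterministic given the
#'   spec, and the seed also names the entry.
#' @param chains Named list (names = chain ids) of character vectors of
#'   component codes.
#' @param planted List of planted modifications, each a list with `def`
#'   (definition id in the starter dictionary), `chain`, `positions`
#'   (1-based residue positions; one per amino-acid residue involved) and,
#'   for attachments and cross-links, `distance` (Angstrom, below
#'   threshold).
#' @param decoys Number of near-miss placements at threshold + 0.2 A.
#' @param entry_id 4-character entry name (default derived from seed).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, chains, planted = list(), decoys = 0L,
                         entry_id = sprintf("F%03d", seed %% 1000L)) {
  structure(list(seed = as.integer(seed), chains = chains, planted = planted,
                 decoys = as.integer(decoys), entry_id = entry_id),
            class = "fixture_spec")
}

DECOY_CYCLE <- c("disulfide", "n-glycosyl-asparagine", "zinc-histidine")

#' Generate a synthetic structure fixture with known truth
#'
#' Builds extended polymer chains (CA spacing 3.8 A) from the spec, plants
#' each requested modification by placing its linkage atoms at the exact
#' requested distance in an isolated "lane" below the backbone, adds decoy
#' placements at threshold + 0.2 A, and emits byte-identical-per-spec PDB
#' and mmCIF renderings of the same coordinates together with the truth
#' table of planted identifications.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created; default a fresh temporary
#'   directory).
#' @param tolerance Bond tolerance the fixture is calibrated against.
#' @return List of class `mod_fixture`: `pdb`, `cif` (file paths), `truth`
#'   (data frame `def_id`, `category`, `residues` (sorted
#'   semicolon-joined residue uids), `n_bonds`), `atoms` (the emitted atom
#'   table) and `entry_id`.
#' @export
make_fixture <- function(spec, dir = tempfile("fixture"),
                         tolerance = 0.4) {
  stopifnot(inherits(spec, "fixture_spec"))
  dict <- default_dictionary()
  aat <- .aa_templates(); npt <- .np_templates()
  radii <- default_covalent_radii()

  chains <- spec$chains
  if (is.null(names(chains)) || any(!nzchar(names(chains))))
    stop("chains must be a named list")

  ## decoys become extra planted entries (flagged) on appended residues of
  ## the first chain
  planted <- lapply(spec$planted, function(p) { p$decoy <- FALSE; p })
  first_chain <- names(chains)[1]
  for (k in seq_len(spec$decoys)) {
    def_id <- DECOY_CYCLE[((k - 1L) %% length(DECOY_CYCLE)) + 1L]
    def <- dict$definitions[[def_id]]
    n_aa <- if (def$category == "cross-link") length(def$components) else 1L
    pos <- length(chains[[first_chain]]) + seq_len(n_aa)
    chains[[first_chain]] <- c(chains[[first_chain]],
                               rep("GLY", n_aa))
    planted[[length(planted) + 1L]] <-
      list(def = def_id, chain = first_chain, positions = pos,
           distance = linkage_threshold(def, tolerance, radii) + 0.2,
           decoy = TRUE)
  }

  ## apply code overrides required by planted modifications
  used <- character(0)
  for (p in planted) {
    def <- dict$definitions[[p$def]]
    if (is.null(def)) stop("unknown definition id: ", p$def)
    key <- paste(p$chain, p$positions)
    if (any(key %in% used))
      stop("planted modifications overlap on residue(s): ",
           paste(intersect(key, used), collapse = ", "))
    used <- c(used, key)
    aa_codes <- switch(def$category,
      "modified-residue" = def$components[[1]]$codes[1],
      "attachment" = rep(def$components[[
        which(vapply(def$components, function(cm) cm$role, character(1)) ==
              "amino-acid")[1]]]$codes[1], length(p$positions)),
      "cross-link" = vapply(def$components, function(cm) cm$codes[1],
                            character(1)))
    if (length(p$positions) != length(aa_codes))
      stop(sprintf("'%s' needs %d residue position(s), got %d", p$def,
                   length(aa_codes), length(p$positions)))
    if (any(p$positions < 1L | p$positions > length(chains[[p$chain]])))
      stop("planted position outside chain ", p$chain)
    chains[[p$chain]][p$positions] <- aa_codes
  }

  ## lay down template atoms
  atoms <- list()
  for (ci in seq_along(chains)) {
    ch <- names(chains)[ci]
    for (pos in seq_along(chains[[ci]])) {
      code <- chains[[ci]][pos]
      tpl <- aat[[code]]
      if (is.null(tpl)) stop("no atom template for residue code ", code)
      atoms[[length(atoms) + 1L]] <- data.frame(
        record = if (code %in% CANONICAL_AA) "ATOM" else "HETATM",
        name = tpl$name, element = tpl$element,
        code = code, chain = ch, seq = pos,
        x = 3.8 * (pos - 1L) + tpl$dx, y = tpl$dy,
        z = 25 * (ci - 1L) + tpl$dz,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atoms)

  move_atom <- function(chain, seq, name, xyz) {
    i <- which(atoms$chain == chain & atoms$seq == seq & atoms$name == name)
    if (length(i) != 1L)
      stop(sprintf("cannot place atom %s of %s:%d", name, chain, seq))
    atoms$x[i] <<- xyz[1]; atoms$y[i] <<- xyz[2]; atoms$z[i] <<- xyz[3]
  }

  np_atoms <- list()
  np_seq <- 200L
  truth <- list()

  for (slot in seq_along(planted)) {
    p <- planted[[slot]]
    def <- dict$definitions[[p$def]]
    lane_y <- -9 - 6 * slot
    ci <- match(p$chain, names(chains))
    lane_z <- 25 * (ci - 1L)
    base_x <- 3.8 * (p$positions[1] - 1L)

    if (def$category == "modified-residue") {
      if (!p$decoy)
        truth[[length(truth) + 1L]] <- data.frame(
          def_id = def$internal_id, category = def$category,
          residues = paste0(p$chain, ":", p$positions[1]), n_bonds = 0L,
          stringsAsFactors = FALSE)
      next
    }

    d <- p$distance
    thr <- linkage_threshold(def, tolerance, radii)
    if (is.null(d)) stop("planted '", p$def, "' needs a distance")
    if (!p$decoy && (d < 0.6 || d > thr - 0.05))
      stop(sprintf("infeasible planted distance %.2f for '%s' (threshold %.2f)",
                   d, p$def, thr))

    if (def$category == "cross-link") {
      lk <- def$linkages[[1]]
      move_atom(p$chain, p$positions[lk$comp1], lk$atoms1[1],
                c(base_x, lane_y, lane_z))
      move_atom(p$chain, p$positions[lk$comp2], lk$atoms2[1],
                c(base_x + d, lane_y, lane_z))
      if (!p$decoy)
        truth[[length(truth) + 1L]] <- data.frame(
          def_id = def$internal_id, category = def$category,
          residues = paste(sort(paste0(p$chain, ":", p$positions)),
                           collapse = ";"),
          n_bonds = length(def$linkages), stringsAsFactors = FALSE)
    } else {  # attachment
      roles <- vapply(def$components, function(cm) cm$role, character(1))
      np_cm <- def$components[[which(roles == "non-polymer")[1]]]
      np_code <- np_cm$codes[1]
      tpl <- npt[[np_code]]
      if (is.null(tpl)) stop("no template for non-polymer code ", np_code)
      np_seq <- np_seq + 1L
      origin <- c(base_x, lane_y, lane_z)
      grp <- data.frame(record = "HETATM", name = tpl$name,
                        element = tpl$element, code = np_code,
                        chain = p$chain, seq = np_seq,
                        x = origin[1] + tpl$dx, y = origin[2] + tpl$dy,
                        z = origin[3] + tpl$dz, stringsAsFactors = FALSE)
      np_atoms[[length(np_atoms) + 1L]] <- grp

      lk <- def$linkages[[1]]
      aa_end_first <- roles[lk$comp1] == "amino-acid"
      aa_names <- if (aa_end_first) lk$atoms1 else lk$atoms2
      np_names <- if (aa_end_first) lk$atoms2 else lk$atoms1
      centroid <- c(mean(grp$x), mean(grp$y), mean(grp$z))
      spread_dirs <- rbind(c(0, -1, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, -1),
                           c(-1, 0, 0), c(1, 0, 0))
      for (k in seq_along(p$positions)) {
        anchor_name <- np_names[min(k, length(np_names))]
        ai <- match(anchor_name, grp$name)
        if (is.na(ai)) stop("anchor atom ", anchor_name, " not in ", np_code)
        anchor <- c(grp$x[ai], grp$y[ai], grp$z[ai])
        dirv <- anchor - centroid
        if (sqrt(sum(dirv^2)) < 1e-6) dirv <- spread_dirs[min(k, 6L), ]
        dirv <- dirv / sqrt(sum(dirv^2))
        move_atom(p$chain, p$positions[k], aa_names[1], anchor + d * dirv)
        if (!p$decoy)
          truth[[length(truth) + 1L]] <- data.frame(
            def_id = def$internal_id, category = def$category,
            residues = paste(sort(c(paste0(p$chain, ":", p$positions[k]),
                                    paste0(p$chain, ":", np_seq))),
                             collapse = ";"),
            n_bonds = 1L, stringsAsFactors = FALSE)
      }
    }
  }

  if (length(np_atoms)) atoms <- rbind(atoms, do.call(rbind, np_atoms))
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(def_id = character(), category = character(),
                           residues = character(), n_bonds = integer(),
                           stringsAsFactors = FALSE)
  truth <- truth[order(truth$def_id, truth$residues), , drop = FALSE]
  rownames(truth) <- NULL

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- tolower(spec$entry_id)
  pdb_path <- file.path(dir, paste0(stem, ".pdb"))
  cif_path <- file.path(dir, paste0(stem, ".cif"))
  .write_fixture_pdb(atoms, spec$entry_id, pdb_path)
  .write_fixture_cif(atoms, spec$entry_id, cif_path)

  structure(list(pdb = pdb_path, cif = cif_path, truth = truth,
                 atoms = atoms, entry_id = spec$entry_id, spec = spec),
            class = "mod_fixture")
}

.write_fixture_pdb <- function(atoms, entry_id, path) {
  lines <- character(nrow(atoms) + 2L)
  lines[1] <- sprintf("%-62s%-4s", "HEADER    SYNTHETIC FIXTURE", entry_id)
  for (i in seq_len(nrow(atoms))) {
    nm <- atoms$name[i]
    name_field <- if (nchar(nm) >= 4L || nchar(atoms$element[i]) == 2L)
      formatC(nm, width = -4) else paste0(" ", formatC(nm, width = -3))
    lines[i + 1L] <- sprintf(
      "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      atoms$record[i], i, name_field, "", atoms$code[i], atoms$chain[i],
      atoms$seq[i], "", atoms$x[i], atoms$y[i], atoms$z[i], 1, 0,
      atoms$element[i])
  }
  lines[length(lines)] <- "END"
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
}

.write_fixture_cif <- function(atoms, entry_id, path) {
  hdr <- c(paste0("data_", entry_id), "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  entity <- cumsum(!duplicated(paste(atoms$chain, atoms$record == "HETATM" &
                                     atoms$seq >= 200L, atoms$seq >= 200L)))
  rows <- sprintf(
    "%-6s %-5d %-2s %-4s . %-3s %-2s %d %-4s ? %8.3f %8.3f %8.3f 1.00 0.00 %-4d %-3s %-2s %-4s 1",
    atoms$record, seq_len(nrow(atoms)), atoms$element, atoms$name,
    atoms$code, atoms$chain, 1L,
    ifelse(atoms$seq < 200L, as.character(atoms$seq), "."),
    atoms$x, atoms$y, atoms$z, atoms$seq, atoms$code, atoms$chain,
    atoms$name)
  con <- file(path, open = "wb")
  writeLines(c(hdr, rows, "#"), con, sep = "\n")
  close(con)
}

#' Rigid-motion and record-order perturbation of a fixture
#'
#' Applies one rotation + translation to every coordinate and shuffles the
#' order of residue blocks (and of atoms within each residue), then
#' re-emits the PDB/mmCIF pair.  The truth table is unchanged: the
#' identification scans must be invariant to both operations.
#'
#' @param fixture A [make_fixture()] result.
#' @param angles Euler rotation angles in degrees (x, y, z axes).
#' @param translation Length-3 translation in Angstrom.
#' @param permutation_seed Seed for the record shuffle; `NULL` keeps the
#'   original order.
#' @param dir Output directory.
#' @return A new `mod_fixture` with the same truth table.
#' @export
perturb_fixture <- function(fixture, angles = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            permutation_seed = NULL,
                            dir = tempfile("perturbed")) {
  stopifnot(inherits(fixture, "mod_fixture"))
  atoms <- fixture$atoms
  R <- .rotation_matrix(angles * pi / 180)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + translation[1]
  atoms$y <- xyz[, 2] + translation[2]
  atoms$z <- xyz[, 3] + translation[3]

  if (!is.null(permutation_seed)) {
    set.seed(permutation_seed)
    res_key <- paste(atoms$chain, atoms$seq)
    blocks <- split(seq_len(nrow(atoms)), factor(res_key, unique(res_key)))
    blocks <- blocks[sample(length(blocks))]
    blocks <- lapply(blocks, function(ix) ix[sample(length(ix))])
    atoms <- atoms[unlist(blocks, use.names = FALSE), , drop = FALSE]
    rownames(atoms) <- NULL
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- tolower(fixture$entry_id)
  pdb_path <- file.path(dir, paste0(stem, ".pdb"))
  cif_path <- file.path(dir, paste0(stem, ".cif"))
  .write_fixture_pdb(atoms, fixture$entry_id, pdb_path)
  .write_fixture_cif(atoms, fixture$entry_id, cif_path)
  structure(list(pdb = pdb_path, cif = cif_path, truth = fixture$truth,
                 atoms = atoms, entry_id = fixture$entry_id,
                 spec = fixture$spec),
            class = "mod_fixture")
}

.rotation_matrix <- function(a) {
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

## modifications the random generator samples from, with the residue count
## each plant needs
.RANDOM_CATALOGUE <- list(
  list(def = "phosphoserine", n = 1L), list(def = "phosphothreonine", n = 1L),
  list(def = "phosphotyrosine", n = 1L), list(def = "hydroxyproline", n = 1L),
  list(def = "selenomethionine", n = 1L), list(def = "n6-acetyllysine", n = 1L),
  list(def = "n-glycosyl-asparagine", n = 1L),
  list(def = "o-glycosyl-serine", n = 1L),
  list(def = "o-glycosyl-threonine", n = 1L),
  list(def = "zinc-histidine", n = 1L), list(def = "zinc-cysteine", n = 1L),
  list(def = "4fe-4s-cysteine", n = 2L), list(def = "3fe-4s-cysteine", n = 1L),
  list(def = "disulfide", n = 2L), list(def = "isopeptide-lys-asp", n = 2L),
  list(def = "isopeptide-lys-asn", n = 2L))

#' Draw a random fixture specification
#'
#' Samples 2-4 planted modifications across all three categories plus 0-2
#' boundary decoys, with bond distances drawn below each definition's
#' threshold.  Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param n_mods Number of planted modifications (default random 2-4).
#' @param decoys Number of decoys (default random 0-2).
#' @return A [fixture_spec()].
#' @export
random_fixture_spec <- function(seed, n_mods = NULL, decoys = NULL) {
  set.seed(seed)
  dict <- default_dictionary()
  if (is.null(n_mods)) n_mods <- sample(2:4, 1L)
  if (is.null(decoys)) decoys <- sample(0:2, 1L)
  picks <- .RANDOM_CATALOGUE[sample(length(.RANDOM_CATALOGUE), n_mods)]

  filler <- c("GLY", "ALA", "VAL", "LEU", "PRO", "PHE", "ILE", "TRP")
  n_res_needed <- sum(vapply(picks, function(p) p$n, integer(1)))
  chain_len <- 3L * n_res_needed + 5L
  chain <- sample(filler, chain_len, replace = TRUE)

  planted <- list()
  next_pos <- 2L
  for (p in picks) {
    def <- dict$definitions[[p$def]]
    positions <- next_pos + 3L * (seq_len(p$n) - 1L)
    next_pos <- max(positions) + 3L
    entry <- list(def = p$def, chain = "A", positions = positions)
    if (def$category != "modified-residue") {
      thr <- linkage_threshold(def)
      entry$distance <- round(stats::runif(1, max(0.8, thr - 1.0), thr - 0.1), 2)
    }
    planted[[length(planted) + 1L]] <- entry
  }
  fixture_spec(seed = seed, chains = list(A = chain), planted = planted,
               decoys = decoys)
}
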