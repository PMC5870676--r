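#' @importFrom bio3d read.pdb read.cif
NULL

## Component codes treated as water and excluded from non-polymer groups.
WATER_CODES <- c("HOH", "DOD", "WAT")

## Two-letter element symbols recognised when inferring elements from atom
## names in files lacking an element column.
TWO_LETTER_ELEMENTS <- c(
  "LI", "BE", "NA", "MG", "AL", "SI", "CL", "AR", "CA", "SC", "TI", "CR",
  "MN", "FE", "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR",
  "RB", "SR", "MO", "RU", "RH", "PD", "AG", "CD", "SN", "SB", "TE", "XE",
  "CS", "BA", "PT", "AU", "HG", "TL", "PB", "BI")

#' Component codes recognised as modified residues during parsing
#'
#' Used to classify HETATM records that sit inside a polymer chain's residue
#' numbering: a HETATM residue with one of these codes is treated as a
#' polymer residue (the PDB format files nonstandard residues as HETATM even
#' when they are part of the chain).  Defaults to the modified-residue codes
#' of the bundled dictionary plus a few frequent extras.
#'
#' @return Character vector of 3-character component codes.
#' @export
known_modres_codes <- function() {
  dict <- default_dictionary()
  from_dict <- unlist(lapply(dict$definitions, function(d)
    if (d$category == "modified-residue") d$components[[1]]$codes))
  unique(c(from_dict,
           c("LLP", "CSD", "OCS", "M3L", "MLZ", "HIC", "CGU", "CME",
             "SMC", "TYS", "DAL", "FME")))
}

#' Parse a PDB or mmCIF file into a structure model
#'
#' Produces the uniform model all identification scans run on: a flat atom
#' table with author chain/residue identifiers, stripped atom names,
#' element symbols and coordinates, plus a residue table with
#' polymer/non-polymer classification.  Waters (HOH/DOD/WAT) are excluded;
#' for alternate locations only the highest-occupancy conformer of each
#' atom is kept (ties broken by the lexicographically smallest altloc);
#' multi-model files contribute a single selected model.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file; when the
#'   extension is ambiguous the content is sniffed.
#' @param model 1-based coordinate model to use (default first).
#' @param format Force `"pdb"` or `"mmcif"`; `NULL` autodetects.
#' @param modres_codes Component codes treated as polymer residues when
#'   filed as HETATM inside a chain (see [known_modres_codes()]).
#' @return A list of class `structure_model` with elements `entry_id`,
#'   `model_number`, `source_format`, `atoms` (one row per atom) and
#'   `residues` (one row per residue; polymer residues carry a 0-based
#'   `polymer_index` within their chain).
#' @export
parse_structure <- function(path, model = 1L, format = NULL,
                            modres_codes = known_modres_codes()) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  fmt <- if (is.null(format)) .detect_format(path) else match.arg(format, c("pdb", "mmcif"))

  pdb <- tryCatch(
    if (fmt == "pdb")
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    else
      suppressWarnings(bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE)),
    error = function(e) stop("failed to parse ", basename(path), ": ",
                             conditionMessage(e), call. = FALSE))

  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  model <- as.integer(model)
  if (model < 1L || model > n_models)
    stop(sprintf("model %d requested but file has %d model(s)", model, n_models))
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }

  atoms <- data.frame(
    record  = as.character(at$type),
    name    = toupper(trimws(as.character(at$elety))),
    element = toupper(trimws(ifelse(is.na(at$elesy), "", as.character(at$elesy)))),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    chain  = ifelse(is.na(at$chain), "", as.character(at$chain)),
    seq_id = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    code   = toupper(trimws(as.character(at$resid))),
    stringsAsFactors = FALSE)

  atoms <- atoms[!atoms$code %in% WATER_CODES, , drop = FALSE]
  atoms <- atoms[is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z),
                 , drop = FALSE]

  ## infer missing elements from the atom-name convention; atoms whose
  ## element cannot be resolved are dropped from bond detection downstream
  need <- !nzchar(atoms$element)
  if (any(need))
    atoms$element[need] <- mapply(.infer_element, atoms$name[need],
                                  atoms$record[need])
  unresolved <- !nzchar(atoms$element)
  if (any(unresolved)) {
    warning(sum(unresolved), " atom(s) with unresolvable element skipped")
    atoms <- atoms[!unresolved, , drop = FALSE]
  }

  atoms$res_uid <- paste0(atoms$chain, ":", atoms$seq_id,
                          ifelse(nzchar(atoms$insert), atoms$insert, ""))
  atoms <- .resolve_altlocs(atoms)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")

  residues <- .classify_residues(atoms, modres_codes)
  m <- match(atoms$res_uid, residues$res_uid)
  atoms$is_polymer <- residues$is_polymer[m]
  atoms$polymer_index <- residues$polymer_index[m]
  rownames(atoms) <- NULL

  structure(list(entry_id = .read_entry_id(path, fmt),
                 model_number = model,
                 source_format = fmt,
                 atoms = atoms,
                 residues = residues),
            class = "structure_model")
}

.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  head_lines <- readLines(path, n = 200L, warn = FALSE)
  if (any(grepl("^data_", head_lines)) || any(grepl("_atom_site\\.", head_lines)))
    return("mmcif")
  if (any(grepl("^(ATOM  |HETATM|HEADER)", head_lines)))
    return("pdb")
  stop("cannot determine format of ", basename(path))
}

.read_entry_id <- function(path, fmt) {
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  if (fmt == "pdb") {
    h <- head_lines[startsWith(head_lines, "HEADER")]
    if (length(h)) {
      id <- trimws(substr(h[[1]], 63L, 66L))
      if (nzchar(id)) return(id)
    }
  } else {
    d <- head_lines[startsWith(head_lines, "data_")]
    if (length(d)) {
      id <- trimws(sub("^data_", "", d[[1]]))
      if (nzchar(id)) return(id)
    }
  }
  toupper(tools::file_path_sans_ext(basename(path)))
}

## Atom-name convention: leading alphabetic characters, digits stripped.
## In polymer residues the Greek-letter naming makes the first character the
## element ("CA" is C-alpha), except selenium; in non-polymer groups a
## two-letter element prefix (FE1, ZN, CL1) takes precedence.
.infer_element <- function(name, record) {
  alpha <- gsub("[^A-Z]", "", toupper(name))
  if (!nzchar(alpha)) return("")
  two <- substr(alpha, 1L, 2L)
  if (record == "HETATM" && two %in% TWO_LETTER_ELEMENTS) return(two)
  if (alpha == "SE") return("SE")
  substr(alpha, 1L, 1L)
}

## One geometry per atom: keep the highest-occupancy altloc of each
## (residue, atom name); ties go to the lexicographically smallest altloc.
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$res_uid, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

.classify_residues <- function(atoms, modres_codes) {
  first <- !duplicated(atoms$res_uid)
  res <- data.frame(res_uid = atoms$res_uid[first],
                    code = atoms$code[first],
                    chain = atoms$chain[first],
                    seq_id = atoms$seq_id[first],
                    insert = atoms$insert[first],
                    record = atoms$record[first],
                    stringsAsFactors = FALSE)

  res$is_polymer <- res$record == "ATOM"
  ## HETATM residues with a known modified-residue code lying inside (or
  ## directly adjacent to) a chain's ATOM numbering belong to the polymer
  for (ch in unique(res$chain)) {
    in_ch <- res$chain == ch
    rng <- range(res$seq_id[in_ch & res$is_polymer])
    if (!is.finite(rng[1])) next
    het <- in_ch & !res$is_polymer & res$code %in% modres_codes &
      res$seq_id >= rng[1] - 1L & res$seq_id <= rng[2] + 1L
    res$is_polymer[het] <- TRUE
  }

  res$polymer_index <- NA_integer_
  for (ch in unique(res$chain)) {
    sel <- which(res$chain == ch & res$is_polymer)  # file order
    res$polymer_index[sel] <- seq_along(sel) - 1L
  }
  res$record <- NULL
  rownames(res) <- NULL
  res
}

#' Polymer sequence of one chain
#'
#' @param model A [parse_structure()] model.
#' @param chain_id Author chain identifier.
#' @return Character vector of component codes in polymer order (modified
#'   residues keep their own codes, e.g. `"SEP"`).
#' @export
polymer_sequence <- function(model, chain_id) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  sel <- res$chain == chain_id & res$is_polymer
  if (!any(sel)) stop("no polymer chain with id '", chain_id, "'")
  res$code[sel][order(res$polymer_index[sel])]
}

#' Chain identifiers of a structure model
#' @param model A [parse_structure()] model.
#' @return Character vector of chains that contain polymer residues.
#' @export
polymer_chains <- function(model) {
  unique(model$residues$chain[model$residues$is_polymer])
}

#' @export
print.structure_model <- function(x, ...) {
  np <- sum(x$residues$is_polymer)
  nn <- sum(!x$residues$is_polymer)
  cat(sprintf("Structure %s (%s, model %d): %d polymer residue(s) in %d chain(s), %d non-polymer group(s), %d atoms\n",
              x$entry_id, x$source_format, x$model_number, np,
              length(polymer_chains(x)), nn, nrow(x$atoms)))
  invisible(x)
}
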