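#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_attr xml_text
#'   xml_name xml_add_child write_xml xml_new_root
NULL

## Category labels.  Every definition carries exactly one.
MOD_CATEGORIES <- c("modified-residue", "attachment", "cross-link")

#' Construct a component specification
#'
#' A component is one chemical building block of a modification: either an
#' amino-acid residue located on a polymer chain, or a non-polymer group
#' (ligand, glycan, ion) deposited as its own HETATM group.  Alternate
#' component codes (e.g. the two anomers NAG/NDG) may be listed together.
#'
#' @param codes Character vector of 1-3 character uppercase alphanumeric
#'   component codes; alternates allowed, first is canonical.
#' @param role `"amino-acid"` or `"non-polymer"`.
#' @param terminal Restrict matching to chain termini: `"any"` (default),
#'   `"n"` or `"c"`.
#' @return A list of class `mod_component`.
#' @export
mod_component <- function(codes, role = c("amino-acid", "non-polymer"),
                          terminal = c("any", "n", "c")) {
  role <- match.arg(role)
  terminal <- match.arg(terminal)
  structure(list(codes = toupper(as.character(codes)), role = role,
                 terminal = terminal),
            class = "mod_component")
}

#' Construct a linkage specification
#'
#' A linkage names one covalent bond of a modification: two endpoints, each
#' an index into the definition's component list plus an ordered list of
#' candidate PDB atom names (first matching name wins during
#' identification).
#'
#' @param comp1,comp2 1-based indices into the definition's component list.
#' @param atoms1,atoms2 Character vectors of candidate atom names in order
#'   of preference.
#' @return A list of class `mod_linkage`.
#' @export
mod_linkage <- function(comp1, atoms1, comp2, atoms2) {
  structure(list(comp1 = as.integer(comp1),
                 atoms1 = toupper(trimws(as.character(atoms1))),
                 comp2 = as.integer(comp2),
                 atoms2 = toupper(trimws(as.character(atoms2)))),
            class = "mod_linkage")
}

#' Construct a modification definition
#'
#' One dictionary record: the identity of a modification (internal id,
#' optional PSI-MOD `MOD:NNNNN` and RESID `AANNNN` accessions, names,
#' keywords), its category, the chemical components involved and the atom
#' pairs that bond them.
#'
#' @param internal_id Unique string id within a dictionary.
#' @param category One of `"modified-residue"`, `"attachment"`,
#'   `"cross-link"`.
#' @param components List of [mod_component()] objects.
#' @param linkages List of [mod_linkage()] objects (empty for modified
#'   residues).
#' @param name Human-readable name.
#' @param psimod_id,resid_id,description,systematic_name Optional strings
#'   (`NA` when absent).
#' @param keywords Character vector of keywords.
#' @return A list of class `mod_definition`.  Use [validate_definition()]
#'   to check category invariants.
#' @export
mod_definition <- function(internal_id, category, components,
                           linkages = list(), name = internal_id,
                           psimod_id = NA_character_,
                           resid_id = NA_character_,
                           description = NA_character_,
                           systematic_name = NA_character_,
                           keywords = character()) {
  structure(list(
    internal_id = as.character(internal_id),
    psimod_id = as.character(psimod_id),
    resid_id = as.character(resid_id),
    name = as.character(name),
    description = as.character(description),
    systematic_name = as.character(systematic_name),
    category = as.character(category),
    keywords = as.character(keywords),
    components = components,
    linkages = linkages
  ), class = "mod_definition")
}

#' Validate a modification definition
#'
#' Checks the structural rules of each category: a modified residue is a
#' single amino-acid component with no linkages; an attachment joins at
#' least one amino-acid component to at least one non-polymer component by
#' at least one linkage; a cross-link joins two or more amino-acid
#' components by a connected linkage graph.
#'
#' @param def A [mod_definition()].
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_definition <- function(def) {
  v <- character()
  say <- function(msg) v[[length(v) + 1L]] <<- msg

  if (!nzchar(def$internal_id %||% "")) say("internal_id must be non-empty")
  if (!def$category %in% MOD_CATEGORIES)
    say(sprintf("unknown category '%s'", def$category))

  comps <- def$components
  if (length(comps) == 0L) say("definition has no components")
  for (i in seq_along(comps)) {
    cm <- comps[[i]]
    if (length(cm$codes) == 0L)
      say(sprintf("component %d has no codes", i))
    bad <- cm$codes[!grepl("^[0-9A-Z]{1,3}$", cm$codes)]
    if (length(bad))
      say(sprintf("component %d has malformed code(s): %s", i,
                  paste(bad, collapse = ", ")))
    if (!cm$role %in% c("amino-acid", "non-polymer"))
      say(sprintf("component %d has unknown role '%s'", i, cm$role))
  }

  roles <- vapply(comps, function(cm) cm$role, character(1))
  for (j in seq_along(def$linkages)) {
    lk <- def$linkages[[j]]
    ends_ok <- TRUE
    for (end in c("1", "2")) {
      ci <- lk[[paste0("comp", end)]]
      at <- lk[[paste0("atoms", end)]]
      if (is.na(ci) || ci < 1L || ci > length(comps)) {
        say(sprintf("linkage %d references invalid component index %s", j, ci))
        ends_ok <- FALSE
      }
      if (length(at) == 0L || any(!nzchar(at)))
        say(sprintf("linkage %d end %s has an empty atom-name list", j, end))
      if (any(nchar(at) > 4L))
        say(sprintf("linkage %d end %s has atom name longer than 4 characters",
                    j, end))
    }
    if (ends_ok && def$category %in% c("attachment", "cross-link") &&
        lk$comp1 == lk$comp2)
      say(sprintf("linkage %d must reference two distinct components", j))
    if (ends_ok && def$category == "attachment" &&
        length(unique(roles[c(lk$comp1, lk$comp2)])) != 2L)
      say(sprintf(
        "linkage %d of an attachment must join an amino-acid component to a non-polymer component",
        j))
  }

  n_aa <- sum(roles == "amino-acid")
  n_np <- sum(roles == "non-polymer")
  switch(def$category,
    "modified-residue" = {
      if (length(comps) != 1L || n_aa != 1L)
        say("modified-residue requires exactly 1 amino-acid component")
      if (length(def$linkages) != 0L)
        say("modified-residue must have 0 linkages")
    },
    "attachment" = {
      if (length(comps) < 2L || n_aa < 1L || n_np < 1L)
        say("attachment requires >=2 components with >=1 amino-acid and >=1 non-polymer")
      if (length(def$linkages) < 1L)
        say("attachment requires >=1 linkage")
    },
    "cross-link" = {
      if (n_aa < 2L)
        say("cross-link requires >=2 amino-acid components")
      if (length(def$linkages) < 1L)
        say("cross-link requires >=1 linkage")
      else if (length(comps) >= 2L && !.linkage_graph_connected(def))
        say("cross-link linkage graph must connect all components")
    }
  )
  v
}

## Connectivity of the linkage graph over component indices.
.linkage_graph_connected <- function(def) {
  n <- length(def$components)
  if (n <= 1L) return(TRUE)
  adj <- vector("list", n)
  for (lk in def$linkages) {
    if (lk$comp1 >= 1L && lk$comp1 <= n && lk$comp2 >= 1L && lk$comp2 <= n) {
      adj[[lk$comp1]] <- c(adj[[lk$comp1]], lk$comp2)
      adj[[lk$comp2]] <- c(adj[[lk$comp2]], lk$comp1)
    }
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (nb in adj[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  all(seen)
}

#' Assemble a modification dictionary
#'
#' Validates every definition, checks id uniqueness and builds the
#' code-to-definition index used by the identification scans.
#'
#' @param definitions List of [mod_definition()] objects.
#' @param version Free-form version string recorded in reports.
#' @return A list of class `mod_dictionary` with elements `definitions`
#'   (named by internal id), `index_by_code` (component code ->
#'   character vector of internal ids) and `version`.
#' @export
mod_dictionary <- function(definitions, version = "unversioned") {
  ids <- vapply(definitions, function(d) d$internal_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate internal_id value(s): ", paste(unique(dup), collapse = ", "))
  for (d in definitions) {
    viol <- validate_definition(d)
    if (length(viol))
      stop(sprintf("invalid definition '%s': %s", d$internal_id,
                   paste(viol, collapse = "; ")))
  }
  names(definitions) <- ids
  structure(list(definitions = definitions,
                 index_by_code = .build_code_index(definitions),
                 version = as.character(version)),
            class = "mod_dictionary")
}

.build_code_index <- function(definitions) {
  idx <- list()
  for (d in definitions) {
    for (cm in d$components) {
      for (code in cm$codes) {
        idx[[code]] <- unique(c(idx[[code]], d$internal_id))
      }
    }
  }
  idx
}

#' Read a modification dictionary from XML
#'
#' The format is a `<protein-modifications>` root holding one
#' `<modification>` element per definition; see the bundled
#' `inst/extdata/modifications.xml` for a complete example.
#'
#' @param path Path to an XML dictionary file.
#' @return A validated [mod_dictionary()].
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  doc <- xml2::read_xml(path)  # malformed XML -> xml2 parse error with line
  if (xml2::xml_name(doc) != "protein-modifications")
    stop("not a modification dictionary: root element is <",
         xml2::xml_name(doc), ">")
  version <- xml2::xml_attr(doc, "version")
  if (is.na(version)) version <- "unversioned"

  defs <- lapply(xml2::xml_find_all(doc, "./modification"), .parse_definition)
  mod_dictionary(defs, version = version)
}

.parse_definition <- function(node) {
  opt_text <- function(xp) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
  }
  comps <- lapply(xml2::xml_find_all(node, "./component"), function(cn) {
    mod_component(
      codes = vapply(xml2::xml_find_all(cn, "./code"), xml2::xml_text,
                     character(1)),
      role = xml2::xml_attr(cn, "role"),
      terminal = if (is.na(xml2::xml_attr(cn, "terminal"))) "any"
                 else xml2::xml_attr(cn, "terminal"))
  })
  ## components carry an explicit index attribute; honour document order of
  ## the attribute, not of the elements
  comp_idx <- vapply(xml2::xml_find_all(node, "./component"), function(cn)
    as.integer(xml2::xml_attr(cn, "index")), integer(1))
  comps <- comps[order(comp_idx)]

  links <- lapply(xml2::xml_find_all(node, "./linkage"), function(ln) {
    ends <- xml2::xml_find_all(ln, "./end")
    if (length(ends) != 2L) stop("linkage must have exactly two <end> elements")
    atoms <- function(e) strsplit(xml2::xml_attr(e, "atoms"), ",", fixed = TRUE)[[1]]
    mod_linkage(comp1 = as.integer(xml2::xml_attr(ends[[1]], "component")),
                atoms1 = atoms(ends[[1]]),
                comp2 = as.integer(xml2::xml_attr(ends[[2]], "component")),
                atoms2 = atoms(ends[[2]]))
  })

  kw <- vapply(xml2::xml_find_all(node, "./keyword"), xml2::xml_text,
               character(1))
  mod_definition(
    internal_id = xml2::xml_attr(node, "id"),
    category = xml2::xml_attr(node, "category"),
    components = comps,
    linkages = links,
    name = if (is.na(opt_text("./name"))) xml2::xml_attr(node, "id")
           else opt_text("./name"),
    psimod_id = opt_text("./psimod-id"),
    resid_id = opt_text("./resid-id"),
    description = opt_text("./description"),
    systematic_name = opt_text("./systematic-name"),
    keywords = kw)
}

#' Write a modification dictionary to XML
#'
#' Inverse of [load_dictionary()]: `load_dictionary(save_dictionary(d))`
#' reproduces `d` field for field.  Optional fields that are `NA` are
#' omitted from the file.
#'
#' @param dict A [mod_dictionary()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "mod_dictionary"))
  root <- xml2::xml_new_root("protein-modifications", version = dict$version)
  for (d in dict$definitions) {
    mn <- xml2::xml_add_child(root, "modification", id = d$internal_id,
                              category = d$category)
    add_opt <- function(tag, value) {
      if (length(value) == 1L && !is.na(value))
        xml2::xml_add_child(mn, tag, value)
    }
    add_opt("psimod-id", d$psimod_id)
    add_opt("resid-id", d$resid_id)
    add_opt("name", d$name)
    add_opt("description", d$description)
    add_opt("systematic-name", d$systematic_name)
    for (k in d$keywords) xml2::xml_add_child(mn, "keyword", k)
    for (i in seq_along(d$components)) {
      cm <- d$components[[i]]
      cn <- xml2::xml_add_child(mn, "component", index = as.character(i),
                                role = cm$role, terminal = cm$terminal)
      for (code in cm$codes) xml2::xml_add_child(cn, "code", code)
    }
    for (lk in d$linkages) {
      ln <- xml2::xml_add_child(mn, "linkage")
      xml2::xml_add_child(ln, "end", component = as.character(lk$comp1),
                          atoms = paste(lk$atoms1, collapse = ","))
      xml2::xml_add_child(ln, "end", component = as.character(lk$comp2),
                          atoms = paste(lk$atoms2, collapse = ","))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

## package-local cache for the bundled dictionary
.modfinder_cache <- new.env(parent = emptyenv())

#' The bundled starter dictionary
#'
#' A representative dictionary covering all three categories: common
#' phospho/hydroxy/acetyl/methyl modified residues, N- and O-glycosylation,
#' zinc coordination, iron-sulfur cluster attachments, and disulfide and
#' isopeptide cross-links.
#'
#' @return A [mod_dictionary()].
#' @export
default_dictionary <- function() {
  if (is.null(.modfinder_cache$default_dict)) {
    path <- system.file("extdata", "modifications.xml", package = "modfinder",
                        mustWork = TRUE)
    .modfinder_cache$default_dict <- load_dictionary(path)
  }
  .modfinder_cache$default_dict
}

#' @export
print.mod_dictionary <- function(x, ...) {
  cats <- vapply(x$definitions, function(d) d$category, character(1))
  cat(sprintf("Modification dictionary (version %s): %d definitions\n",
              x$version, length(x$definitions)))
  for (ct in MOD_CATEGORIES)
    cat(sprintf("  %-16s %d\n", ct, sum(cats == ct)))
  invisible(x)
}

#' @export
print.mod_definition <- function(x, ...) {
  cat(sprintf("<%s> %s (%s)\n", x$category, x$internal_id, x$name))
  for (cm in x$components)
    cat(sprintf("  component: %s [%s%s]\n", paste(cm$codes, collapse = "/"),
                cm$role,
                if (cm$terminal != "any") paste0(", ", cm$terminal, "-terminal")
                else ""))
  for (lk in x$linkages)
    cat(sprintf("  linkage: %d:%s -- %d:%s\n", lk$comp1,
                paste(lk$atoms1, collapse = ","), lk$comp2,
                paste(lk$atoms2, collapse = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
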