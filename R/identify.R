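#' Scan configuration
#'
#' Bundles the modification dictionary, the bond-detection settings and the
#' category filter for an identification run.
#'
#' @param dictionary A [mod_dictionary()]; defaults to the bundled starter
#'   dictionary.
#' @param bond_config A [bond_config()].
#' @param categories Subset of `c("modified-residue", "attachment",
#'   "cross-link")` to scan.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(dictionary = default_dictionary(),
                        bond_config = modfinder::bond_config(),
                        categories = MOD_CATEGORIES) {
  categories <- match.arg(categories, MOD_CATEGORIES, several.ok = TRUE)
  stopifnot(length(categories) >= 1L, inherits(dictionary, "mod_dictionary"),
            inherits(bond_config, "bond_config"))
  structure(list(dictionary = dictionary, bond_config = bond_config,
                 categories = categories),
            class = "scan_config")
}

.defs_of <- function(dict, category) {
  Filter(function(d) d$category == category, dict$definitions)
}

## residue table rows for the given uids, in the given order
.residue_rows <- function(model, uids) {
  model$residues[match(uids, model$residues$res_uid), , drop = FALSE]
}

## does residue row satisfy a component's terminal restriction?
.terminal_ok <- function(model, res_rows, terminal) {
  if (terminal == "any") return(rep(TRUE, nrow(res_rows)))
  idx <- res_rows$polymer_index
  if (terminal == "n") return(!is.na(idx) & idx == 0L)
  ## c-terminal: last polymer index of the residue's chain
  last <- vapply(res_rows$chain, function(ch) {
    sel <- model$residues$is_polymer & model$residues$chain == ch
    if (!any(sel)) return(NA_integer_)
    max(model$residues$polymer_index[sel])
  }, integer(1))
  !is.na(idx) & idx == last
}

.make_identification <- function(def, residues, bonds) {
  structure(list(def_id = def$internal_id,
                 category = def$category,
                 name = def$name,
                 psimod_id = def$psimod_id,
                 resid_id = def$resid_id,
                 residues = residues,
                 bonds = bonds),
            class = "mod_identification")
}

#' @export
print.mod_identification <- function(x, ...) {
  res <- paste(sprintf("%s %s%s (%s)", x$residues$chain, x$residues$seq_id,
                       x$residues$insert, x$residues$code), collapse = ", ")
  cat(sprintf("[%s] %s: %s\n", x$category, x$def_id, res))
  if (nrow(x$bonds))
    for (i in seq_len(nrow(x$bonds)))
      cat(sprintf("  bond %s(%s)-%s(%s) %.2f A\n",
                  x$bonds$atom1[i], x$bonds$res_uid1[i],
                  x$bonds$atom2[i], x$bonds$res_uid2[i], x$bonds$distance[i]))
  invisible(x)
}

#' Identify modified residues
#'
#' Scans the polymer sequences and reports every residue whose 3-character
#' component code matches a modified-residue definition.  Purely a code
#' comparison: no geometry is consulted.
#'
#' @param model A [parse_structure()] model.
#' @param cfg A [scan_config()].
#' @return List of identification records ordered by (chain,
#'   polymer_index).
#' @export
identify_modified_residues <- function(model, cfg = scan_config()) {
  defs <- .defs_of(cfg$dictionary, "modified-residue")
  res <- model$residues[model$residues$is_polymer, , drop = FALSE]
  if (nrow(res) == 0L || length(defs) == 0L) return(list())
  res <- res[order(res$chain, res$polymer_index), , drop = FALSE]

  out <- list()
  for (def in defs) {
    cm <- def$components[[1]]
    hit <- res$code %in% cm$codes
    if (!any(hit)) next
    hit[hit] <- .terminal_ok(model, res[hit, , drop = FALSE], cm$terminal)
    for (i in which(hit))
      out[[length(out) + 1L]] <-
        .make_identification(def, res[i, , drop = FALSE], .empty_bonds())
  }
  .sort_identifications(out)
}

## Pick, per (residue pair), the preferred bond: earliest atom-name match on
## each side of the linkage, then shortest distance.
.prefer_bonds <- function(bonds, names_for_1, names_for_2) {
  p1 <- match(bonds$atom1, names_for_1)
  p2 <- match(bonds$atom2, names_for_2)
  key <- paste(bonds$res_uid1, bonds$res_uid2, sep = "\r")
  ord <- order(key, p1, p2, bonds$distance)
  bonds <- bonds[ord, , drop = FALSE]
  bonds[!duplicated(key[ord]), , drop = FALSE]
}

## Orient bond rows so endpoint 1 lies in uid set `first`; drops rows whose
## endpoints both fall on the same side.
.orient_bonds <- function(bonds, first, second) {
  fwd <- bonds$res_uid1 %in% first & bonds$res_uid2 %in% second
  rev <- bonds$res_uid2 %in% first & bonds$res_uid1 %in% second & !fwd
  flipped <- bonds[rev, , drop = FALSE]
  if (nrow(flipped)) {
    sw <- function(df, a, b) { tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df }
    for (col in c("chain", "seq", "ins", "res_uid", "code", "atom", "idx"))
      flipped <- sw(flipped, paste0(col, 1), paste0(col, 2))
  }
  rbind(bonds[fwd, , drop = FALSE], flipped)
}

#' Identify attachment modifications
#'
#' For each attachment definition, scans for polymer residues in close
#' proximity to matching non-polymer groups and checks whether the listed
#' atom pair forms a covalent bond under the distance criterion.  One
#' record is emitted per bonded (polymer residue, non-polymer group) pair;
#' when a linkage lists several candidate atom names the first matching
#' name wins.
#'
#' @inheritParams identify_modified_residues
#' @return List of identification records.
#' @export
identify_attachments <- function(model, cfg = scan_config()) {
  defs <- .defs_of(cfg$dictionary, "attachment")
  at <- model$atoms
  out <- list()
  for (def in defs) {
    seen <- character(0)  # dedup key: "aa_uid \r np_uid"
    for (lk in def$linkages) {
      roles <- vapply(def$components, function(cm) cm$role, character(1))
      aa_end <- if (roles[lk$comp1] == "amino-acid") 1L else 2L
      aa_cm <- def$components[[if (aa_end == 1L) lk$comp1 else lk$comp2]]
      np_cm <- def$components[[if (aa_end == 1L) lk$comp2 else lk$comp1]]
      aa_names <- if (aa_end == 1L) lk$atoms1 else lk$atoms2
      np_names <- if (aa_end == 1L) lk$atoms2 else lk$atoms1

      aa_idx <- which(at$is_polymer & at$code %in% aa_cm$codes &
                      at$name %in% aa_names)
      np_idx <- which(!at$is_polymer & at$code %in% np_cm$codes &
                      at$name %in% np_names)
      if (length(aa_idx) == 0L || length(np_idx) == 0L) next
      if (aa_cm$terminal != "any") {
        rows <- .residue_rows(model, at$res_uid[aa_idx])
        aa_idx <- aa_idx[.terminal_ok(model, rows, aa_cm$terminal)]
        if (length(aa_idx) == 0L) next
      }

      bonds <- find_close_pairs(model, cfg$bond_config, aa_idx, np_idx)
      if (nrow(bonds) == 0L) next
      bonds <- .orient_bonds(bonds, at$res_uid[aa_idx], at$res_uid[np_idx])
      bonds <- .prefer_bonds(bonds, aa_names, np_names)

      for (i in seq_len(nrow(bonds))) {
        key <- paste(bonds$res_uid1[i], bonds$res_uid2[i], sep = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        ## residues ordered as the definition orders the two endpoint
        ## components (amino acid first in the bundled dictionary)
        uids <- if (roles[lk$comp1] == "amino-acid")
          c(bonds$res_uid1[i], bonds$res_uid2[i])
        else
          c(bonds$res_uid2[i], bonds$res_uid1[i])
        out[[length(out) + 1L]] <-
          .make_identification(def, .residue_rows(model, uids),
                               bonds[i, , drop = FALSE])
      }
    }
  }
  .sort_identifications(out)
}

#' Identify cross-link modifications
#'
#' For each cross-link definition, matches all involved residues and the
#' atom pairs forming the required chemical bonds: the detected-bond graph
#' is restricted to the atoms the definition names, then residue
#' assignments to the definition's components are enumerated with
#' backtracking.  Symmetric definitions (e.g. the two cysteines of a
#' disulfide) report each residue set once.  Intra- and inter-chain links
#' are both allowed.  Nonstandard residue codes participate exactly like
#' canonical ones, matched by code.
#'
#' @inheritParams identify_modified_residues
#' @return List of identification records.
#' @export
identify_crosslinks <- function(model, cfg = scan_config()) {
  defs <- .defs_of(cfg$dictionary, "cross-link")
  at <- model$atoms
  out <- list()
  for (def in defs) {
    k <- length(def$components)
    cand <- lapply(def$components, function(cm) {
      rows <- model$residues[model$residues$is_polymer &
                             model$residues$code %in% cm$codes, , drop = FALSE]
      rows$res_uid[.terminal_ok(model, rows, cm$terminal)]
    })
    if (any(vapply(cand, length, integer(1)) == 0L)) next

    ## per linkage: directed edge list comp1-residue -> comp2-residue with
    ## its preferred bond row
    edges <- vector("list", length(def$linkages))
    feasible <- TRUE
    for (j in seq_along(def$linkages)) {
      lk <- def$linkages[[j]]
      idx1 <- which(at$res_uid %in% cand[[lk$comp1]] & at$name %in% lk$atoms1)
      idx2 <- which(at$res_uid %in% cand[[lk$comp2]] & at$name %in% lk$atoms2)
      if (length(idx1) == 0L || length(idx2) == 0L) { feasible <- FALSE; break }
      bonds <- find_close_pairs(model, cfg$bond_config, idx1, idx2)
      if (nrow(bonds)) {
        ## each physical bond can support the linkage in either direction
        ## when both endpoints qualify for both components
        b_fwd <- .orient_bonds(bonds, at$res_uid[idx1], at$res_uid[idx2])
        b_fwd <- b_fwd[b_fwd$atom1 %in% lk$atoms1 & b_fwd$atom2 %in% lk$atoms2,
                       , drop = FALSE]
        b_rev <- .orient_bonds(bonds, at$res_uid[idx2], at$res_uid[idx1])
        b_rev <- b_rev[b_rev$atom1 %in% lk$atoms2 & b_rev$atom2 %in% lk$atoms1,
                       , drop = FALSE]
        if (nrow(b_rev)) {  # store re-oriented: endpoint1 = comp1 side
          sw <- function(df, a, b) { tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df }
          for (col in c("chain", "seq", "ins", "res_uid", "code", "atom", "idx"))
            b_rev <- sw(b_rev, paste0(col, 1), paste0(col, 2))
        }
        bonds <- rbind(b_fwd, b_rev)
        bonds <- bonds[bonds$res_uid1 != bonds$res_uid2, , drop = FALSE]
        bonds <- .prefer_bonds(bonds, lk$atoms1, lk$atoms2)
      }
      if (nrow(bonds) == 0L) { feasible <- FALSE; break }
      edges[[j]] <- bonds
    }
    if (!feasible) next

    assignments <- .enumerate_assignments(def, cand, edges)
    if (length(assignments) == 0L) next

    ## canonical de-duplication on the residue identity multiset
    keys <- vapply(assignments, function(a) paste(sort(a), collapse = "\r"),
                   character(1))
    reps <- vapply(assignments, function(a) paste(a, collapse = "\r"),
                   character(1))
    keep <- !duplicated(keys)
    ## among automorphic duplicates keep the lexicographically smallest
    ## assignment vector, deterministically
    by_key <- split(reps, keys)
    chosen <- vapply(by_key, function(g) sort(g)[1L], character(1))
    assignments <- lapply(unname(chosen[unique(keys)]),
                          function(s) strsplit(s, "\r", fixed = TRUE)[[1]])

    for (a in assignments) {
      bonds <- do.call(rbind, lapply(seq_along(def$linkages), function(j) {
        lk <- def$linkages[[j]]
        e <- edges[[j]]
        e[e$res_uid1 == a[lk$comp1] & e$res_uid2 == a[lk$comp2], , drop = FALSE]
      }))
      out[[length(out) + 1L]] <-
        .make_identification(def, .residue_rows(model, a), bonds)
    }
  }
  .sort_identifications(out)
}

## Backtracking enumeration of residue-to-component assignments satisfying
## every linkage; definitions are tiny (2-7 components) so exact search.
.enumerate_assignments <- function(def, cand, edges) {
  k <- length(def$components)
  results <- list()
  assign <- character(k)

  check_partial <- function(pos) {
    for (j in seq_along(def$linkages)) {
      lk <- def$linkages[[j]]
      if (lk$comp1 <= pos && lk$comp2 <= pos) {
        e <- edges[[j]]
        if (!any(e$res_uid1 == assign[lk$comp1] &
                 e$res_uid2 == assign[lk$comp2]))
          return(FALSE)
      }
    }
    TRUE
  }
  recurse <- function(pos) {
    if (pos > k) { results[[length(results) + 1L]] <<- assign; return(invisible()) }
    for (uid in cand[[pos]]) {
      if (uid %in% assign[seq_len(pos - 1L)]) next  # residues distinct
      assign[pos] <<- uid
      if (check_partial(pos)) recurse(pos + 1L)
    }
    assign[pos] <<- ""
    invisible()
  }
  recurse(1L)
  results
}

## canonical report order: category, definition id, first residue
.sort_identifications <- function(ids) {
  if (length(ids) <= 1L) return(ids)
  key <- vapply(ids, function(x) {
    r <- x$residues[1L, ]
    sprintf("%d|%s|%s|%08d|%s", match(x$category, MOD_CATEGORIES), x$def_id,
            r$chain, r$seq_id + 10000000L, r$insert)
  }, character(1))
  ids[order(key)]
}

#' Run all identification scans on one structure
#'
#' Applies the modified-residue, attachment and cross-link scans (as
#' selected in `cfg$categories`) and assembles a modification report.
#' Category overlap is not suppressed: a residue may appear both as a
#' modified residue and inside a cross-link.
#'
#' @inheritParams identify_modified_residues
#' @return A `mod_report`: list with `entry_id`, `identifications`
#'   (canonically ordered), and `scan_summary` (tolerance and dictionary
#'   version).
#' @export
identify_all <- function(model, cfg = scan_config()) {
  ids <- list()
  if ("modified-residue" %in% cfg$categories)
    ids <- c(ids, identify_modified_residues(model, cfg))
  if ("attachment" %in% cfg$categories)
    ids <- c(ids, identify_attachments(model, cfg))
  if ("cross-link" %in% cfg$categories)
    ids <- c(ids, identify_crosslinks(model, cfg))
  structure(list(entry_id = model$entry_id,
                 identifications = .sort_identifications(ids),
                 scan_summary = list(
                   tolerance = cfg$bond_config$tolerance,
                   dictionary_version = cfg$dictionary$version)),
            class = "mod_report")
}

#' @export
print.mod_report <- function(x, ...) {
  cat(sprintf("Modification report for %s: %d identification(s)\n",
              x$entry_id, length(x$identifications)))
  cats <- vapply(x$identifications, function(i) i$category, character(1))
  for (ct in MOD_CATEGORIES)
    if (any(cats == ct)) cat(sprintf("  %-16s %d\n", ct, sum(cats == ct)))
  invisible(x)
}

#' @export
summary.mod_report <- function(object, ...) {
  ids <- object$identifications
  df <- data.frame(
    def_id = vapply(ids, function(i) i$def_id, character(1)),
    category = vapply(ids, function(i) i$category, character(1)),
    residues = vapply(ids, function(i)
      paste(i$residues$res_uid, collapse = ";"), character(1)),
    n_bonds = vapply(ids, function(i) nrow(i$bonds), integer(1)),
    stringsAsFactors = FALSE)
  df
}
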