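## Single-bond covalent radii (Angstrom), Cordero et al. (2008) compilation;
## high-spin values for Mn/Fe/Co.  Values are data: override via
## read_radii_table() or by editing the returned table.
.DEFAULT_RADII <- c(
  H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NA_ = NA,  # placeholder removed below; sodium written out explicitly
  SI = 1.11, P = 1.07, S = 1.05, CL = 1.02, K = 2.03, CA = 1.76,
  MN = 1.61, FE = 1.52, CO = 1.50, NI = 1.24, CU = 1.32, ZN = 1.22,
  GA = 1.22, AS = 1.19, SE = 1.20, BR = 1.20, MO = 1.54, CD = 1.44,
  I = 1.39, W = 1.62, PT = 1.36, AU = 1.36, HG = 1.32, PB = 1.46,
  LI = 1.28, MG = 1.41, AL = 1.21)

#' Default covalent-radius table
#'
#' Single-bond covalent radii for the elements commonly seen in PDB
#' entries, with a fallback radius for unknown elements.  The disulfide
#' worked example follows from these values: S + S + 0.4 tolerance gives a
#' 2.50 A threshold.
#'
#' @param default_radius Radius (A) assumed for elements not in the table.
#' @return List of class `covalent_radii` with `radius_by_element` (named
#'   numeric, Angstrom) and `default_radius`.
#' @export
default_covalent_radii <- function(default_radius = 1.5) {
  r <- .DEFAULT_RADII[!is.na(.DEFAULT_RADII)]
  r[["NA"]] <- 1.66  # sodium ("NA_" placeholder avoids the R missing value)
  covalent_radii(r, default_radius)
}

#' Construct a covalent-radius table
#'
#' @param radius_by_element Named numeric vector, element symbol -> radius
#'   in Angstrom; all radii must lie in (0.2, 3.0).
#' @param default_radius Fallback radius for unknown elements.
#' @return List of class `covalent_radii`.
#' @export
covalent_radii <- function(radius_by_element, default_radius = 1.5) {
  stopifnot(length(radius_by_element) > 0,
            all(radius_by_element > 0.2 & radius_by_element < 3.0),
            default_radius > 0.2, default_radius < 3.0)
  names(radius_by_element) <- toupper(names(radius_by_element))
  structure(list(radius_by_element = radius_by_element,
                 default_radius = default_radius),
            class = "covalent_radii")
}

#' Read a covalent-radius override table
#'
#' Two whitespace-separated columns: element symbol, radius in Angstrom.
#' Lines starting with `#` are comments.
#'
#' @param path Path to the table.
#' @param default_radius Fallback radius for unknown elements.
#' @return A [covalent_radii()] table.
#' @export
read_radii_table <- function(path, default_radius = 1.5) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("element", "radius"),
                           stringsAsFactors = FALSE)
  covalent_radii(stats::setNames(as.numeric(tab$radius),
                                 toupper(tab$element)),
                 default_radius)
}

#' Bond-detection configuration
#'
#' Two atoms are considered covalently bonded when their distance is at
#' most the sum of their covalent radii plus `tolerance`, and at least
#' `min_distance` (a lower cutoff rejecting duplicated/overlapping
#' coordinate artifacts).
#'
#' @param tolerance Distance tolerance in Angstrom added to the radius sum
#'   (default 0.4).
#' @param radii A [covalent_radii()] table.
#' @param min_distance Lower distance cutoff in Angstrom (default 0.5).
#' @return List of class `bond_config`.
#' @export
bond_config <- function(tolerance = 0.4, radii = default_covalent_radii(),
                        min_distance = 0.5) {
  stopifnot(tolerance >= 0, min_distance > 0,
            inherits(radii, "covalent_radii"))
  structure(list(tolerance = tolerance, radii = radii,
                 min_distance = min_distance),
            class = "bond_config")
}

## Vectorised radius lookup with fallback + one warning per unknown element.
.radii_for <- function(elements, radii) {
  r <- radii$radius_by_element[elements]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(elements[unknown]), collapse = ", "),
            "; using default radius ", radii$default_radius)
    r[unknown] <- radii$default_radius
  }
  unname(r)
}

#' Covalent-bond decision for one atom pair
#'
#' @param a,b Atom records: lists or one-row data frames with fields
#'   `element`, `x`, `y`, `z`.
#' @param cfg A [bond_config()].
#' @return `TRUE` iff `min_distance <= ||a-b|| <= r(a) + r(b) + tolerance`.
#' @export
is_bonded <- function(a, b, cfg = bond_config()) {
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  thr <- .radii_for(toupper(a$element), cfg$radii) +
    .radii_for(toupper(b$element), cfg$radii) + cfg$tolerance
  d >= cfg$min_distance & d <= thr
}

## Lexicographic "tuple1 < tuple2" on (chain, seq_id, insert, atom name),
## vectorised; used to canonicalise unordered atom pairs.
.pair_swap_needed <- function(c1, s1, i1, n1, c2, s2, i2, n2) {
  lt <- (c2 < c1) |
    (c2 == c1 & s2 < s1) |
    (c2 == c1 & s2 == s1 & i2 < i1) |
    (c2 == c1 & s2 == s1 & i2 == i1 & n2 < n1)
  lt
}

#' Find all bonded atom pairs between two selections
#'
#' Grid-accelerated close-pair search: atoms are binned into a uniform
#' spatial grid with cell edge `2 * max(radius) + tolerance` (the largest
#' possible bond threshold), so only the 27 neighbouring cells of each atom
#' need inspection.  The result is defined by the brute-force all-pairs
#' criterion: exactly those cross-selection pairs, not within one residue,
#' that satisfy [is_bonded()].  Hydrogens are excluded.  Each unordered
#' pair is reported once in canonical orientation (endpoint 1 is the
#' lexicographically smaller (chain, seq_id, insertion, atom name)) and
#' rows are sorted on the same key.
#'
#' @param model A [parse_structure()] model.
#' @param cfg A [bond_config()].
#' @param group_a,group_b Integer row indices into `model$atoms`.
#' @return Data frame of detected bonds: atom identity columns for both
#'   endpoints (`chain`, `seq_id`, `insert`, `res_uid`, `code`, `name`
#'   suffixed 1/2), `distance` and `threshold` in Angstrom, plus the atom
#'   row indices `idx1`/`idx2`.
#' @export
find_close_pairs <- function(model, cfg, group_a, group_b) {
  at <- model$atoms
  group_a <- group_a[!at$is_hydrogen[group_a]]
  group_b <- group_b[!at$is_hydrogen[group_b]]
  if (length(group_a) == 0L || length(group_b) == 0L)
    return(.empty_bonds())

  rad <- cfg$radii
  r_a <- .radii_for(at$element[group_a], rad)
  r_b <- .radii_for(at$element[group_b], rad)
  edge <- 2 * max(rad$radius_by_element, rad$default_radius) + cfg$tolerance

  ## bin group_b into grid cells
  cell <- function(idx) cbind(floor(at$x[idx] / edge),
                              floor(at$y[idx] / edge),
                              floor(at$z[idx] / edge))
  cb <- cell(group_b)
  key_b <- paste(cb[, 1], cb[, 2], cb[, 3])
  bmap <- split(seq_along(group_b), key_b)

  ca <- cell(group_a)
  hits_i <- integer(0); hits_j <- integer(0); hits_d <- numeric(0)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (k in seq_along(group_a)) {
    keys <- paste(ca[k, 1] + off[, 1], ca[k, 2] + off[, 2], ca[k, 3] + off[, 3])
    cand <- unlist(bmap[keys], use.names = FALSE)
    if (length(cand) == 0L) next
    ai <- group_a[k]; bi <- group_b[cand]
    d <- sqrt((at$x[bi] - at$x[ai])^2 + (at$y[bi] - at$y[ai])^2 +
              (at$z[bi] - at$z[ai])^2)
    thr <- r_a[k] + r_b[cand] + cfg$tolerance
    ok <- d >= cfg$min_distance & d <= thr &
      at$res_uid[bi] != at$res_uid[ai]
    if (any(ok)) {
      hits_i <- c(hits_i, rep.int(ai, sum(ok)))
      hits_j <- c(hits_j, bi[ok])
      hits_d <- c(hits_d, d[ok])
    }
  }
  if (length(hits_i) == 0L) return(.empty_bonds())

  thr_all <- .radii_for(at$element[hits_i], rad) +
    .radii_for(at$element[hits_j], rad) + cfg$tolerance

  ## canonical orientation, then de-duplicate pairs seen from both sides
  swap <- .pair_swap_needed(at$chain[hits_i], at$seq_id[hits_i],
                            at$insert[hits_i], at$name[hits_i],
                            at$chain[hits_j], at$seq_id[hits_j],
                            at$insert[hits_j], at$name[hits_j])
  i1 <- ifelse(swap, hits_j, hits_i)
  i2 <- ifelse(swap, hits_i, hits_j)
  pair_key <- paste(i1, i2)
  keep <- !duplicated(pair_key)
  i1 <- i1[keep]; i2 <- i2[keep]
  d <- hits_d[keep]; thr_all <- thr_all[keep]

  out <- data.frame(
    chain1 = at$chain[i1], seq1 = at$seq_id[i1], ins1 = at$insert[i1],
    res_uid1 = at$res_uid[i1], code1 = at$code[i1], atom1 = at$name[i1],
    chain2 = at$chain[i2], seq2 = at$seq_id[i2], ins2 = at$insert[i2],
    res_uid2 = at$res_uid[i2], code2 = at$code[i2], atom2 = at$name[i2],
    distance = d, threshold = thr_all,
    idx1 = i1, idx2 = i2,
    stringsAsFactors = FALSE)
  out <- out[order(out$chain1, out$seq1, out$ins1, out$atom1,
                   out$chain2, out$seq2, out$ins2, out$atom2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_bonds <- function() {
  data.frame(chain1 = character(), seq1 = integer(), ins1 = character(),
             res_uid1 = character(), code1 = character(), atom1 = character(),
             chain2 = character(), seq2 = integer(), ins2 = character(),
             res_uid2 = character(), code2 = character(), atom2 = character(),
             distance = numeric(), threshold = numeric(),
             idx1 = integer(), idx2 = integer(),
             stringsAsFactors = FALSE)
}
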