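# Ground-truth interhelical contact labels from 3D coordinates, under three
# distance definitions:
#   I   minimum heavy-atom (side chain or backbone) distance < 5.5 A (strict),
#   II  some heavy-atom pair within the sum of the two van der Waals radii
#       plus 0.6 A (inclusive),
#   III C-beta to C-beta distance (C-alpha for glycine) <= 8 A (inclusive).
# Definition I is the default: it is the most restrictive of the three.

#' Bundled van der Waals radius table
#'
#' A compact table in the spirit of the Li-Nussinov atomic radii: a few
#' atom-name classes layered over per-element defaults (carbon 1.7, nitrogen
#' 1.55, oxygen 1.52, sulfur 1.8, phosphorus 1.8 A). Atom names not matched
#' by a class fall back to their element radius; an unknown element raises a
#' lookup error.
#'
#' @return Object of class `ihrc_vdw_table`: list with `element` and
#'   `class` named radius vectors (Angstrom).
#' @export
vdw_radius_table <- function() {
  structure(list(
    element = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90),
    class = c(
      # backbone carbonyl carbon and oxygen are slightly smaller than the
      # aliphatic defaults
      "C"  = 1.61, "O"  = 1.42,
      # backbone amide nitrogen
      "N"  = 1.64)
  ), class = "ihrc_vdw_table")
}

vdw_radius <- function(name, element, table, warn_env = NULL) {
  r <- unname(table$class[name])
  hit <- !is.na(r)
  fe <- unname(table$element[element])
  if (anyNA(fe[!hit]))
    abort(sprintf("no van der Waals radius for element '%s'",
                  element[!hit][is.na(fe[!hit])][1]), "ihrc_lookup_error")
  r[!hit] <- fe[!hit]
  r
}

#' Minimum heavy-atom distance between two residues
#'
#' @param resA,resB Residue atom sets as returned by the structure reader:
#'   lists with an `xyz` coordinate matrix (and `name`/`element` vectors).
#' @return Minimum Euclidean distance (Angstrom) over all heavy-atom pairs.
#' @export
min_heavy_atom_distance <- function(resA, resB) {
  a <- resA$xyz; b <- resB$xyz
  if (!nrow(a) || !nrow(b))
    abort("residue has no heavy atoms", "ihrc_missing_atom_error")
  # squared distances via the Gram expansion; exact enough at this scale
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Contact, definition I: heavy-atom minimum distance < 5.5 A (strict)
#'
#' @inheritParams min_heavy_atom_distance
#' @return Logical flag.
#' @export
contact_def1 <- function(resA, resB) {
  min_heavy_atom_distance(resA, resB) < 5.5
}

#' Contact, definition II: within vdW-radius sum plus 0.6 A
#'
#' True when some heavy-atom pair lies at distance no greater than the sum
#' of the two atoms' van der Waals radii plus a 0.6 A threshold.
#'
#' @inheritParams min_heavy_atom_distance
#' @param table A [vdw_radius_table()].
#' @return Logical flag.
#' @export
contact_def2 <- function(resA, resB, table = vdw_radius_table()) {
  ra <- vdw_radius(resA$name, resA$element, table)
  rb <- vdw_radius(resB$name, resB$element, table)
  d2 <- outer(rowSums(resA$xyz^2), rowSums(resB$xyz^2), "+") -
    2 * tcrossprod(resA$xyz, resB$xyz)
  cutoff <- outer(ra, rb, "+") + 0.6
  any(sqrt(pmax(d2, 0)) <= cutoff)
}

cb_coord <- function(res, code) {
  want <- if (identical(code, "G")) "CA" else "CB"
  k <- match(want, res$name)
  if (is.na(k)) return(NULL)
  res$xyz[k, ]
}

#' Contact, definition III: C-beta distance <= 8 A (C-alpha for glycine)
#'
#' @inheritParams min_heavy_atom_distance
#' @param codeA,codeB One-letter residue codes (glycine switches to C-alpha).
#' @return Logical flag.
#' @export
contact_def3 <- function(resA, resB, codeA = "X", codeB = "X") {
  a <- cb_coord(resA, codeA); b <- cb_coord(resB, codeB)
  if (is.null(a) || is.null(b))
    abort("required C-beta (or glycine C-alpha) atom missing",
          "ihrc_missing_atom_error")
  sqrt(sum((a - b)^2)) <= 8.0
}

#' Label interhelical contacts from coordinates
#'
#' Evaluates every interhelical candidate pair (both residues on `H`
#' segments, different segments) under one distance definition and collects
#' the positives. Residues without coordinates — and, under definition III,
#' residues missing the required C-beta — are skipped with a warning rather
#' than aborting.
#'
#' @param struct An `ihrc_structure` whose residue numbers index into
#'   `[1, L]` of the topology.
#' @param topo An `ihrc_topology` with at least 2 helix segments.
#' @param definition `"I"` (default), `"II"`, or `"III"`.
#' @param table vdW radius table for definition II.
#' @return Object of class `ihrc_contact_map`: list with `L`, `contacts`
#'   (two-column matrix `i < j`), `definition`.
#' @export
label_contacts <- function(struct, topo,
                           definition = c("I", "II", "III"),
                           table = vdw_radius_table()) {
  definition <- match.arg(definition)
  L <- topo$length
  if (any(struct$residues$resseq < 1L | struct$residues$resseq > L))
    abort("structure residue numbers do not map into [1, L] of the topology",
          "ihrc_alignment_error")
  pairs <- enumerate_candidate_pairs(topo)
  have <- struct$residues$resseq
  codes <- stats::setNames(struct$residues$code, have)
  atoms <- lapply(have, function(r) residue_atoms(struct, r))
  names(atoms) <- have
  hits <- logical(nrow(pairs))
  skipped <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ra <- atoms[[as.character(i)]]; rb <- atoms[[as.character(j)]]
    if (is.null(ra) || is.null(rb)) { skipped <- skipped + 1L; next }
    hits[k] <- switch(definition,
      I  = contact_def1(ra, rb),
      II = contact_def2(ra, rb, table),
      III = {
        a <- cb_coord(ra, codes[[as.character(i)]])
        b <- cb_coord(rb, codes[[as.character(j)]])
        if (is.null(a) || is.null(b)) { skipped <- skipped + 1L; FALSE }
        else sqrt(sum((a - b)^2)) <= 8.0
      })
  }
  if (skipped > 0L)
    warning(sprintf("%d candidate pair(s) skipped for missing atoms", skipped),
            call. = FALSE)
  structure(list(L = L, contacts = pairs[hits, , drop = FALSE],
                 definition = definition),
            class = "ihrc_contact_map")
}

#' @export
print.ihrc_contact_map <- function(x, ...) {
  cat(sprintf("<ihrc_contact_map> definition %s: %d contact(s) over L = %d\n",
              x$definition, nrow(x$contacts), x$L))
  invisible(x)
}

#' Export a contact map in the pair-list TSV dialect
#'
#' Contacts are written with probability 1 and label 1, so ground truth and
#' predictions share one file format.
#'
#' @param cmap An `ihrc_contact_map`.
#' @param path Output path.
#' @export
write_contact_map <- function(cmap, path) {
  n <- nrow(cmap$contacts)
  write_pair_list(path, data.frame(i = cmap$contacts[, 1],
                                   j = cmap$contacts[, 2],
                                   probability = rep(1, n),
                                   label = rep(1L, n)))
}
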