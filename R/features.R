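# Per-residue feature tracks and the dual sliding-window pair featurizer.
#
# Three tracks of length L feed the classifier:
#   E — evolutionary conservation (per-position information content, bits),
#   T — digitized membrane topology (H -> 2, o/O -> 1, i/I -> 0),
#   R — within-helix relative position (alternating direction, -1 off-helix).
# A candidate pair (i, j) is described by the 31-element vector
#   V = (C_ij, (E,T,R)_{i-2..i+2}, (E,T,R)_{j-2..j+2})
# where C_ij is the z-standardized covariation score and each window spans
# the residue plus its 2 upstream and 2 downstream neighbours.

TOPOLOGY_DIGITS <- c(i = 0, o = 1, H = 2)

#' Parse a membrane topology string
#'
#' Accepted characters: `H`/`h` (membrane-spanning helix), `i`/`I` (inside),
#' `o`/`O` (outside). Maximal runs of `H` become helix segments with ordinals
#' numbered 1..n from the N-terminus.
#'
#' @param codes Topology string, one character per residue.
#' @return Object of class `ihrc_topology`: `codes` (normalized string),
#'   `length`, and `segments` (data frame `start`, `end`, `ordinal`, 1-based
#'   inclusive).
#' @export
parse_topology <- function(codes) {
  if (!is.character(codes) || length(codes) != 1L || !nzchar(codes))
    abort("topology must be a single non-empty string", "ihrc_parse_error")
  bad <- regexpr("[^HhiIoO]", codes)
  if (bad > 0)
    abort(sprintf("illegal topology character '%s' at position %d",
                  substring(codes, bad, bad), bad), "ihrc_parse_error")
  norm <- chartr("hIO", "Hio", codes)
  ch <- strsplit(norm, "")[[1]]
  r <- rle(ch == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hel <- which(r$values)
  segments <- data.frame(start = starts[hel], end = ends[hel],
                         ordinal = seq_along(hel))
  structure(list(codes = norm, length = length(ch), segments = segments),
            class = "ihrc_topology")
}

#' @export
print.ihrc_topology <- function(x, ...) {
  cat(sprintf("<ihrc_topology> %d residues, %d helix segment(s)\n",
              x$length, nrow(x$segments)))
  invisible(x)
}

#' Digitize a topology string into the T track
#'
#' Fixed mapping `H -> 2`, `o/O -> 1`, `i/I -> 0`. The labels are arbitrary
#' but frozen; the classifier is invariant to the coding up to retraining.
#'
#' @param topo An `ihrc_topology`.
#' @return Integer vector of length L.
#' @export
digitize_topology <- function(topo) {
  unname(TOPOLOGY_DIGITS[strsplit(topo$codes, "")[[1]]])
}

#' Within-helix relative position (R track)
#'
#' Non-helix residues get `-1`. Odd-ordinal helixes are numbered 1, 2, 3, ...
#' from their N-terminal residue; even-ordinal helixes are numbered 1, 2,
#' 3, ... from their C-terminal residue. Because consecutive transmembrane
#' helixes cross the membrane in alternating directions, residues with
#' similar relative positions on neighbouring helixes sit near the same
#' membrane side.
#'
#' @param topo An `ihrc_topology`.
#' @return Integer vector of length L.
#' @export
relative_positions <- function(topo) {
  r <- rep(-1L, topo$length)
  seg <- topo$segments
  for (k in seq_len(nrow(seg))) {
    idx <- seg$start[k]:seg$end[k]
    vals <- seq_along(idx)
    if (seg$ordinal[k] %% 2L == 0L) vals <- rev(vals)
    r[idx] <- vals
  }
  r
}

#' Per-residue conservation scalar (E track)
#'
#' The per-position information content of the PSSM profile: the relative
#' entropy, in bits, of the position's implied residue distribution against
#' the uniform background. A fully conserved position scores
#' `log2(20) ~ 4.32` bits; an uninformative one scores 0.
#'
#' @param pssm An [pssm_profile()].
#' @param L Expected sequence length; checked when supplied.
#' @return Numeric vector of length L, finite and non-negative.
#' @export
conservation_scalar <- function(pssm, L = NULL) {
  if (!inherits(pssm, "ihrc_pssm"))
    abort("expected an ihrc_pssm", "ihrc_contract_error")
  if (!is.null(L) && pssm$length != L)
    abort(sprintf("PSSM length %d disagrees with sequence length %d",
                  pssm$length, L), "ihrc_shape_error")
  pmax(pssm$info, 0)
}

#' Assemble the three per-residue feature tracks
#'
#' @param pssm An [pssm_profile()].
#' @param topo An `ihrc_topology` of matching length.
#' @return Object of class `ihrc_tracks`: list with `E`, `T`, `R`, `L`.
#' @export
feature_tracks <- function(pssm, topo) {
  E <- conservation_scalar(pssm, L = topo$length)
  structure(list(E = E, T = digitize_topology(topo),
                 R = relative_positions(topo), L = topo$length),
            class = "ihrc_tracks")
}

#' Enumerate interhelical candidate pairs
#'
#' All pairs `(i, j)`, `i < j`, with both residues coded `H` and lying on
#' different helix segments. Intra-helix and non-membrane pairs are
#' excluded; with fewer than two helix segments the result is empty.
#'
#' @param topo An `ihrc_topology`.
#' @param all_pairs When `TRUE`, lift the interhelical restriction and
#'   return every pair `i < j` over the full sequence.
#' @return Two-column integer matrix (`i`, `j`).
#' @export
enumerate_candidate_pairs <- function(topo, all_pairs = FALSE) {
  if (all_pairs) {
    L <- topo$length
    if (L < 2L) return(cbind(i = integer(), j = integer()))
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    return(cbind(i = idx[, 1], j = idx[, 2])[order(idx[, 1], idx[, 2]), ,
                                             drop = FALSE])
  }
  seg <- topo$segments
  if (nrow(seg) < 2L) return(cbind(i = integer(), j = integer()))
  out <- list()
  for (a in seq_len(nrow(seg) - 1L)) {
    for (b in seq.int(a + 1L, nrow(seg))) {
      g <- expand.grid(i = seg$start[a]:seg$end[a],
                       j = seg$start[b]:seg$end[b])
      out[[length(out) + 1L]] <- as.matrix(g)
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Build the 31-element pair feature vector
#'
#' Element order: the z-standardized covariation score `C[i, j]`, then five
#' `(E, T, R)` triplets for the window `i-2 .. i+2`, then five for
#' `j-2 .. j+2`. Window positions falling outside `[1, L]` contribute the
#' sentinel triplet `(0, -1, -1)` (`-1` is already the off-membrane code of
#' the R track).
#'
#' @param i,j Residue positions, 1-based, `i != j`.
#' @param tracks An `ihrc_tracks`.
#' @param cov A z-standardized `ihrc_covmat` of matching dimension.
#' @return Numeric vector of length 31.
#' @export
build_pair_vector <- function(i, j, tracks, cov) {
  L <- tracks$L
  if (i == j) abort("pair positions must differ (i != j)",
                    "ihrc_contract_error")
  if (i < 1L || i > L || j < 1L || j > L)
    abort(sprintf("pair (%d, %d) outside [1, %d]", i, j, L),
          "ihrc_index_error")
  if (!isTRUE(cov$standardized))
    abort("covariation matrix must be z-standardized before featurization",
          "ihrc_contract_error")
  if (cov$L != L)
    abort("covariation matrix dimension disagrees with track length",
          "ihrc_shape_error")
  window <- function(center) {
    pos <- (center - 2L):(center + 2L)
    inside <- pos >= 1L & pos <= L
    trip <- matrix(rep(c(0, -1, -1), 5), nrow = 3)   # sentinel columns
    trip[1, inside] <- tracks$E[pos[inside]]
    trip[2, inside] <- tracks$T[pos[inside]]
    trip[3, inside] <- tracks$R[pos[inside]]
    as.numeric(trip)
  }
  c(cov$scores[i, j], window(i), window(j))
}

#' Pair feature matrix for a set of candidate pairs
#'
#' @param pairs Two-column matrix of `(i, j)` positions.
#' @param tracks An `ihrc_tracks`.
#' @param cov A z-standardized `ihrc_covmat`.
#' @return Numeric matrix, one 31-element row per pair.
#' @export
build_pair_matrix <- function(pairs, tracks, cov) {
  if (!nrow(pairs)) return(matrix(numeric(), 0L, 31L))
  t(apply(pairs, 1L, function(p)
    build_pair_vector(p[1], p[2], tracks, cov)))
}

#' Compute a PSSM profile from a multiple alignment
#'
#' Stand-in for profile-search output when only the alignment is available:
#' per-column residue frequencies over ungapped rows give the information
#' content exactly (no pseudocount), while the log-odds scores use a single
#' pseudocount over a uniform background, rounded to integers in half-bit
#' units to match the parsed-file dialect.
#'
#' @param aln An [msa()] object; the first row is the query.
#' @return An [pssm_profile()] of length `ncols`.
#' @export
pssm_from_msa <- function(aln) {
  m <- msa_matrix(aln)
  L <- ncol(m)
  scores <- matrix(0L, L, 20L)
  info <- numeric(L)
  bg <- 1 / 20
  for (k in seq_len(L)) {
    col <- m[, k]
    col <- col[col != "-" & col %in% AMINO_ACIDS]
    n <- length(col)
    cnt <- table(factor(col, levels = AMINO_ACIDS))
    if (n > 0) {
      p <- as.numeric(cnt) / n
      info[k] <- sum(ifelse(p > 0, p * log2(p / bg), 0))
      psc <- (as.numeric(cnt) + bg) / (n + 1)   # single pseudocount
      scores[k, ] <- as.integer(round(2 * log2(psc / bg)))
    }
  }
  pssm_profile(scores, info = info,
               query = paste(m[1, ], collapse = ""))
}
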