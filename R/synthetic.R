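# Synthetic fixtures with known planted structure: multiple alignments with
# coevolving column pairs, idealized antiparallel helix-bundle coordinates,
# and end-to-end training sets where the planted couplings sit exactly at
# the geometric contact pairs. Every generator is a pure function of its
# seed.

# Background residue frequencies, roughly database-like (BLOSUM-style), so
# conservation/information content is non-degenerate. Order: AMINO_ACIDS.
BACKGROUND_FREQS <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047, G = 0.074,
  H = 0.026, I = 0.068, K = 0.058, L = 0.099, M = 0.025, N = 0.045,
  P = 0.039, Q = 0.034, R = 0.052, S = 0.057, T = 0.051, V = 0.073,
  W = 0.013, Y = 0.032)

#' Specification of the synthetic world
#'
#' Fixes the generator once: 2 antiparallel transmembrane helixes of 5
#' residues at 9 Angstrom axis separation, flanked by 4-residue loops;
#' 64-row alignments; perfectly coupled planted pairs (`p_couple = 1`).
#' Helix geometry uses the ideal alpha-helical rise (1.5 A/residue) and
#' twist (100 deg/residue), a C-alpha ring of radius `side_chain_radius`
#' (2.3 A, the canonical helical radius) and a single pseudo-side-chain
#' atom 1.5 A further out along the radial direction.
#'
#' @param seed Master seed; per-protein seeds are derived from it.
#' @param n_proteins Number of pseudo-proteins in a training set.
#' @param n_seqs Alignment depth (rows per MSA).
#' @param p_couple Coupling probability of a planted column pair in `[0,1]`.
#' @param planted_pairs Two-column matrix of column indices to couple
#'   (`NULL` = none for a standalone MSA; training sets plant at contacts).
#' @param n_helices,residues_per_helix,loop_length Topology layout.
#' @param axis_separation Distance between neighbouring helix axes (A, > 0).
#' @param rise,twist,side_chain_radius Helix geometry (A, degrees, A).
#' @return Object of class `ihrc_synth_spec`; field `length` is the derived
#'   sequence length.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_proteins = 200L,
                           n_seqs = 64L,
                           p_couple = 1,
                           planted_pairs = NULL,
                           n_helices = 2L,
                           residues_per_helix = 5L,
                           loop_length = 4L,
                           axis_separation = 9,
                           rise = 1.5,
                           twist = 100,
                           side_chain_radius = 2.3) {
  if (p_couple < 0 || p_couple > 1)
    abort("p_couple must lie in [0, 1]", "ihrc_config_error")
  if (axis_separation < 1)
    abort("axis separation below 1 A would overlap the helixes",
          "ihrc_config_error")
  spec <- list(seed = stopifnot_scalar_int(seed, "seed"),
               n_proteins = stopifnot_scalar_int(n_proteins, "n_proteins"),
               n_seqs = stopifnot_scalar_int(n_seqs, "n_seqs"),
               p_couple = p_couple,
               planted_pairs = planted_pairs,
               n_helices = stopifnot_scalar_int(n_helices, "n_helices"),
               residues_per_helix =
                 stopifnot_scalar_int(residues_per_helix,
                                      "residues_per_helix"),
               loop_length = stopifnot_scalar_int(loop_length, "loop_length"),
               axis_separation = axis_separation,
               rise = rise, twist = twist,
               side_chain_radius = side_chain_radius)
  spec$length <- spec$n_helices * spec$residues_per_helix +
    (spec$n_helices + 1L) * spec$loop_length
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.matrix(planted_pairs)
    if (any(planted_pairs < 1L) || any(planted_pairs > spec$length))
      abort("planted column index out of range", "ihrc_config_error")
    spec$planted_pairs <- planted_pairs
  }
  structure(spec, class = "ihrc_synth_spec")
}

# Deterministic bijection on residue codes used for coupled columns.
couple_map <- function(x) {
  k <- match(x, AMINO_ACIDS)
  AMINO_ACIDS[(k %% 20L) + 1L]
}

#' Generate a multiple alignment with planted coevolving column pairs
#'
#' Background columns are drawn independently from the fixed background
#' distribution. For each planted pair `(a, b)`, the residue in column `b`
#' is, with probability `p_couple`, the deterministic bijective image of
#' the residue in column `a`, and otherwise an independent background draw.
#'
#' @param spec An [synthetic_spec()].
#' @param query Optional query residue string (row 1); by default the query
#'   is drawn like every other row.
#' @param seed Seed (defaults to `spec$seed`).
#' @return An [msa()] object of `spec$n_seqs` rows.
#' @export
generate_msa <- function(spec, query = NULL, seed = spec$seed) {
  if (spec$n_seqs < 2L)
    abort("an alignment needs at least 2 rows", "ihrc_config_error")
  L <- spec$length
  n <- spec$n_seqs
  planted <- spec$planted_pairs
  with_seed(seed, {
    m <- matrix(sample(AMINO_ACIDS, n * L, replace = TRUE,
                       prob = BACKGROUND_FREQS[AMINO_ACIDS]),
                nrow = n)
    if (!is.null(query)) m[1, ] <- strsplit(query, "")[[1]]
    if (!is.null(planted) && nrow(planted)) {
      for (k in seq_len(nrow(planted))) {
        a <- planted[k, 1]; b <- planted[k, 2]
        coupled <- stats::runif(n) < spec$p_couple
        m[coupled, b] <- couple_map(m[coupled, a])
      }
    }
    msa(c("query", sprintf("seq%03d", seq_len(n - 1L))),
        apply(m, 1L, paste, collapse = ""))
  })
}

#' Generate an idealized antiparallel helix bundle
#'
#' Helix axes are parallel to z and spaced `axis_separation` apart along x;
#' odd helixes run N->C in +z, even helixes in -z, so consecutive helixes
#' are antiparallel with overlapping z ranges. Each helix residue carries a
#' C-alpha on the canonical helical ring and one pseudo-side-chain atom
#' (named `CB`) 1.5 A further out radially. Loop residues are parked on a
#' line far from the bundle so they can never contact it.
#'
#' @param spec An [synthetic_spec()].
#' @param seed Seed for the residue sequence draw.
#' @param sequence Optional residue string to use instead of a random one.
#' @return List with `structure` (`ihrc_structure`), `topology`
#'   (`ihrc_topology`) and `sequence` (`ihrc_sequence`).
#' @export
generate_helix_bundle <- function(spec, seed = spec$seed, sequence = NULL) {
  if (spec$n_helices < 2L)
    abort("a bundle needs at least 2 helixes", "ihrc_config_error")
  L <- spec$length
  hl <- spec$residues_per_helix
  lp <- spec$loop_length
  # each helix gets a random azimuthal phase so the residues facing the
  # neighbouring helix -- and hence the contact set -- differ per protein
  drawn <- with_seed(seed, list(
    phase = stats::runif(spec$n_helices, 0, 2 * pi),
    sequence = paste(sample(AMINO_ACIDS, L, replace = TRUE,
                            prob = BACKGROUND_FREQS[AMINO_ACIDS]),
                     collapse = "")))
  if (is.null(sequence)) sequence <- drawn$sequence
  # topology: loops alternate i / o starting inside
  codes <- character(0)
  side <- "i"
  for (k in seq_len(spec$n_helices)) {
    codes <- c(codes, strrep(side, lp), strrep("H", hl))
    side <- if (side == "i") "o" else "i"
  }
  codes <- paste0(paste(codes, collapse = ""), strrep(side, lp))
  topo <- parse_topology(codes)
  ca_r <- spec$side_chain_radius
  cb_r <- ca_r + 1.5
  rows <- list()
  add_atom <- function(resseq, name, element, x, y, z)
    rows[[length(rows) + 1L]] <<- data.frame(
      resseq = resseq, name = name, element = element, x = x, y = y, z = z)
  seg <- topo$segments
  for (k in seq_len(nrow(seg))) {
    x0 <- (k - 1) * spec$axis_separation
    for (t in seq_len(hl)) {
      g <- seg$start[k] + t - 1L
      z <- if (k %% 2L == 1L) (t - 1) * spec$rise else (hl - t) * spec$rise
      th <- drawn$phase[k] + (t - 1) * spec$twist * pi / 180
      add_atom(g, "CA", "C", x0 + ca_r * cos(th), ca_r * sin(th), z)
      add_atom(g, "CB", "C", x0 + cb_r * cos(th), cb_r * sin(th), z)
    }
  }
  loop_res <- setdiff(seq_len(L), unlist(Map(seq, seg$start, seg$end)))
  for (g in loop_res) {
    add_atom(g, "CA", "C", 0.5 * g, 30, 0)
    add_atom(g, "CB", "C", 0.5 * g, 31.5, 0)
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$resseq), , drop = FALSE]
  chseq <- strsplit(sequence, "")[[1]]
  struct <- structure(list(
    chain = "A",
    residues = data.frame(resseq = seq_len(L), code = chseq,
                          stringsAsFactors = FALSE),
    atoms = atoms), class = "ihrc_structure")
  list(structure = struct, topology = topo,
       sequence = protein_sequence("synthetic", sequence))
}

# Greedy filter: keep contact pairs until a column repeats, so each MSA
# column is coupled to at most one partner.
unique_column_pairs <- function(pairs) {
  used <- integer(0)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!(pairs[k, 1] %in% used) && !(pairs[k, 2] %in% used)) {
      keep[k] <- TRUE
      used <- c(used, pairs[k, ])
    }
  }
  pairs[keep, , drop = FALSE]
}

per_protein_seed <- function(spec, p, stream = 0L) {
  (spec$seed + 7919L * p + 104729L * stream) %% .Machine$integer.max
}

#' Generate one synthetic protein (bundle, contacts, alignment)
#'
#' Builds the helix bundle, labels its interhelical contacts under
#' definition I, plants perfectly coupled column pairs at (a column-unique
#' subset of) those contacts, and draws the alignment around the bundle's
#' sequence as query.
#'
#' @param spec An [synthetic_spec()].
#' @param p Protein index (derives the per-protein seed).
#' @return List with `id`, `bundle`, `contacts`, `alignment`, `planted`.
#' @export
generate_protein <- function(spec, p = 1L) {
  bundle <- generate_helix_bundle(spec, seed = per_protein_seed(spec, p))
  cmap <- label_contacts(bundle$structure, bundle$topology, "I")
  planted <- unique_column_pairs(cmap$contacts)
  sp <- spec
  sp$planted_pairs <- planted
  aln <- generate_msa(sp, query = bundle$sequence$residues,
                      seed = per_protein_seed(spec, p, stream = 1L))
  # the coupling map also rewrites the query row at planted columns;
  # propagate the realized query back into the bundle so sequence, MSA,
  # topology and coordinates stay mutually consistent
  realized <- aln$seqs[1]
  bundle$sequence <- protein_sequence("synthetic", realized)
  bundle$structure$residues$code <- strsplit(realized, "")[[1]]
  list(id = sprintf("P%03d", p), bundle = bundle, contacts = cmap,
       alignment = aln, planted = planted)
}

#' Generate an end-to-end training set
#'
#' For each pseudo-protein the full production pipeline runs on generated
#' inputs: covariation matrix (selected method) -> z-standardization ->
#' PSSM-derived conservation -> topology tracks -> dual-window featurizer;
#' labels come from definition-I contact labeling of the generated
#' coordinates. Because couplings are planted exactly at contact pairs,
#' the mapping the classifier must learn is present by construction.
#'
#' @param spec An [synthetic_spec()].
#' @param method Covariation method for the feature (default `"ELSC"`).
#' @param verbose Print per-protein progress.
#' @return List with `x` (pair-by-31 feature matrix), `y` (0/1 labels),
#'   `protein` (id per pair), `positive_fraction`, `spec`, `method`.
#' @export
generate_training_set <- function(spec, method = "ELSC", verbose = FALSE) {
  xs <- vector("list", spec$n_proteins)
  ys <- vector("list", spec$n_proteins)
  ids <- vector("list", spec$n_proteins)
  for (p in seq_len(spec$n_proteins)) {
    pr <- generate_protein(spec, p)
    cm <- zscore_standardize(covariation_matrix(pr$alignment, method))
    tracks <- feature_tracks(pssm_from_msa(pr$alignment), pr$bundle$topology)
    pairs <- enumerate_candidate_pairs(pr$bundle$topology)
    x <- build_pair_matrix(pairs, tracks, cm)
    key <- paste(pr$contacts$contacts[, 1], pr$contacts$contacts[, 2])
    y <- as.integer(paste(pairs[, 1], pairs[, 2]) %in% key)
    xs[[p]] <- x; ys[[p]] <- y; ids[[p]] <- rep(pr$id, nrow(pairs))
    if (verbose && p %% 25L == 0L)
      message(sprintf("generated %d/%d proteins", p, spec$n_proteins))
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  list(x = x, y = y, protein = unlist(ids),
       positive_fraction = mean(y), spec = spec, method = method)
}

#' Write one synthetic protein to disk in all pipeline input formats
#'
#' Emits `<prefix>.fasta`, `<prefix>_msa.fasta`, `<prefix>.pssm`,
#' `<prefix>.topo` (single-line topology) and `<prefix>.pdb`, plus the
#' ground-truth contacts as `<prefix>_contacts.tsv`.
#'
#' @param protein A [generate_protein()] result.
#' @param dir Output directory (created if missing).
#' @return The file prefix, invisibly.
#' @export
write_protein_files <- function(protein, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, protein$id)
  seq <- protein$bundle$sequence
  write_fasta(list(protein_sequence(protein$id, seq$residues)),
              paste0(prefix, ".fasta"))
  write_alignment(protein$alignment, paste0(prefix, "_msa.fasta"))
  write_psiblast_pssm(pssm_from_msa(protein$alignment),
                      paste0(prefix, ".pssm"))
  writeLines(protein$bundle$topology$codes, paste0(prefix, ".topo"))
  write_pdb(protein$bundle$structure, paste0(prefix, ".pdb"))
  write_contact_map(protein$contacts, paste0(prefix, "_contacts.tsv"))
  invisible(prefix)
}
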