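# Readers and writers for every on-disk format the pipeline touches:
# FASTA, aligned FASTA, PSI-BLAST ASCII PSSM, PDB ATOM records, and the two
# prediction output files (tab-separated pair list, upper-triangular matrix).
#
# All user-facing residue indices are 1-based, matching PDB numbering.

#' Construct a protein sequence record
#'
#' @param id Sequence identifier (non-empty string).
#' @param residues One-letter amino-acid string; the 20 standard codes plus
#'   `X` are accepted. Lowercase input is uppercased; `*` (stop) is stripped.
#' @return An object of class `ihrc_sequence` with fields `id` and `residues`.
#' @export
protein_sequence <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort("sequence id must be a non-empty string", "ihrc_parse_error")
  residues <- gsub("*", "", toupper(residues), fixed = TRUE)
  if (!nzchar(residues))
    abort(sprintf("sequence '%s' is empty", id), "ihrc_parse_error")
  bad <- regmatches(residues, regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", residues))
  if (length(bad) && nzchar(bad))
    abort(sprintf("sequence '%s' contains illegal residue code '%s'", id, bad),
          "ihrc_parse_error")
  structure(list(id = id, residues = residues), class = "ihrc_sequence")
}

#' @export
print.ihrc_sequence <- function(x, ...) {
  cat(sprintf("<ihrc_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

# Shared FASTA structural validation; returns parsed (id, seq) pairs.
# Errors name the offending line so malformed inputs are diagnosable.
parse_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    abort(sprintf("'%s': empty FASTA file (line 1)", path), "ihrc_parse_error")
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    abort(sprintf("'%s' line %d: expected FASTA header starting with '>'",
                  path, nonblank[1]), "ihrc_parse_error")
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    id <- sub("\\s.*$", "", sub("^>", "", trimws(lines[h])))
    if (!nzchar(id))
      abort(sprintf("'%s' line %d: malformed FASTA header (empty id)", path, h),
            "ihrc_parse_error")
  }
  # Structure is sound: delegate record assembly to Biostrings.
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  list(ids = ids, seqs = as.character(set))
}

#' Read a FASTA file
#'
#' Sequences are uppercased and `*` characters stripped; record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_sequence()] records.
#' @export
read_fasta <- function(path) {
  p <- parse_fasta_lines(path)
  Map(protein_sequence, p$ids, p$seqs, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs List of `ihrc_sequence` records.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$residues)))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a multiple sequence alignment
#'
#' @param ids Character vector of row identifiers; the first row is the query.
#' @param seqs Character vector of equal-length gapped sequences (gap `-`).
#' @return An object of class `ihrc_msa` with fields `ids`, `seqs`, `nrow`,
#'   `ncols`.
#' @export
msa <- function(ids, seqs) {
  if (length(ids) != length(seqs) || !length(ids))
    abort("alignment needs matching non-empty ids and sequences",
          "ihrc_shape_error")
  seqs <- unname(toupper(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    abort(sprintf("alignment rows have unequal lengths (%s)",
                  paste(unique(widths), collapse = ", ")), "ihrc_shape_error")
  structure(list(ids = unname(as.character(ids)), seqs = seqs,
                 nrow = length(seqs), ncols = widths[1]),
            class = "ihrc_msa")
}

#' @export
print.ihrc_msa <- function(x, ...) {
  cat(sprintf("<ihrc_msa> %d rows x %d columns, query '%s'\n",
              x$nrow, x$ncols, x$ids[1]))
  invisible(x)
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' All rows must have identical length; ragged input is rejected. The first
#' record is taken as the query sequence.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [msa()] object.
#' @export
read_alignment <- function(path) {
  p <- parse_fasta_lines(path)
  msa(p$ids, p$seqs)
}

#' Write a multiple alignment to aligned FASTA
#'
#' @param aln An `ihrc_msa`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  writeLines(rbind(paste0(">", aln$ids), aln$seqs), path)
  invisible(path)
}

#' Construct a PSSM profile
#'
#' @param scores L x 20 integer matrix of log-odds, columns ordered as
#'   `ACDEFGHIKLMNPQRSTVWY`.
#' @param info Optional L-vector of per-position information content (bits);
#'   when `NULL` it is derived from the scores (see [read_psiblast_pssm()]).
#' @param query Optional query residue string of length L.
#' @return Object of class `ihrc_pssm` with fields `length`, `scores`, `info`,
#'   `query`.
#' @export
pssm_profile <- function(scores, info = NULL, query = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    abort("PSSM must have exactly 20 score columns", "ihrc_shape_error")
  L <- nrow(scores)
  colnames(scores) <- AMINO_ACIDS
  if (is.null(info)) info <- pssm_implied_info(scores)
  if (length(info) != L)
    abort("PSSM info vector length disagrees with score rows",
          "ihrc_shape_error")
  structure(list(length = L, scores = scores, info = as.numeric(info),
                 query = query),
            class = "ihrc_pssm")
}

# Information content implied by log-odds scores: scores are taken as
# half-bit log-odds against a uniform background (the PSI-BLAST ASCII
# convention), inverted to a distribution and scored as relative entropy
# against uniform.
pssm_implied_info <- function(scores) {
  p <- 2 ^ (scores / 2) / 20
  p <- p / rowSums(p)
  rowSums(ifelse(p > 0, p * log2(20 * p), 0))
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard 44-column ASCII layout (`-out_ascii_pssm`): header
#' lines, then one row per query residue carrying the position, the residue,
#' 20 log-odds integers, 20 weighted-percentage integers, and two trailing
#' floats of which the first is the per-position information content.
#' Only the 20 log-odds columns and the information column are consumed;
#' rows carrying just the 20 log-odds integers are also accepted, in which
#' case information content is derived from the scores.
#'
#' @param path Path to the ASCII PSSM file.
#' @return An [pssm_profile()] object.
#' @export
read_psiblast_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list(); info <- numeric(); query <- character()
  expect_pos <- 1L
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 2L) next
    if (!grepl("^[0-9]+$", tok[1]) || !grepl("^[A-Z]$", tok[2])) next
    pos <- as.integer(tok[1])
    if (pos != expect_pos)
      abort(sprintf("'%s' line %d: expected position %d, found %d",
                    path, ln, expect_pos, pos), "ihrc_parse_error")
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(vals) || !(length(vals) %in% c(20L, 40L, 42L)))
      abort(sprintf("'%s' line %d: expected 20 integer score fields", path, ln),
            "ihrc_parse_error")
    rows[[expect_pos]] <- vals[1:20]
    info[expect_pos] <- if (length(vals) == 42L) vals[41] else NA_real_
    query[expect_pos] <- tok[2]
    expect_pos <- expect_pos + 1L
  }
  if (!length(rows))
    abort(sprintf("'%s': no PSSM rows found", path), "ihrc_parse_error")
  scores <- do.call(rbind, rows)
  if (anyNA(info)) info <- NULL
  pssm_profile(scores, info = info, query = paste(query, collapse = ""))
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Emits the 44-column layout accepted by [read_psiblast_pssm()]: two header
#' lines, then one row per position with the 20 log-odds integers, 20
#' placeholder percentage columns, the information content and a trailing
#' weight column.
#'
#' @param pssm An [pssm_profile()].
#' @param path Output path.
#' @export
write_psiblast_pssm <- function(pssm, path) {
  query <- if (is.null(pssm$query)) strrep("X", pssm$length) else pssm$query
  qc <- strsplit(query, "")[[1]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste(" ", paste(AMINO_ACIDS, collapse = "  "))), con)
  for (k in seq_len(pssm$length)) {
    writeLines(paste(
      sprintf("%5d %s", k, qc[k]),
      paste(sprintf("%4d", pssm$scores[k, ]), collapse = " "),
      paste(rep("   0", 20), collapse = ""),
      sprintf("%6.2f %6.2f", pssm$info[k], 0)), con)
  }
  invisible(path)
}

# ---- PDB coordinates ------------------------------------------------------

substr_trim <- function(x, a, b) trimws(substring(x, a, b))

#' Read one chain of a PDB file
#'
#' Consumes `ATOM` records of the requested chain; `HETATM` records and
#' hydrogen/deuterium atoms are dropped, alternate locations other than
#' blank or `A` are excluded, and insertion codes are rejected. The element
#' is taken from columns 77-78 when present, else inferred from the atom
#' name.
#'
#' @param path Path to a PDB-format file.
#' @param chain Single chain identifier.
#' @return Object of class `ihrc_structure` with fields `chain`,
#'   `residues` (data frame: `resseq`, `code`) and `atoms` (data frame:
#'   `resseq`, `name`, `element`, `x`, `y`, `z`).
#' @export
read_coordinates <- function(path, chain) {
  lines <- readLines(path, warn = FALSE)
  atom <- lines[startsWith(lines, "ATOM")]
  if (!length(atom))
    abort(sprintf("'%s': no ATOM records", path), "ihrc_parse_error")
  chains <- substring(atom, 22, 22)
  if (!any(chains == chain))
    abort(sprintf("chain '%s' not present in '%s' (found: %s)", chain, path,
                  paste(sort(unique(chains)), collapse = ", ")),
          "ihrc_lookup_error")
  atom <- atom[chains == chain]
  icode <- substring(atom, 27, 27)
  if (any(icode != " "))
    abort(sprintf("'%s' chain %s: insertion codes are not supported",
                  path, chain), "ihrc_parse_error")
  altloc <- substring(atom, 17, 17)
  atom <- atom[altloc %in% c(" ", "A")]
  name <- substr_trim(atom, 13, 16)
  element <- substr_trim(atom, 77, 78)
  fallback <- toupper(substring(gsub("[0-9']", "", name), 1, 1))
  element <- ifelse(nzchar(element), toupper(element), fallback)
  keep <- !(element %in% c("H", "D"))
  atom <- atom[keep]; name <- name[keep]; element <- element[keep]
  atoms <- data.frame(
    resseq  = as.integer(substr_trim(atom, 23, 26)),
    name    = name,
    element = element,
    x = as.numeric(substr_trim(atom, 31, 38)),
    y = as.numeric(substr_trim(atom, 39, 46)),
    z = as.numeric(substr_trim(atom, 47, 54)),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) ||
      any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    abort(sprintf("'%s' chain %s: non-finite coordinates", path, chain),
          "ihrc_parse_error")
  res_rows <- !duplicated(atoms$resseq)
  code3 <- substr_trim(atom, 18, 20)[res_rows]
  residues <- data.frame(resseq = atoms$resseq[res_rows],
                         code = aa3to1(code3), stringsAsFactors = FALSE)
  if (is.unsorted(residues$resseq, strictly = TRUE))
    abort(sprintf("'%s' chain %s: residue numbers not strictly increasing",
                  path, chain), "ihrc_parse_error")
  structure(list(chain = chain, residues = residues, atoms = atoms),
            class = "ihrc_structure")
}

#' @export
print.ihrc_structure <- function(x, ...) {
  cat(sprintf("<ihrc_structure> chain %s: %d residues, %d heavy atoms\n",
              x$chain, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

aa3to1 <- function(code3) {
  out <- unname(AA3[toupper(code3)])
  out[is.na(out)] <- "X"
  out
}

aa1to3 <- function(code1) {
  rev3 <- names(AA3); names(rev3) <- unname(AA3)
  out <- unname(rev3[toupper(code1)])
  out[is.na(out)] <- "UNK"
  out
}

#' Write a structure as PDB ATOM records
#'
#' Counterpart of [read_coordinates()]; used by the synthetic generators to
#' emit desk-scale fixtures in the exact dialect the reader consumes.
#'
#' @param struct An `ihrc_structure`.
#' @param path Output path.
#' @export
write_pdb <- function(struct, path) {
  at <- struct$atoms
  code <- struct$residues$code[match(at$resseq, struct$residues$resseq)]
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
    aa1to3(code), struct$chain, at$resseq, at$x, at$y, at$z, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Extract the coordinate matrix (n_atoms x 3) of one residue.
residue_atoms <- function(struct, resseq) {
  sel <- struct$atoms$resseq == resseq
  if (!any(sel))
    abort(sprintf("residue %d has no atoms in chain %s", resseq,
                  struct$chain), "ihrc_missing_atom_error")
  list(name = struct$atoms$name[sel], element = struct$atoms$element[sel],
       xyz = as.matrix(struct$atoms[sel, c("x", "y", "z")]))
}

# ---- Prediction output files ---------------------------------------------

validate_predictions <- function(predictions, L = Inf) {
  p <- as.data.frame(predictions)
  need <- c("i", "j", "probability", "label")
  if (!all(need %in% names(p)))
    abort(sprintf("predictions need columns %s", paste(need, collapse = ", ")),
          "ihrc_contract_error")
  if (nrow(p)) {
    if (any(p$i >= p$j))
      abort("prediction pairs must satisfy i < j (1-based)",
            "ihrc_contract_error")
    if (any(p$i < 1L) || any(p$j > L))
      abort(sprintf("pair index outside [1, %s]", L), "ihrc_contract_error")
    if (any(p$probability < 0 | p$probability > 1))
      abort("probabilities must lie in [0, 1]", "ihrc_contract_error")
    if (!all(p$label %in% c(0L, 1L)))
      abort("labels must be 0 or 1", "ihrc_contract_error")
  }
  p[order(p$i, p$j), , drop = FALSE]
}

#' Write the residue-pair prediction list
#'
#' Tab-separated file with one header line (`i j probability label`) and one
#' row per scored pair, ordered by ascending `(i, j)`. Indices are 1-based.
#'
#' @param path Output path.
#' @param predictions Data frame with columns `i`, `j`, `probability`,
#'   `label` (`i < j`, probability in `[0,1]`, label 0/1).
#' @export
write_pair_list <- function(path, predictions) {
  p <- validate_predictions(predictions)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("i\tj\tprobability\tlabel", con)
  if (nrow(p))
    writeLines(sprintf("%d\t%d\t%.6f\t%d", p$i, p$j, p$probability, p$label),
               con)
  invisible(path)
}

#' Read a residue-pair prediction list written by [write_pair_list()]
#'
#' @param path Path to a pair-list file.
#' @return Data frame with columns `i`, `j`, `probability`, `label`.
#' @export
read_pair_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("integer", "integer",
                                         "numeric", "integer"))
  validate_predictions(df)
}

#' Write the upper-triangular contact matrix file
#'
#' One text row per residue, `L` space-separated cells each. Cell `(i, j)`
#' with `i < j` holds the 0/1 predicted label; pairs that were not scored
#' hold `0`; the diagonal and lower triangle hold `-`.
#'
#' @param path Output path.
#' @param L Sequence length (matrix dimension).
#' @param predictions As for [write_pair_list()].
#' @export
write_contact_matrix <- function(path, L, predictions) {
  L <- stopifnot_scalar_int(L, "L")
  p <- validate_predictions(predictions, L = L)
  m <- matrix("0", L, L)
  m[lower.tri(m, diag = TRUE)] <- "-"
  if (nrow(p)) m[cbind(p$i, p$j)] <- as.character(p$label)
  writeLines(apply(m, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Read a contact-matrix file written by [write_contact_matrix()]
#'
#' @param path Path to a matrix file.
#' @return Character matrix of cells (`"0"`, `"1"`, `"-"`).
#' @export
read_contact_matrix <- function(path) {
  rows <- strsplit(readLines(path, warn = FALSE), " ", fixed = TRUE)
  L <- length(rows)
  if (any(lengths(rows) != L))
    abort(sprintf("'%s': matrix is not %d x %d", path, L, L),
          "ihrc_parse_error")
  do.call(rbind, rows)
}
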