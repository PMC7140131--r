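test_that("read_fasta parses, uppercases, strips stops and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDE", ">p2 some description", "acd", "e*"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$residues, "ACDE")
  expect_equal(recs[[2]]$id, "p2")
  expect_equal(recs[[2]]$residues, "ACDE")
})

test_that("malformed FASTA is rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_error(read_fasta(f), "line 1", class = "ihrc_parse_error")
  writeLines(c("ACDE", ">p1", "ACDE"), f)
  expect_error(read_fasta(f), "line 1", class = "ihrc_parse_error")
  writeLines(c(">p1", "ACDE", ">", "ACDE"), f)
  expect_error(read_fasta(f), "line 3", class = "ihrc_parse_error")
})

test_that("FASTA and alignment round-trip through write/read", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- list(protein_sequence("a", "ACDEF"), protein_sequence("b", "GHIKL"))
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)

  aln <- row_msa("AC-EF", "ACDEF", "AC--F")
  g <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, g)
  expect_equal(read_alignment(g), aln)
})

test_that("read_alignment enforces equal row lengths", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGHIKL", ">b", "ACDEFGHIK"), f)
  expect_error(read_alignment(f), class = "ihrc_shape_error")
  writeLines(c(">a", "ACDEFGHIKL"), f)
  one <- read_alignment(f)
  expect_equal(one$ncols, 10L)
  expect_equal(one$nrow, 1L)
})

test_that("PSI-BLAST ASCII PSSM parsing handles the toy dialects", {
  f <- withr::local_tempfile(fileext = ".pssm")
  zeros <- paste(rep("0", 20), collapse = " ")
  writeLines(c("", "header", paste("1 A", zeros), paste("2 C", zeros),
               paste("3 D", zeros)), f)
  p <- read_psiblast_pssm(f)
  expect_equal(dim(p$scores), c(3L, 20L))
  expect_true(all(p$scores == 0))
  expect_equal(p$info, rep(0, 3), tolerance = 1e-12)  # uniform implied freqs

  writeLines(c("x", paste("1 M", paste(1:20, collapse = " ")),
               paste("2 K", paste(20:1, collapse = " "))), f)
  p2 <- read_psiblast_pssm(f)
  expect_equal(unname(p2$scores[1, ]), 1:20)
  expect_equal(unname(p2$scores[2, ]), 20:1)
  expect_equal(p2$query, "MK")

  writeLines(c(paste("1 A", zeros), paste("3 C", zeros)), f)
  expect_error(read_psiblast_pssm(f), "position", class = "ihrc_parse_error")
  writeLines(paste("1 A", paste(rep("0", 19), collapse = " ")), f)
  expect_error(read_psiblast_pssm(f), "20", class = "ihrc_parse_error")
})

test_that("PSSM writer round-trips scores and information content", {
  aln <- random_msa(12, 6, seed = 3)
  p <- pssm_from_msa(aln)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_psiblast_pssm(p, f)
  p2 <- read_psiblast_pssm(f)
  expect_equal(p2$scores, p$scores, ignore_attr = TRUE)
  expect_equal(p2$info, p$info, tolerance = 0.006)  # file stores 2 decimals
})

pdb_line <- function(serial, name, res, chain, resseq, x, y, z, el,
                     altloc = " ", icode = " ") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), altloc,
          res, chain, resseq, icode, x, y, z, el)
}

test_that("read_coordinates groups heavy atoms and applies filters", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1, 0, 0, "C"),
    pdb_line(3, "CB", "ALA", "A", 1, 2, 0, 0, "C"),
    pdb_line(4, "HB1", "ALA", "A", 1, 2, 1, 0, "H"),   # hydrogen: dropped
    pdb_line(5, "N", "GLY", "A", 2, 3, 0, 0, "N"),
    pdb_line(6, "CA", "GLY", "A", 2, 4, 0, 0, "C", altloc = "A"),
    pdb_line(7, "CA", "GLY", "A", 2, 9, 9, 9, "C", altloc = "B"), # excluded
    "HETATM 8888  O   HOH A 900      0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  s <- read_coordinates(f, "A")
  expect_equal(nrow(s$residues), 2L)
  expect_equal(s$residues$code, c("A", "G"))
  expect_false(any(s$atoms$element == "H"))
  expect_equal(sum(s$atoms$resseq == 2), 2L)           # altloc B gone
  expect_error(read_coordinates(f, "B"), "chain 'B'",
               class = "ihrc_lookup_error")
})

test_that("insertion codes are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C", icode = "A"),
               "END"), f)
  expect_error(read_coordinates(f, "A"), "insertion",
               class = "ihrc_parse_error")
})

test_that("PDB writer round-trips through the reader", {
  b <- generate_helix_bundle(tiny_spec(), seed = 21)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b$structure, f)
  s <- read_coordinates(f, "A")
  expect_equal(s$residues, b$structure$residues)
  expect_equal(s$atoms$name, b$structure$atoms$name)
  expect_equal(s$atoms$x, b$structure$atoms$x, tolerance = 1e-3)
  expect_equal(s$atoms$z, b$structure$atoms$z, tolerance = 1e-3)
})

test_that("pair-list writer enforces its contract and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_list(f, data.frame(i = integer(), j = integer(),
                                probability = numeric(), label = integer()))
  expect_equal(readLines(f), "i\tj\tprobability\tlabel")

  preds <- data.frame(i = c(3L, 1L), j = c(10L, 5L),
                      probability = c(0.91, 0.2), label = c(1L, 0L))
  write_pair_list(f, preds)
  back <- read_pair_list(f)
  expect_equal(back$i, c(1L, 3L))            # (i, j) ascending
  expect_equal(back$probability, c(0.2, 0.91))
  expect_error(write_pair_list(f, data.frame(i = 5L, j = 3L,
                                             probability = 0.5, label = 1L)),
               class = "ihrc_contract_error")
  expect_error(write_pair_list(f, data.frame(i = 1L, j = 3L,
                                             probability = 1.5, label = 1L)),
               class = "ihrc_contract_error")
})

test_that("contact-matrix writer fills cells as documented", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_contact_matrix(f, 3L, data.frame(i = integer(), j = integer(),
                                         probability = numeric(),
                                         label = integer()))
  m <- read_contact_matrix(f)
  expect_equal(m[1, ], c("-", "0", "0"))
  expect_equal(diag(m), rep("-", 3))
  expect_true(all(m[lower.tri(m)] == "-"))

  preds <- data.frame(i = 1L, j = 3L, probability = 0.9, label = 1L)
  write_contact_matrix(f, 3L, preds)
  expect_equal(read_contact_matrix(f)[1, 3], "1")
  expect_error(write_contact_matrix(f, 2L, preds),
               class = "ihrc_contract_error")
})

test_that("pair list and matrix from identical predictions are consistent", {
  preds <- data.frame(i = c(1L, 2L, 1L), j = c(3L, 4L, 4L),
                      probability = c(0.9, 0.1, 0.7), label = c(1L, 0L, 1L))
  fp <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".txt")
  write_pair_list(fp, preds)
  write_contact_matrix(fm, 4L, preds)
  expect_true(check_output_consistency(fp, fm))
})
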