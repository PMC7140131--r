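covary4 <- col_msa(c("A", "A", "C", "C"), c("D", "D", "E", "E"))
indep4  <- col_msa(c("A", "A", "C", "C"), c("D", "E", "D", "E"))

test_that("column_pair_counts counts jointly over ungapped rows", {
  cts <- column_pair_counts(covary4, 1, 2)
  expect_equal(cts$n_valid, 4L)
  expect_equal(as.integer(cts$joint[cbind(c("A", "C"), c("D", "E"))]),
               c(2L, 2L))
  expect_equal(sum(cts$joint), 4L)

  gapped <- row_msa("AD", "-D", "CE", "CE")
  cts2 <- column_pair_counts(gapped, 1, 2)
  expect_equal(cts2$n_valid, 3L)

  expect_error(column_pair_counts(row_msa("-A", "-C"), 1, 2),
               class = "ihrc_degenerate_column_error")
  expect_error(column_pair_counts(covary4, 0, 2),
               class = "ihrc_config_error")
})

test_that("mutual information matches the closed-form toys", {
  expect_equal(mutual_information(covary4, 1, 2), 1.0)       # H(X)+H(Y)-H(XY)
  expect_equal(mutual_information(indep4, 1, 2), 0.0)
  const <- col_msa(c("A", "C", "A", "C"), c("D", "D", "D", "D"))
  expect_equal(mutual_information(const, 1, 2), 0.0)         # H(Y) = 0 bound
})

test_that("OMES matches the closed-form toys", {
  expect_equal(omes(covary4, 1, 2), 1.0)   # 4 cells off by 1, / n = 4
  expect_equal(omes(indep4, 1, 2), 0.0)
  same <- row_msa("AD", "AD", "AD")
  expect_equal(omes(same, 1, 2), 0.0)
})

test_that("ELSC vanishes on conserved or fully identical columns", {
  same <- row_msa("ADK", "ADK", "ADK", "ADK")
  for (p in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_equal(elsc(same, p[1], p[2]), 0.0)
  constj <- col_msa(c("A", "A", "C", "C", "A", "C"), rep("D", 6))
  expect_equal(elsc(constj, 1, 2), 0.0)
})

test_that("MI and OMES agree with brute-force oracles on random alignments", {
  for (s in 1:10) {
    aln <- random_msa(nrow = 5 + s %% 5, ncol = 8, seed = 100 + s,
                      gap_rate = ifelse(s %% 2, 0, 0.1))
    i <- 1 + s %% 4; j <- 5 + s %% 3
    expect_equal(mutual_information(aln, i, j), mi_oracle(aln, i, j),
                 tolerance = 1e-12)
    expect_equal(omes(aln, i, j), omes_oracle(aln, i, j), tolerance = 1e-12)
  }
})

test_that("ELSC agrees with the exact binomial-product oracle", {
  for (s in 1:8) {
    aln <- random_msa(nrow = 6, ncol = 4, seed = 300 + s)
    expect_equal(elsc(aln, 1, 3), elsc_oracle(aln, 1, 3), tolerance = 1e-10)
  }
})

test_that("MI is bounded by min(H(i), H(j)) and all scorers are symmetric", {
  entropy <- function(aln, i) {
    pc <- pair_columns(aln, i, i)
    p <- table(pc$a) / length(pc$a)
    -sum(p * log2(p))
  }
  for (s in 1:6) {
    aln <- random_msa(nrow = 8, ncol = 6, seed = 40 + s)
    for (fn in list(mutual_information, omes, elsc)) {
      expect_equal(fn(aln, 2, 5), fn(aln, 5, 2))
      expect_gte(fn(aln, 2, 5), 0)
    }
    expect_lte(mutual_information(aln, 2, 5),
               min(entropy(aln, 2), entropy(aln, 5)) + 1e-12)
  }
})

test_that("covariation_matrix is symmetric and carries the toy values", {
  two <- row_msa("AD", "AD", "CE", "CE")
  cm <- covariation_matrix(two, "MI")
  expect_equal(cm$scores[1, 2], cm$scores[2, 1])
  expect_equal(cm$scores[1, 2], 1.0)
  expect_true(all(is.na(diag(cm$scores))))

  aln <- random_msa(8, 6, seed = 9)
  for (m in c("ELSC", "MI", "OMES")) {
    cm2 <- covariation_matrix(aln, m)
    expect_equal(cm2$scores, t(cm2$scores))
    expect_false(cm2$standardized)
  }
  expect_error(covariation_matrix(aln, "DCA"))
  expect_error(covariation_matrix(row_msa("A", "C"), "MI"),
               class = "ihrc_config_error")
})

test_that("z-score standardization meets its contract", {
  cm <- covariation_matrix(random_msa(8, 4, seed = 2), "OMES")
  # overwrite with a known triangle {1, 2, 3}
  cm$scores[upper.tri(cm$scores)] <- c(1, 2, 3, 1, 2, 3)[1:6]
  cm$scores[lower.tri(cm$scores)] <- t(cm$scores)[lower.tri(cm$scores)]
  z <- zscore_standardize(cm)
  vals <- z$scores[upper.tri(z$scores)]
  expect_equal(sort(unique(round(vals, 4))), c(-1.2247, 0, 1.2247))
  expect_equal(mean(vals), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((vals - mean(vals))^2)), 1, tolerance = 1e-9)
  expect_true(z$standardized)
  expect_error(zscore_standardize(z), class = "ihrc_contract_error")

  cm$scores[!is.na(cm$scores)] <- 7      # constant matrix -> all zeros
  zc <- zscore_standardize(cm)
  expect_true(all(zc$scores[upper.tri(zc$scores)] == 0))
})

test_that("a planted perfectly covarying pair is the matrix maximum", {
  # ELSC needs deeper alignments than MI/OMES before the planted pair
  # dominates reliably; 48 rows is comfortably inside that regime
  sp <- synthetic_spec(seed = 77, n_seqs = 48L, p_couple = 1,
                       planted_pairs = cbind(5L, 17L))
  aln <- generate_msa(sp)
  for (m in c("ELSC", "MI", "OMES")) {
    cm <- covariation_matrix(aln, m)
    top <- which(cm$scores == max(cm$scores, na.rm = TRUE), arr.ind = TRUE)
    expect_true(any(top[, 1] == 5 & top[, 2] == 17),
                label = sprintf("planted pair is %s maximum", m))
  }
})

test_that("covariation TSV round-trips raw and standardized matrices", {
  cm <- zscore_standardize(covariation_matrix(random_msa(8, 5, seed = 4),
                                              "ELSC"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_covariation_tsv(cm, f)
  back <- read_covariation_tsv(f)
  expect_equal(back$scores, cm$scores, tolerance = 1e-9)
  expect_equal(back$method, "ELSC")
  expect_true(back$standardized)
})
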