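# Evolutionary covariation between alignment columns by three
# correlated-mutation statistics: mutual information (MI), the
# observed-minus-expected-squared statistic (OMES, Fodor-Aldrich
# normalization), and the Explicit Likelihood of Subset Covariation (ELSC).
#
# Gap handling is pairwise deletion: for a column pair only rows ungapped in
# BOTH columns enter the counts. No pseudocounts, no sequence weighting and
# no average-product correction are applied; these are documented extension
# points rather than part of the method.

msa_matrix <- function(aln) {
  matrix(unlist(strsplit(aln$seqs, "")), nrow = aln$nrow, byrow = TRUE)
}

#' Joint and marginal residue counts for one column pair
#'
#' Counts use only alignment rows where neither column carries a gap
#' (pairwise deletion).
#'
#' @param aln An [msa()] object.
#' @param i,j Column indices (1-based).
#' @return List with `joint` (contingency table of column `i` x column `j`
#'   residues), `fi`, `fj` (marginal counts), and `n_valid`.
#' @export
column_pair_counts <- function(aln, i, j) {
  m <- if (is.matrix(aln)) aln else msa_matrix(aln)
  nc <- ncol(m)
  if (i < 1L || i > nc || j < 1L || j > nc)
    abort(sprintf("column index out of range [1, %d]", nc), "ihrc_config_error")
  a <- m[, i]; b <- m[, j]
  ok <- a != "-" & b != "-"
  if (!any(ok))
    abort(sprintf("columns %d/%d have no ungapped row pair", i, j),
          "ihrc_degenerate_column_error")
  a <- a[ok]; b <- b[ok]
  list(joint = table(a, b), fi = table(a), fj = table(b),
       n_valid = sum(ok))
}

#' Mutual information between two alignment columns
#'
#' Plug-in MI over residue categories in bits (log base 2), from raw
#' frequencies without pseudocounts; zero-probability cells contribute 0.
#'
#' @inheritParams column_pair_counts
#' @return Non-negative scalar (bits).
#' @export
mutual_information <- function(aln, i, j) {
  cts <- column_pair_counts(aln, i, j)
  n <- cts$n_valid
  pxy <- cts$joint / n
  px <- rowSums(pxy); py <- colSums(pxy)
  terms <- pxy * log2(pxy / outer(px, py))
  sum(terms[pxy > 0])
}

#' Observed-minus-expected-squared covariation (OMES)
#'
#' \eqn{\sum_{x,y} (N_{obs}(x,y) - N_{exp}(x,y))^2 / N_{valid}} with
#' \eqn{N_{exp}(x,y) = N_{valid} f_i(x) f_j(y)} — the chi-squared numerator
#' normalized by the number of ungapped row pairs.
#'
#' @inheritParams column_pair_counts
#' @return Non-negative scalar.
#' @export
omes <- function(aln, i, j) {
  cts <- column_pair_counts(aln, i, j)
  n <- cts$n_valid
  obs <- cts$joint
  expd <- outer(as.numeric(cts$fi), as.numeric(cts$fj)) / n
  sum((obs - expd)^2) / n
}

# Directed ELSC score i -> j. The perturbation subset is the set of rows
# carrying the modal residue of column i (ties broken by alphabetical
# residue code). For each residue type y of column j, N_y is its count over
# all valid rows, n_y its count inside the subset, and m_y the expected
# subset count under proportional sampling, rounded half-up with
# largest-remainder repair so that sum(m_y) equals the subset size. The
# score is -ln prod_y C(N_y, n_y) / C(N_y, m_y), evaluated in log space.
elsc_directed <- function(m, i, j) {
  a <- m[, i]; b <- m[, j]
  ok <- a != "-" & b != "-"
  if (!any(ok))
    abort(sprintf("columns %d/%d have no ungapped row pair", i, j),
          "ihrc_degenerate_column_error")
  a <- a[ok]; b <- b[ok]
  fi <- table(a)
  modal <- names(fi)[fi == max(fi)][1]   # table() is alphabetical
  sub <- a == modal
  n_sub <- sum(sub)
  Ny <- table(b)
  ny <- table(factor(b[sub], levels = names(Ny)))
  my <- round_proportional(as.numeric(Ny), n_sub)
  sum(lchoose(as.numeric(Ny), my) - lchoose(as.numeric(Ny), as.numeric(ny)))
}

# Allocate `total` among categories proportionally to `counts`: half-up
# rounding, then largest-remainder repair so the allocation sums to `total`
# and never exceeds a category's count.
round_proportional <- function(counts, total) {
  x <- total * counts / sum(counts)
  m <- floor(x + 0.5)
  m <- pmin(m, counts)
  d <- total - sum(m)
  if (d != 0) {
    rem <- x - m
    ord <- if (d > 0) order(-rem, seq_along(rem)) else order(rem, seq_along(rem))
    step <- sign(d)
    for (k in ord) {
      if (d == 0) break
      cand <- m[k] + step
      if (cand >= 0 && cand <= counts[k]) {
        m[k] <- cand
        d <- d - step
      }
    }
  }
  m
}

#' Explicit Likelihood of Subset Covariation (ELSC)
#'
#' Perturbation-based covariation score: how unlikely is the residue
#' composition of column `j` inside the subset of rows carrying the modal
#' residue of column `i`, relative to proportional sampling. The directed
#' score is symmetrized as `(s(i->j) + s(j->i)) / 2`.
#'
#' @inheritParams column_pair_counts
#' @return Non-negative scalar.
#' @export
elsc <- function(aln, i, j) {
  m <- if (is.matrix(aln)) aln else msa_matrix(aln)
  (elsc_directed(m, i, j) + elsc_directed(m, j, i)) / 2
}

#' Covariation matrix over all column pairs
#'
#' @param aln An [msa()] object with at least 2 columns.
#' @param method One of `"ELSC"` (default), `"MI"`, `"OMES"`.
#' @return Object of class `ihrc_covmat`: list with `L`, symmetric `scores`
#'   matrix (diagonal `NA`), `method`, and `standardized` flag.
#' @export
covariation_matrix <- function(aln, method = c("ELSC", "MI", "OMES")) {
  method <- match.arg(toupper(method[1]), c("ELSC", "MI", "OMES"))
  if (aln$ncols < 2L)
    abort("covariation needs at least 2 alignment columns", "ihrc_config_error")
  m <- msa_matrix(aln)
  L <- ncol(m)
  scorer <- switch(method, MI = mutual_information, OMES = omes, ELSC = elsc)
  scores <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      scores[i, j] <- scores[j, i] <- scorer(m, i, j)
    }
  }
  structure(list(L = L, scores = scores, method = method,
                 standardized = FALSE),
            class = "ihrc_covmat")
}

#' @export
print.ihrc_covmat <- function(x, ...) {
  cat(sprintf("<ihrc_covmat> %s, L = %d%s\n", x$method, x$L,
              if (x$standardized) ", z-standardized" else " (raw)"))
  invisible(x)
}

#' z-score standardization of a covariation matrix
#'
#' Each defined off-diagonal entry is replaced by `(x - mean) / sd`, where
#' the mean and population standard deviation are taken over all defined
#' off-diagonal entries of this protein's matrix ("for each sequence" —
#' never pooled across proteins). A constant matrix maps to all zeros.
#'
#' @param cm An unstandardized `ihrc_covmat`.
#' @return The standardized matrix with `standardized = TRUE`.
#' @export
zscore_standardize <- function(cm) {
  if (!inherits(cm, "ihrc_covmat"))
    abort("expected an ihrc_covmat", "ihrc_contract_error")
  if (cm$standardized)
    abort("covariation matrix is already standardized", "ihrc_contract_error")
  vals <- cm$scores[upper.tri(cm$scores)]
  vals <- vals[!is.na(vals)]
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))   # population sd
  cm$scores <- if (sdev == 0) {
    ifelse(is.na(cm$scores), NA_real_, 0)
  } else {
    (cm$scores - mu) / sdev
  }
  cm$standardized <- TRUE
  cm
}

#' Export a covariation matrix as TSV
#'
#' One row per unordered pair `(i, j)`, `i < j`, with the score; the same
#' dialect is accepted back by [read_covariation_tsv()], so scores produced
#' by external covariation tools can be injected into the pipeline.
#'
#' @param cm An `ihrc_covmat`.
#' @param path Output path.
#' @export
write_covariation_tsv <- function(cm, path) {
  idx <- which(upper.tri(cm$scores), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   score = cm$scores[idx])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# method=%s standardized=%d", cm$method,
                     as.integer(cm$standardized)), con)
  writeLines("i\tj\tscore", con)
  writeLines(sprintf("%d\t%d\t%.10g", df$i, df$j, df$score), con)
  invisible(path)
}

#' Read a covariation matrix from the TSV dialect of [write_covariation_tsv()]
#'
#' @param path Path to a covariation TSV.
#' @param L Matrix dimension; inferred from the largest index when `NULL`.
#' @return An `ihrc_covmat`.
#' @export
read_covariation_tsv <- function(path, L = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[1]
  method <- sub(".*method=(\\S+).*", "\\1", meta)
  standardized <- grepl("standardized=1", meta)
  df <- utils::read.delim(textConnection(lines[-1]), header = TRUE)
  if (is.null(L)) L <- max(df$j)
  scores <- matrix(NA_real_, L, L)
  scores[cbind(df$i, df$j)] <- df$score
  scores[cbind(df$j, df$i)] <- df$score
  structure(list(L = L, scores = scores, method = method,
                 standardized = standardized),
            class = "ihrc_covmat")
}
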