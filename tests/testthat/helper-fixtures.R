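# Shared fixtures: tiny alignments, point-atom residues, brute-force oracles
# kept deliberately independent of the package's own code paths.

# Alignment from per-row strings.
row_msa <- function(...) {
  rows <- c(...)
  msa(sprintf("s%d", seq_along(rows)), rows)
}

# Alignment from per-column residue vectors (rows = length of each vector).
col_msa <- function(...) {
  cols <- list(...)
  rows <- apply(do.call(cbind, cols), 1, paste, collapse = "")
  msa(sprintf("s%d", seq_along(rows)), rows)
}

# A residue as a set of point atoms: xyz is n x 3.
point_residue <- function(xyz, name = "CB", element = "C") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  list(name = rep_len(name, n), element = rep_len(element, n), xyz = xyz)
}

# Random gapless alignment over the 20 residue codes.
random_msa <- function(nrow, ncol, seed, gap_rate = 0) {
  set.seed(seed)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(sample(letters20, nrow * ncol, replace = TRUE), nrow)
  if (gap_rate > 0)
    m[sample(length(m), round(gap_rate * length(m)))] <- "-"
  msa(sprintf("s%d", seq_len(nrow)), apply(m, 1, paste, collapse = ""))
}

# --- independent brute-force oracles --------------------------------------

LETTERS20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

pair_columns <- function(aln, i, j) {
  m <- matrix(unlist(strsplit(aln$seqs, "")), nrow = aln$nrow, byrow = TRUE)
  a <- m[, i]; b <- m[, j]
  ok <- a != "-" & b != "-"
  list(a = a[ok], b = b[ok], n = sum(ok))
}

mi_oracle <- function(aln, i, j) {
  pc <- pair_columns(aln, i, j)
  total <- 0
  for (x in LETTERS20) for (y in LETTERS20) {
    pxy <- mean(pc$a == x & pc$b == y)
    px <- mean(pc$a == x); py <- mean(pc$b == y)
    if (pxy > 0) total <- total + pxy * log2(pxy / (px * py))
  }
  total
}

omes_oracle <- function(aln, i, j) {
  pc <- pair_columns(aln, i, j)
  total <- 0
  for (x in LETTERS20) for (y in LETTERS20) {
    nobs <- sum(pc$a == x & pc$b == y)
    nexp <- pc$n * mean(pc$a == x) * mean(pc$b == y)
    if (nexp > 0) total <- total + (nobs - nexp)^2
  }
  total / pc$n
}

# Exact-arithmetic ELSC oracle: literal product of binomial coefficients via
# choose(); safe for the small row counts used in tests. Reimplements the
# modal-subset and rounding conventions with plain loops.
elsc_directed_oracle <- function(aln, i, j) {
  pc <- pair_columns(aln, i, j)
  cnt_i <- table(pc$a)
  modal <- sort(names(cnt_i)[cnt_i == max(cnt_i)])[1]
  sub <- pc$b[pc$a == modal]
  n_sub <- length(sub)
  types <- sort(unique(pc$b))
  Ny <- vapply(types, function(y) sum(pc$b == y), numeric(1))
  ny <- vapply(types, function(y) sum(sub == y), numeric(1))
  exact <- n_sub * Ny / sum(Ny)
  my <- pmin(floor(exact + 0.5), Ny)
  d <- n_sub - sum(my)
  while (d != 0) {
    rem <- exact - my
    if (d > 0) {
      feas <- which(my < Ny)
      k <- feas[which.max(rem[feas])]
      my[k] <- my[k] + 1; d <- d - 1
    } else {
      feas <- which(my > 0)
      k <- feas[which.min(rem[feas])]
      my[k] <- my[k] - 1; d <- d + 1
    }
  }
  prod_ratio <- prod(choose(Ny, ny) / choose(Ny, my))
  -log(prod_ratio)
}

elsc_oracle <- function(aln, i, j) {
  (elsc_directed_oracle(aln, i, j) + elsc_directed_oracle(aln, j, i)) / 2
}

metrics_oracle <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  list(ACC = (tp + tn) / length(pred),
       Precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       Recall = if (tp + fn == 0) 0 else tp / (tp + fn),
       MCC = if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den)
}

# Small-capacity config so unit tests train in milliseconds.
tiny_config <- function(...) {
  defaults <- list(channels = c(8L, 8L, 8L, 8L, 8L), epochs = 30L,
                   batch_size = 32L, learning_rate = 5e-3, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# A small synthetic world for pipeline-level tests.
tiny_spec <- function(n_proteins = 8L, seed = 5L, ...) {
  synthetic_spec(seed = seed, n_proteins = n_proteins, n_seqs = 32L, ...)
}
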