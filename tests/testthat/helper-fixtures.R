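# Fixture builders and independent oracles used across the suite.

# random ProteinExperiment with case/control metadata
makePE <- function(n = 20, p = 5, seed = 1, state = "standardized",
                   caseFrac = 0.5) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("P%03d", seq_len(p))))
  if (state == "raw") m <- 2^(m + 10)
  nCase <- round(n * caseFrac)
  md <- data.frame(
    sample_id = rownames(m),
    status = factor(rep(c("case", "control"), c(nCase, n - nCase)),
                    levels = c("control", "case")),
    age = round(runif(n, 45, 85), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    cohort = "OPDC",
    stringsAsFactors = FALSE)
  ProteinExperiment(m, sampleData = md, transformState = state)
}

# AUC oracle: enumerate every case-control pair, ties count one half
enumAuc <- function(scores, case) {
  s1 <- scores[case]; s0 <- scores[!case]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# TOM oracle: literal triple loop over the formula
tomOracle <- function(a) {
  p <- ncol(a)
  k <- colSums(a)
  tom <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# ORA oracle: enumerate all C(M, n) query draws from the universe and count
# those overlapping the set by at least k
oraEnum <- function(M, K, n, k) {
  draws <- combn(M, n)
  inSet <- seq_len(K)          # wlog the set is the first K elements
  hits <- apply(draws, 2, function(d) sum(d %in% inSet) >= k)
  mean(hits)
}

# independently coded cross-validated logistic AUC on fixed folds
cvLogisticOracle <- function(X, case, subset, folds) {
  pred <- numeric(length(case))
  df <- data.frame(y = as.numeric(case), X[, subset, drop = FALSE])
  for (f in unique(folds)) {
    fit <- suppressWarnings(
      glm(y ~ ., data = df[folds != f, , drop = FALSE], family = binomial()))
    pred[folds == f] <- suppressWarnings(
      predict(fit, newdata = df[folds == f, , drop = FALSE]))
  }
  enumAuc(pred, case)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
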