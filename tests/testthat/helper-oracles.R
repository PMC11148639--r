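# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Hubert-Arabie adjusted Rand index from the contingency table
adjustedRand <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force two-sided exact Wilcoxon rank-sum p-value by enumerating all
# C(n, nA) assignments of ranks to group A (no ties assumed)
enumerateRankSumP <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  wObs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  ws <- apply(combos, 2L, function(idx) sum(seq_len(n)[idx])) -
    length(a) * (length(a) + 1) / 2
  mu <- length(a) * length(b) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# brute-force two-sided Fisher p: sum of hypergeometric probabilities of all
# tables with the same margins whose probability <= observed (with the
# standard 1e-7 relative tolerance used by fisher.test)
enumerateFisherP <- function(tb) {
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(tb[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# BH step-up q-values from first principles
stepUpBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# mean silhouette width from first principles (singletons contribute 0)
bruteSilhouette <- function(d, cl) {
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- setdiff(which(cl == cl[i]), i)
    if (!length(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(d[i, cl == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# equal-block toy distance matrix: within-block 0 (plus eps), between-block 1
blockDistance <- function(blockSizes, within = 0, between = 1) {
  cl <- rep(seq_along(blockSizes), blockSizes)
  n <- length(cl)
  d <- matrix(between, n, n)
  d[outer(cl, cl, "==")] <- within
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("f", seq_len(n))
  d
}

makeRepertoire <- function(counts, sample = "s") {
  n <- length(counts)
  Repertoire(data.frame(
    v_gene = paste0("TRBV", seq_len(n)),
    j_gene = "TRBJ1-1",
    cdr3_aa = paste0("CASS", LETTERS[seq_len(n)], "F"),
    templates = counts), sample = sample)
}
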