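# Independent oracles used across tests. Each re-derives its quantity by a
# different route than the implementation under test.

# HWE exact test by direct evaluation of the conditional probability of every
# attainable heterozygote count (closed-form factorial expression; the
# implementation instead uses a ratio recurrence).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hs <- seq.int(min(nA, na) %% 2, min(nA, na), by = 2)
  lp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  pr <- exp(lp)
  obs <- pr[hs == n_Aa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Hudson's FST estimator for two populations from per-population sample
# allele frequencies, as a ratio of averages over variants.
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# ROC AUC by exhaustive positive x negative pair counting, ties as 1/2.
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Ridge in the standardized space via an augmented least-squares QR solve
# (rbind sqrt(lambda) * I), an algorithmic route independent of the
# normal-equations / dual solution used by fit_ridge.
ridge_aug_oracle <- function(X, y, lam) {
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)
  Xa <- rbind(Z, diag(sqrt(lam), ncol(Z)))
  ya <- c(yc, rep(0, ncol(Z)))
  b <- qr.coef(qr(Xa), ya)
  w <- b / scl
  list(weights = unname(w), intercept = mean(y) - sum(w * ctr))
}
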