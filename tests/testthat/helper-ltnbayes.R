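# shared fixtures and small oracles, all built in code

balanced4 <- function() ltn_tree("((u1,u2),(u3,u4));")

random_tree <- function(K, seed) {
  set.seed(seed)
  ltn_tree(ape::rtree(K))
}

random_composition <- function(K) {
  p <- stats::rgamma(K, shape = 1) + 1e-4
  p / sum(p)
}

# rank-based AUC of scores for binary labels
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (mean(r[label]) - (n1 + 1) / 2) / n0
}

# independent threshold-scan oracle for posterior-expected-FDR selection:
# try every achievable "report all PMAP >= t" set and keep the largest
# feasible one
fdr_bruteforce <- function(pmap, c) {
  best <- integer(0)
  for (t in unique(pmap)) {
    sel <- which(pmap >= t)
    if (mean(1 - pmap[sel]) <= c && length(sel) > length(best)) {
      best <- sel
    }
  }
  sort(best)
}
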