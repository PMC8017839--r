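# Independent brute-force oracles used to check the implementation.

# Exhaustive-path semantic contribution: for each ancestor a of `disease`,
# enumerate every upward path disease -> ... -> a and take the maximum of
# delta^length. Independent of the memoised recursion in the package.
oracle_contributions <- function(onto, disease, delta) {
  out <- c(1)
  names(out) <- disease
  walk <- function(term, len) {
    for (p in onto$parents[[term]]) {
      val <- delta^(len + 1L)
      if (is.na(out[p]) || val > out[p]) out[p] <<- val
      walk(p, len + 1L)
    }
  }
  walk(disease, 0L)
  out
}

# Pairwise-concordance AUC: P(score_pos > score_neg) with ties counted half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random parent-pointer DAG over n nodes: node i > 1 picks parents among
# 1..(i-1), so the edge set is acyclic by construction.
random_dag <- function(n, seed) {
  set.seed(seed)
  child <- character(0); parent <- character(0)
  ids <- paste0("n", seq_len(n))
  for (i in seq(2L, n)) {
    for (p in sample(seq_len(i - 1L), min(sample(1:2, 1L), i - 1L))) {
      child <- c(child, ids[i]); parent <- c(parent, ids[p])
    }
  }
  ipcarf:::make_ontology(child, parent)
}

# Principal angles between the column spans of two orthonormal bases,
# sine-based (Bjorck-Golub): numerically accurate for small angles, where the
# acos of the cosine formulation bottoms out at sqrt(machine eps) ~ 1e-8.
principal_angles <- function(Q1, Q2) {
  resid <- Q2 - Q1 %*% crossprod(Q1, Q2)
  asin(pmin(svd(resid)$d, 1))
}

# Small deterministic toy ontology: diamond D -> {P1, P2} -> R.
diamond_ontology <- function() {
  ipcarf:::make_ontology(c("D", "D", "P1", "P2"), c("P1", "P2", "R", "R"))
}
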