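#' Simulate a rooted disease ontology DAG
#'
#' Generates a random rooted directed acyclic graph of disease terms: one
#' root, every other term placed at a depth in `1..depth` and linked to one
#' or two parents at strictly smaller depth, so the graph is acyclic by
#' construction and every term reaches the root. Diseases are mapped to
#' non-root terms with probability weight doubling per depth level
#' (leaf-biased), without replacement.
#'
#' @param n_terms Number of ontology terms (including the root).
#' @param n_dis Number of diseases to map onto terms (`<= n_terms - 1`).
#' @param depth Maximum DAG depth (default 4).
#' @param seed Integer seed.
#' @return List with `ontology` (a `disease_ontology`) and `disease_terms`
#'   (named character vector, disease label to term id).
#' @export
simulate_ontology <- function(n_terms = 60, n_dis = 40, depth = 4, seed = 1) {
  stopifnot(n_terms >= 2L, depth >= 1L)
  if (n_dis > n_terms - 1L) {
    stop("need n_terms - 1 >= n_dis non-root terms to map diseases onto",
         call. = FALSE)
  }
  terms <- zero_pad_labels("t", n_terms)
  with_seed(seed, {
    level <- c(0L, sort(sample.int(depth, n_terms - 1L, replace = TRUE)))
    child <- character(0); parent <- character(0)
    for (i in seq(2L, n_terms)) {
      shallower <- which(level < level[i])
      n_par <- min(sample(1:2, 1L), length(shallower))
      for (p in sample(shallower)[seq_len(n_par)]) {
        child <- c(child, terms[i]); parent <- c(parent, terms[p])
      }
    }
    onto <- make_ontology(child, parent)
    w <- 2^level[-1L]
    picked <- terms[-1L][sample.int(n_terms - 1L, n_dis, prob = w)]
  })
  list(ontology = onto,
       disease_terms = setNames(picked, zero_pad_labels("d", n_dis)))
}

#' Simulate a planted-block association matrix
#'
#' lncRNAs and diseases are partitioned into `n_clusters` blocks; a pair
#' inside a matched block is associated with probability `signal`, any other
#' pair with probability `noise`. Block structure is the learnable ground
#' truth: the method's premise that similar diseases share associated lncRNAs
#' is exactly what blocks encode.
#'
#' @param n_lnc,n_dis Numbers of lncRNAs and diseases.
#' @param n_clusters Number of planted blocks (default 4).
#' @param signal Within-block association probability (default 0.6).
#' @param noise Background association probability (default 0.05).
#' @param seed Integer seed.
#' @return List with `assoc` (binary matrix), `lnc_block`, `dis_block`
#'   (integer block labels).
#' @export
simulate_associations <- function(n_lnc = 80, n_dis = 40, n_clusters = 4,
                                  signal = 0.6, noise = 0.05, seed = 1) {
  stopifnot(signal >= 0, signal <= 1, noise >= 0, noise <= 1)
  if (signal <= noise) {
    message("signal <= noise: generated associations carry no learnable structure")
  }
  lnc_block <- rep_len(seq_len(n_clusters), n_lnc)
  dis_block <- rep_len(seq_len(n_clusters), n_dis)
  p <- ifelse(outer(lnc_block, dis_block, "=="), signal, noise)
  A <- with_seed(seed,
                 matrix(rbinom(n_lnc * n_dis, 1L, p), n_lnc, n_dis))
  dimnames(A) <- list(zero_pad_labels("l", n_lnc), zero_pad_labels("d", n_dis))
  list(assoc = A, lnc_block = lnc_block, dis_block = dis_block)
}

#' Simulate a complete lncRNA-disease benchmark dataset
#'
#' Generates an ontology, a planted-block association matrix, and runs the
#' real pipeline stages (kernel similarities, semantic similarity,
#' integration, pair sampling, feature construction) so every downstream
#' component can be exercised without external data.
#'
#' @inheritParams simulate_associations
#' @inheritParams simulate_ontology
#' @param delta Semantic attenuation factor used for the semantic stage.
#' @param neg_ratio Negatives per positive in the sampled pairs.
#' @param seed Integer seed for the whole bundle.
#' @return List: `ontology`, `disease_terms`, `assoc`, `lnc_block`,
#'   `dis_block`, `sim_lnc`, `sim_dis`, `pairs`, `features`
#'   (a `pair_features`), and `config`.
#' @export
simulate_lda_data <- function(n_lnc = 80, n_dis = 40, n_terms = 60,
                              n_clusters = 4, signal = 0.6, noise = 0.05,
                              depth = 4, delta = 0.5, neg_ratio = 1,
                              seed = 42) {
  onto <- simulate_ontology(n_terms = n_terms, n_dis = n_dis, depth = depth,
                            seed = seed)
  ass <- simulate_associations(n_lnc = n_lnc, n_dis = n_dis,
                               n_clusters = n_clusters, signal = signal,
                               noise = noise, seed = seed + 1L)
  diseases <- colnames(ass$assoc)
  sem <- semantic_similarity(onto$ontology, diseases, delta = delta,
                             terms = onto$disease_terms)
  gip_dis <- gip_similarity(ass$assoc, "disease")
  sim_dis <- integrate_disease_similarity(sem, gip_dis)
  sim_lnc <- gip_similarity(ass$assoc, "lncrna")
  pairs <- sample_pairs(ass$assoc, neg_ratio = neg_ratio, seed = seed + 2L)
  feats <- pair_features(pairs, sim_lnc, sim_dis)
  list(ontology = onto$ontology, disease_terms = onto$disease_terms,
       assoc = ass$assoc, lnc_block = ass$lnc_block,
       dis_block = ass$dis_block, sim_lnc = sim_lnc, sim_dis = sim_dis,
       pairs = pairs, features = feats,
       config = list(n_lnc = n_lnc, n_dis = n_dis, n_terms = n_terms,
                     n_clusters = n_clusters, signal = signal, noise = noise,
                     depth = depth, delta = delta, neg_ratio = neg_ratio,
                     seed = seed))
}

#' Write a simulated dataset to pipeline input files
#'
#' Emits the association list (`assoc.tsv`), ontology edge list (`dag.tsv`),
#' disease-to-term mapping (`disease_terms.tsv`) and ground-truth block
#' labels (`truth.json`) in the same formats the loaders read, so the
#' file-based pipeline path is exercised end to end.
#'
#' @param bundle Output of [simulate_lda_data()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_lda_data <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(bundle$assoc == 1L, arr.ind = TRUE)
  writeLines(c("LncRNA name\tDisease name",
               paste(rownames(bundle$assoc)[idx[, 1L]],
                     colnames(bundle$assoc)[idx[, 2L]], sep = "\t")),
             file.path(dir, "assoc.tsv"))
  edges <- unlist(lapply(bundle$ontology$terms, function(t) {
    vapply(bundle$ontology$parents[[t]], function(p) paste(t, p, sep = "\t"), "")
  }))
  writeLines(c("# child\tparent", edges), file.path(dir, "dag.tsv"))
  writeLines(paste(names(bundle$disease_terms), bundle$disease_terms,
                   sep = "\t"),
             file.path(dir, "disease_terms.tsv"))
  jsonlite::write_json(list(lnc_block = bundle$lnc_block,
                            dis_block = bundle$dis_block,
                            config = bundle$config),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
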