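test_that("simulated ontologies are rooted, acyclic and reproducible", {
  out <- simulate_ontology(n_terms = 10, n_dis = 6, depth = 3, seed = 5)
  onto <- out$ontology
  expect_s3_class(onto, "disease_ontology")  # make_ontology validates acyclicity
  expect_length(onto$roots, 1L)
  # Every term reaches the root.
  for (t in onto$terms) expect_true(onto$roots %in% ancestor_terms(onto, t))
  expect_length(out$disease_terms, 6L)
  expect_false(onto$roots %in% out$disease_terms)

  out2 <- simulate_ontology(n_terms = 10, n_dis = 6, depth = 3, seed = 5)
  expect_identical(out, out2)
  expect_error(simulate_ontology(n_terms = 5, n_dis = 6), "non-root terms")
})

test_that("depth-1 star ontology gives the sibling closed form", {
  out <- simulate_ontology(n_terms = 12, n_dis = 5, depth = 1, seed = 2)
  S <- semantic_similarity(out$ontology, names(out$disease_terms),
                           delta = 0.5, model = "model1",
                           terms = out$disease_terms)
  off <- S[upper.tri(S)]
  expect_true(all(abs(off - 0.5 / 1.5) < 1e-12))
})

test_that("planted associations have block structure and expected density", {
  out <- simulate_associations(n_lnc = 12, n_dis = 8, n_clusters = 2,
                               signal = 1, noise = 0, seed = 3)
  blocks <- outer(out$lnc_block, out$dis_block, "==")
  expect_true(all(out$assoc[blocks] == 1))
  expect_true(all(out$assoc[!blocks] == 0))

  # Density matches the block-weighted expectation within 3 binomial sd.
  big <- simulate_associations(n_lnc = 100, n_dis = 60, n_clusters = 4,
                               signal = 0.6, noise = 0.05, seed = 7)
  w <- mean(outer(big$lnc_block, big$dis_block, "=="))
  p_exp <- w * 0.6 + (1 - w) * 0.05
  n_cells <- 100 * 60
  tol <- 3 * sqrt(p_exp * (1 - p_exp) / n_cells)
  expect_lt(abs(mean(big$assoc) - p_exp), tol)

  expect_message(simulate_associations(n_lnc = 6, n_dis = 4, signal = 0.3,
                                       noise = 0.3, seed = 1),
                 "no learnable structure")
})

test_that("the full synthetic bundle is seed-deterministic and coherent", {
  a <- simulate_lda_data(n_lnc = 20, n_dis = 10, n_terms = 14, seed = 17)
  b <- simulate_lda_data(n_lnc = 20, n_dis = 10, n_terms = 14, seed = 17)
  expect_identical(a$assoc, b$assoc)
  expect_identical(a$features$x, b$features$x)
  # Upstream invariants hold on the generated matrices.
  expect_equal(a$sim_dis, t(a$sim_dis), tolerance = 1e-12)
  expect_equal(unname(diag(a$sim_lnc)), rep(1, 20))
  expect_true(all(a$sim_dis >= 0 & a$sim_dis <= 1))
  expect_equal(ncol(a$features$x), 30)
})

test_that("written bundles reload identically through the package loaders", {
  bundle <- simulate_lda_data(n_lnc = 15, n_dis = 8, n_terms = 12, seed = 23)
  dir <- withr::local_tempdir()
  write_lda_data(bundle, dir)
  A <- association_matrix(suppressMessages(
    read_associations(file.path(dir, "assoc.tsv"), normalize = FALSE)))
  # The file lists positive pairs; lncRNAs/diseases with no association do
  # not round-trip, so compare the positive-cell sets.
  key <- function(M) {
    i <- which(M == 1L, arr.ind = TRUE)
    sort(paste(rownames(M)[i[, 1]], colnames(M)[i[, 2]]))
  }
  expect_identical(key(A), key(bundle$assoc))
  onto <- read_ontology(file.path(dir, "dag.tsv"))
  expect_identical(onto$terms, bundle$ontology$terms)
  expect_identical(onto$roots, bundle$ontology$roots)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$lnc_block, bundle$lnc_block)
})

test_that("cross-validated AUC increases with the planted signal gap", {
  gaps <- c(0.1, 0.3, 0.55)
  aucs <- vapply(gaps, function(gap) {
    vals <- vapply(1:3, function(s) {
      sim <- simulate_lda_data(signal = 0.05 + gap, noise = 0.05,
                               seed = 100 + s)
      cv <- cross_validate(sim$features$x, sim$features$y, folds = 10,
                           num_trees = 100, seed = s)
      mean(cv$per_fold$auc)
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(aucs) >= -0.02))
})
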