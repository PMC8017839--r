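chain_ontology <- function() ipcarf:::make_ontology(c("D", "P"), c("P", "R"))

test_that("ancestor closure covers chains, roots and diamonds", {
  onto <- chain_ontology()
  expect_setequal(ancestor_terms(onto, "D"), c("D", "P", "R"))
  expect_identical(ancestor_terms(onto, "R"), "R")
  expect_setequal(ancestor_terms(diamond_ontology(), "D"),
                  c("D", "P1", "P2", "R"))
  expect_error(ancestor_terms(onto, "nope"), "unknown term")
})

test_that("semantic contributions follow the decay recursion", {
  cm <- semantic_contributions(chain_ontology(), "D", delta = 0.5)
  expect_equal(cm$contributions, c(D = 1, P = 0.5, R = 0.25))
  expect_equal(cm$semantic_value, 1.75)

  # Diamond: shared grandparent gets the max over the two routes.
  cm2 <- semantic_contributions(diamond_ontology(), "D", delta = 0.5)
  expect_equal(cm2$contributions[c("P1", "P2", "R")],
               c(P1 = 0.5, P2 = 0.5, R = 0.25))
  expect_equal(cm2$semantic_value, 2.25)

  # Zero attenuation kills every ancestor.
  cm0 <- semantic_contributions(diamond_ontology(), "D", delta = 0)
  expect_equal(cm0$semantic_value, 1)
})

test_that("contribution recursion matches the exhaustive-path oracle", {
  for (seed in 1:40) {
    n <- sample(4:12, 1)
    onto <- random_dag(n, seed + 1000)
    disease <- sample(onto$terms, 1)
    delta <- runif(1, 0.1, 1)
    cm <- semantic_contributions(onto, disease, delta)
    oracle <- oracle_contributions(onto, disease, delta)
    expect_equal(cm$contributions[sort(names(oracle))],
                 oracle[sort(names(oracle))], tolerance = 1e-12)
  }
})

test_that("model-1 similarity: self, siblings, disjoint components", {
  sibs <- ipcarf:::make_ontology(c("D1", "D2"), c("P", "P"))
  S <- semantic_similarity(sibs, c("D1", "D2", "P"), delta = 0.5,
                           model = "model1")
  expect_equal(diag(S), c(D1 = 1, D2 = 1, P = 1))
  expect_equal(S["D1", "D2"], 1 / 3)  # (0.5 + 0.5) / (1.5 + 1.5)
  expect_equal(S, t(S))

  # Sibling closed form delta / (1 + delta), strictly increasing in delta.
  prev <- -Inf
  for (d in seq(0.1, 0.9, by = 0.1)) {
    v <- semantic_similarity(sibs, c("D1", "D2"), delta = d,
                             model = "model1")["D1", "D2"]
    expect_equal(v, d / (1 + d), tolerance = 1e-12)
    expect_gt(v, prev)
    prev <- v
  }

  # Disjoint components share no ancestor terms.
  two <- ipcarf:::make_ontology(c("A", "B"), c("RA", "RB"))
  expect_equal(semantic_similarity(two, c("A", "B"),
                                   model = "model1")["A", "B"], 0)
})

test_that("model-2 similarity matches a hand information-content computation", {
  onto <- diamond_ontology()
  diseases <- c("D", "P1", "P2")
  S <- semantic_similarity(onto, diseases, model = "model2")
  expect_equal(unname(diag(S)), rep(1, 3))

  # Hand computation: closures D->{D,P1,P2,R}, P1->{P1,R}, P2->{P2,R}.
  # Corpus frequencies over 3 diseases: D 1/3, P1 2/3, P2 2/3, R 3/3.
  ic <- c(D = -log(1 / 3), P1 = -log(2 / 3), P2 = -log(2 / 3), R = 0)
  g <- c(D = sum(ic), P1 = ic[["P1"]], P2 = ic[["P2"]])
  hand <- function(a, b, shared) sum(2 * ic[shared]) / (g[[a]] + g[[b]])
  expect_equal(S["D", "P1"], hand("D", "P1", c("P1", "R")), tolerance = 1e-12)
  expect_equal(S["D", "P2"], hand("D", "P2", c("P2", "R")), tolerance = 1e-12)
  expect_equal(S["P1", "P2"], hand("P1", "P2", "R"), tolerance = 1e-12)

  # A term shared by every disease in the corpus carries no information.
  pair <- semantic_similarity(onto, c("P1", "P2"), model = "model2")
  expect_equal(pair["P1", "P2"], 0)  # only shared term is R, IC(R) = 0
})

test_that("similarity matrices satisfy symmetry/diagonal/range invariants", {
  for (seed in 1:10) {
    onto <- random_dag(10, seed + 2000)
    diseases <- sample(onto$terms, 5)
    for (model in c("model1", "model2", "average")) {
      S <- semantic_similarity(onto, diseases, delta = runif(1, 0.1, 1),
                               model = model)
      expect_equal(S, t(S), tolerance = 1e-12)
      expect_equal(unname(diag(S)), rep(1, 5))
      expect_true(all(S >= 0 & S <= 1 + 1e-12))
    }
  }
})

test_that("combine_similarity averages element-wise and keeps the diagonal", {
  M <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(combine_similarity(M, M), M)
  ones <- matrix(1, 2, 2, dimnames = dimnames(M))
  zeros <- diag(2); dimnames(zeros) <- dimnames(M)
  avg <- combine_similarity(zeros, ones)
  expect_equal(avg["a", "b"], 0.5)
  expect_equal(unname(diag(avg)), c(1, 1))
  expect_identical(combine_similarity(M, ones, mode = "model1_only"), M)
  bad <- ones; rownames(bad) <- colnames(bad) <- c("x", "y")
  expect_error(combine_similarity(M, bad), "label mismatch")
})
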