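#' Fit the IPCARF lncRNA-disease association predictor
#'
#' End-to-end fit of the prediction pipeline on a known association catalogue:
#'
#' 1. Gaussian interaction profile kernel similarities for diseases and
#'    lncRNAs from the association matrix;
#' 2. optional disease semantic similarity from an ontology DAG
#'    ([semantic_similarity()]), averaged with the kernel similarity for
#'    ontology-covered diseases; optional lncRNA functional similarity
#'    averaged likewise;
#' 3. positive pairs plus uniformly sampled unassociated pairs, each encoded
#'    as the concatenation of its lncRNA and disease similarity rows;
#' 4. stratified k-fold cross-validation of the IPCA + random-forest stage
#'    (fitted per training fold, no leakage) for an honest performance
#'    estimate;
#' 5. a final IPCA reduction and forest fitted on all sampled pairs, used by
#'    [predict.ipcarf()] and [rank_candidates()].
#'
#' @param assoc Binary association matrix (lncRNA rows x disease columns, see
#'   [association_matrix()]), or an association table / file path accepted by
#'   [read_associations()].
#' @param ontology Optional `disease_ontology` for semantic similarity.
#' @param disease_terms Optional named character vector mapping disease labels
#'   to ontology terms; defaults to the labels themselves. Diseases without an
#'   ontology term fall back to kernel similarity alone.
#' @param functional Optional lncRNA functional similarity matrix.
#' @param delta Semantic contribution attenuation factor (default 0.5).
#' @param semantic_model `"average"`, `"model1"` or `"model2"`.
#' @param neg_ratio Sampled negatives per positive (default 1).
#' @param n_components,k IPCA size parameters (see [ipca()]).
#' @param num_trees Trees per forest (default 1500); may also be a vector, in
#'   which case it is grid-searched by inner cross-validation
#'   ([grid_search_trees()]) before the final fit.
#' @param folds Cross-validation folds (default 10); `cv = FALSE` skips the
#'   evaluation and only fits the final model.
#' @param use_ipca Set `FALSE` for the plain random-forest comparator arm.
#' @param cv Run cross-validation (default `TRUE`).
#' @param seed Integer seed controlling sampling, folds and forests.
#' @return Object of class `ipcarf` with the association matrix, integrated
#'   similarity matrices, sampled training pairs, cross-validation report
#'   (`$cv`), grid-search table (`$grid`, when requested), and the final
#'   fitted `$reduction` and `$forest`.
#' @examples
#' sim <- simulate_lda_data(n_lnc = 20, n_dis = 10, n_terms = 15, seed = 7)
#' fit <- ipcarf(sim$assoc, ontology = sim$ontology,
#'               disease_terms = sim$disease_terms,
#'               num_trees = 50, folds = 3, seed = 7)
#' fit
#' head(rank_candidates(fit, colnames(sim$assoc)[1]))
#' @export
ipcarf <- function(assoc, ontology = NULL, disease_terms = NULL,
                   functional = NULL, delta = 0.5,
                   semantic_model = c("average", "model1", "model2"),
                   neg_ratio = 1, n_components = NULL, k = NULL,
                   num_trees = 1500, folds = 10, use_ipca = TRUE,
                   cv = TRUE, seed = 1) {
  semantic_model <- match.arg(semantic_model)
  cl <- match.call()
  if (is.character(assoc)) assoc <- read_associations(assoc)
  if (is.data.frame(assoc)) assoc <- association_matrix(assoc)
  stopifnot_binary_matrix(assoc, "assoc")

  # Similarity construction.
  gip_dis <- gip_similarity(assoc, "disease")
  gip_lnc <- gip_similarity(assoc, "lncrna")
  coverage <- character(0)
  if (!is.null(ontology)) {
    diseases <- colnames(assoc)
    if (is.null(disease_terms)) disease_terms <- setNames(diseases, diseases)
    coverage <- diseases[diseases %in% names(disease_terms) &
                           disease_terms[diseases] %in% ontology$terms]
    if (length(coverage) > 0L) {
      sem <- semantic_similarity(ontology, coverage, delta = delta,
                                 model = semantic_model,
                                 terms = disease_terms)
      sem_full <- expand_similarity(sem, diseases)
      sim_dis <- integrate_disease_similarity(sem_full, gip_dis, coverage)
    } else {
      sim_dis <- gip_dis
    }
  } else {
    sim_dis <- gip_dis
  }
  sim_lnc <- integrate_lncrna_similarity(gip_lnc, functional)

  # Training pairs and features.
  pairs <- sample_pairs(assoc, neg_ratio = neg_ratio, seed = seed)
  feats <- pair_features(pairs, sim_lnc, sim_dis)

  grid <- NULL
  if (length(num_trees) > 1L) {
    grid <- grid_search_trees(feats$x, feats$y, grid = num_trees, seed = seed,
                              use_ipca = use_ipca, n_components = n_components,
                              k = k)
    num_trees <- grid$best
  }

  cv_report <- NULL
  if (isTRUE(cv)) {
    cv_report <- cross_validate(feats$x, feats$y, folds = folds,
                                num_trees = num_trees, seed = seed,
                                use_ipca = use_ipca,
                                n_components = n_components, k = k)
  }

  reduction <- if (use_ipca) ipca(feats$x, n_components = n_components, k = k)
  xfit <- if (use_ipca) predict(reduction, feats$x) else feats$x
  forest <- train_rf(xfit, feats$y, num_trees = num_trees, seed = seed)

  structure(list(assoc = assoc, sim_lnc = sim_lnc, sim_dis = sim_dis,
                 coverage = coverage, pairs = pairs, features = feats,
                 reduction = reduction, forest = forest, cv = cv_report,
                 grid = grid,
                 params = list(delta = delta, semantic_model = semantic_model,
                               neg_ratio = neg_ratio, num_trees = num_trees,
                               folds = folds, use_ipca = use_ipca,
                               seed = seed),
                 call = cl),
            class = "ipcarf")
}

# Embed a similarity matrix over a label subset into the full label set
# (zero outside the subset, unit diagonal).
expand_similarity <- function(s, labels) {
  out <- diag(1, length(labels))
  dimnames(out) <- list(labels, labels)
  out[rownames(s), colnames(s)] <- s
  out
}

#' Score lncRNA-disease pairs with a fitted model
#'
#' Builds the similarity-row feature vector of each requested pair from the
#' fitted model's integrated similarity matrices, applies the stored IPCA
#' reduction, and returns the forest's positive-class probability. Note that
#' the similarity matrices are those of the training association matrix; new
#' pairs are scored without recomputing kernels.
#'
#' @param object A fitted [ipcarf()] model.
#' @param newdata Data frame with columns `lncrna` and `disease`; defaults to
#'   the training pairs.
#' @param ... Unused.
#' @return Numeric vector of association scores in `[0, 1]`.
#' @export
predict.ipcarf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$pairs
  feats <- pair_features(newdata, object$sim_lnc, object$sim_dis)
  x <- if (!is.null(object$reduction)) predict(object$reduction, feats$x) else feats$x
  unname(rf_scores(object$forest, x))
}

#' Rank candidate lncRNAs for a disease
#'
#' Scores every lncRNA not yet associated with the disease and returns them
#' in decreasing score order (ties broken alphabetically), the model's
#' prioritised candidate list for follow-up.
#'
#' @param object A fitted [ipcarf()] model.
#' @param disease A disease label present in the association matrix.
#' @param top Optionally keep only the top `top` candidates.
#' @return Data frame with columns `rank`, `lncrna`, `score`.
#' @export
rank_candidates <- function(object, disease, top = NULL) {
  stopifnot(inherits(object, "ipcarf"))
  A <- object$assoc
  if (!disease %in% colnames(A)) stop("unknown disease: ", disease, call. = FALSE)
  cand <- rownames(A)[A[, disease] == 0L]
  if (length(cand) == 0L) {
    return(data.frame(rank = integer(0), lncrna = character(0),
                      score = numeric(0)))
  }
  sc <- predict(object, data.frame(lncrna = cand, disease = disease,
                                   stringsAsFactors = FALSE))
  ord <- order(-sc, cand)
  out <- data.frame(rank = seq_along(cand), lncrna = cand[ord],
                    score = sc[ord], stringsAsFactors = FALSE)
  if (!is.null(top)) out <- head(out, top)
  out
}

#' @export
print.ipcarf <- function(x, ...) {
  cat("IPCARF lncRNA-disease association model\n")
  cat(sprintf("  associations: %d lncRNAs x %d diseases, %d positives\n",
              nrow(x$assoc), ncol(x$assoc), sum(x$assoc)))
  cat(sprintf("  training pairs: %d (%d positive / %d negative)\n",
              nrow(x$pairs), sum(x$pairs$label == 1L), sum(x$pairs$label == 0L)))
  if (!is.null(x$reduction)) {
    cat(sprintf("  reduction: %d -> %d components\n",
                x$reduction$p, x$reduction$n_components))
  } else cat("  reduction: none (RF only)\n")
  cat(sprintf("  forest: %d trees\n", x$params$num_trees))
  if (!is.null(x$cv)) {
    auc <- x$cv$aggregate$mean[x$cv$aggregate$metric == "auc"]
    cat(sprintf("  %d-fold CV mean AUC: %.4f\n", x$cv$config$folds, auc))
  }
  invisible(x)
}

#' @export
summary.ipcarf <- function(object, ...) {
  print(object)
  if (!is.null(object$grid)) {
    cat("\n"); print(object$grid)
  }
  if (!is.null(object$cv)) {
    cat("\ncross-validation detail:\n")
    print(object$cv)
  }
  invisible(object)
}

#' Plot the pooled cross-validation ROC curve of a fitted model
#'
#' @param x A fitted [ipcarf()] model with a cross-validation report.
#' @param ... Passed to [plot.roc_curve()].
#' @export
plot.ipcarf <- function(x, ...) {
  if (is.null(x$cv)) stop("model was fitted with cv = FALSE", call. = FALSE)
  plot(x$cv$roc, ...)
}
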