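#' Ancestor closure of a disease term
#'
#' Returns the disease itself together with every term reachable by following
#' child-to-parent edges — the sub-DAG on which semantic contributions are
#' computed.
#'
#' @param ontology A `disease_ontology` (see [read_ontology()]).
#' @param term A term identifier present in the ontology.
#' @return Character vector of term ids (the term plus all ancestors).
#' @export
ancestor_terms <- function(ontology, term) {
  if (!term %in% ontology$terms) stop("unknown term: ", term, call. = FALSE)
  seen <- character(0)
  queue <- term
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, setdiff(ontology$parents[[t]], seen))
  }
  sort(seen)
}

#' Semantic contributions of a disease's ancestor terms
#'
#' Each term in the ancestor closure of a disease contributes decayed credit
#' to the disease's semantic value: the disease itself contributes 1, and any
#' other term contributes `delta` times the maximum contribution among its
#' children inside the closure. With a uniform attenuation factor this equals
#' `delta^h` where `h` is the least number of generations separating the term
#' from the disease. The semantic value is the sum of all contributions.
#'
#' @inheritParams ancestor_terms
#' @param disease Term identifier of the disease.
#' @param delta Semantic contribution attenuation factor in `[0, 1]`.
#' @return List with `disease`, `contributions` (named numeric over the
#'   closure, value 1 at the disease itself) and `semantic_value` (their sum).
#' @examples
#' onto <- ipcarf:::make_ontology(c("D", "P"), c("P", "R"))
#' semantic_contributions(onto, "D", delta = 0.5)
#' @export
semantic_contributions <- function(ontology, disease, delta = 0.5) {
  stopifnot(is.numeric(delta), delta >= 0, delta <= 1)
  closure <- ancestor_terms(ontology, disease)
  contrib <- setNames(rep(NA_real_, length(closure)), closure)
  contrib[[disease]] <- 1

  # Memoised recursion up the closure; every non-disease closure member has at
  # least one child inside the closure (it is an ancestor through that child).
  resolve <- function(t) {
    if (!is.na(contrib[[t]])) return(contrib[[t]])
    kids <- intersect(ontology$children[[t]], closure)
    val <- delta * max(vapply(kids, resolve, 0))
    contrib[[t]] <<- val
    val
  }
  for (t in closure) resolve(t)

  list(disease = disease, contributions = contrib,
       semantic_value = sum(contrib))
}

#' Disease-disease semantic similarity from an ontology
#'
#' Computes a square symmetric similarity matrix over a list of diseases from
#' their positions in the ontology DAG. Two models are available:
#'
#' * `"model1"` — contribution-decay: each disease's ancestors get credit
#'   attenuated by `delta` per generation ([semantic_contributions()]); the
#'   similarity of two diseases is the summed credit of their shared ancestor
#'   terms, normalised by the two semantic values.
#' * `"model2"` — information content: a term's credit is
#'   `-log(n_t / N)`, where `n_t` of the `N` diseases under study have the
#'   term in their ancestor closure, so terms shared by every disease carry no
#'   information. The same ratio form is used. This variant is an
#'   interpretation of the second model the method family uses; it is not
#'   uniquely pinned down by the decay model alone.
#' * `"average"` (default) — element-wise mean of the two.
#'
#' All variants are symmetric with unit diagonal and entries in `[0, 1]`.
#'
#' @inheritParams semantic_contributions
#' @param diseases Character vector of disease labels.
#' @param model `"model1"`, `"model2"` or `"average"`.
#' @param terms Optional named character vector mapping disease labels to
#'   ontology term ids; by default disease labels are the term ids.
#' @return Similarity matrix with `diseases` as row/column labels.
#' @export
semantic_similarity <- function(ontology, diseases, delta = 0.5,
                                model = c("average", "model1", "model2"),
                                terms = NULL) {
  model <- match.arg(model)
  if (length(diseases) == 0L) stop("empty disease list", call. = FALSE)
  if (is.null(terms)) terms <- setNames(diseases, diseases)
  missing <- diseases[!diseases %in% names(terms)]
  if (length(missing) > 0L) {
    stop("no ontology term mapped for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  term_of <- terms[diseases]

  closures <- lapply(term_of, function(t) ancestor_terms(ontology, t))
  s1 <- s2 <- NULL
  if (model %in% c("model1", "average")) {
    cmaps <- lapply(term_of, function(t) semantic_contributions(ontology, t, delta))
    s1 <- semsim_from_contributions(cmaps, closures, diseases)
  }
  if (model %in% c("model2", "average")) {
    ic <- information_content(closures)
    cmaps2 <- lapply(closures, function(cl) {
      list(contributions = ic[cl], semantic_value = sum(ic[cl]))
    })
    s2 <- semsim_from_contributions(cmaps2, closures, diseases)
  }
  out <- switch(model, model1 = s1, model2 = s2,
                average = combine_similarity(s1, s2))
  attr(out, "kind") <- "semantic"
  out
}

# -log relative corpus frequency of each term over the diseases' closures.
information_content <- function(closures) {
  all_terms <- sort(unique(unlist(closures)))
  counts <- table(factor(unlist(lapply(closures, unique)), levels = all_terms))
  setNames(-log(as.numeric(counts) / length(closures)), all_terms)
}

# Shared ratio form: sum of the two diseases' credits over their shared
# ancestor terms, divided by the sum of the two semantic values.
semsim_from_contributions <- function(cmaps, closures, labels) {
  n <- length(labels)
  S <- diag(1, n)
  dimnames(S) <- list(labels, labels)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        shared <- intersect(closures[[i]], closures[[j]])
        num <- sum(cmaps[[i]]$contributions[shared]) +
          sum(cmaps[[j]]$contributions[shared])
        den <- cmaps[[i]]$semantic_value + cmaps[[j]]$semantic_value
        S[i, j] <- S[j, i] <- if (den > 0) num / den else 0
      }
    }
  }
  S
}

#' Combine two semantic similarity matrices
#'
#' @param s1,s2 Similarity matrices with identical labels.
#' @param mode `"average"` (element-wise mean, the default), `"model1_only"`
#'   or `"model2_only"`.
#' @return Combined similarity matrix; the diagonal stays exactly 1.
#' @export
combine_similarity <- function(s1, s2,
                               mode = c("average", "model1_only", "model2_only")) {
  mode <- match.arg(mode)
  if (mode == "model1_only") return(s1)
  if (mode == "model2_only") return(s2)
  check_same_labels(s1, s2, "similarity matrices")
  out <- (s1 + s2) / 2
  diag(out) <- 1
  out
}
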