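#' Gaussian interaction profile kernel bandwidth
#'
#' The kernel bandwidth is the reciprocal of the mean squared norm of the
#' interaction profiles along the chosen axis: disease profiles are columns of
#' the association matrix, lncRNA profiles are rows.
#'
#' @param A Binary association matrix (lncRNA rows, disease columns).
#' @param axis `"disease"` or `"lncrna"`.
#' @return Positive bandwidth (scalar).
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("l1", "l2"), c("d1", "d2")))
#' gip_bandwidth(A, "disease")  # 1
#' @export
gip_bandwidth <- function(A, axis = c("disease", "lncrna")) {
  axis <- match.arg(axis)
  stopifnot_binary_matrix(A)
  total <- sum(A^2)
  if (total == 0) {
    stop("all-zero association matrix: bandwidth undefined; drop empty profiles",
         call. = FALSE)
  }
  count <- if (axis == "disease") ncol(A) else nrow(A)
  count / total
}

#' Gaussian interaction profile kernel similarity
#'
#' Similarity between two diseases (or two lncRNAs) is a Gaussian kernel on
#' their binary association profiles:
#' `K(x, y) = exp(-k * ||profile(x) - profile(y)||^2)` with bandwidth `k` from
#' [gip_bandwidth()]. Identical profiles score exactly 1; the matrix is
#' symmetric with unit diagonal and entries in `(0, 1]`. The premise is that
#' diseases sharing associated lncRNAs are similar (and vice versa).
#'
#' @inheritParams gip_bandwidth
#' @return Similarity matrix over diseases (columns of `A`) or lncRNAs (rows).
#' @export
gip_similarity <- function(A, axis = c("disease", "lncrna")) {
  axis <- match.arg(axis)
  k <- gip_bandwidth(A, axis)
  P <- if (axis == "disease") t(A) else A   # profiles as rows
  sq <- rowSums(P^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(P), 0)
  K <- exp(-k * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  attr(K, "kind") <- "gip"
  K
}

#' Integrate semantic and Gaussian-kernel disease similarity
#'
#' Where both diseases of a pair have ontology-derived semantic scores, the
#' integrated similarity is the arithmetic mean of the semantic and kernel
#' values; elsewhere the kernel value is used alone, so diseases absent from
#' the ontology degrade gracefully.
#'
#' @param semantic,gip Similarity matrices with identical labels.
#' @param coverage Character vector of diseases with valid semantic scores
#'   (defaults to all labels).
#' @return Integrated disease similarity matrix, diagonal exactly 1.
#' @export
integrate_disease_similarity <- function(semantic, gip,
                                         coverage = rownames(gip)) {
  stopifnot_similarity(semantic, "semantic")
  stopifnot_similarity(gip, "gip")
  check_same_labels(semantic, gip, "semantic and gip matrices")
  covered <- rownames(gip) %in% coverage
  both <- outer(covered, covered, "&")
  out <- gip
  out[both] <- (semantic[both] + gip[both]) / 2
  diag(out) <- 1
  attr(out, "kind") <- "integrated"
  out
}

#' Integrate Gaussian-kernel and functional lncRNA similarity
#'
#' With no functional similarity matrix supplied the kernel matrix passes
#' through unchanged; otherwise the two are averaged element-wise.
#'
#' @param gip Kernel similarity matrix over lncRNAs.
#' @param functional Optional functional similarity matrix, same labels.
#' @return Integrated lncRNA similarity matrix.
#' @export
integrate_lncrna_similarity <- function(gip, functional = NULL) {
  stopifnot_similarity(gip, "gip")
  if (is.null(functional)) return(gip)
  stopifnot_similarity(functional, "functional")
  check_same_labels(functional, gip, "functional and gip matrices")
  out <- (functional + gip) / 2
  diag(out) <- 1
  attr(out, "kind") <- "integrated"
  out
}
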