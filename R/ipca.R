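#' IPCA: covariance column-selection principal component reduction
#'
#' A one-shot dimensionality reduction that approximates PCA by compressing
#' the feature covariance matrix before the eigen-decomposition:
#'
#' 1. centre the samples (subtract column means);
#' 2. form the feature covariance matrix `C` (normalisation `1/(n-1)`);
#' 3. keep the `k` columns of `C` with the largest l2 norms (matrix `B`),
#'    ties broken towards the smaller column index;
#' 4. orthonormalise `B` by QR decomposition, giving a basis `Q` of the
#'    selected subspace;
#' 5. take the singular value decomposition of the compressed covariance
#'    `Q' C Q` and retain the leading `n_components` directions, mapped back
#'    through `Q`.
#'
#' At `k = p` (all columns kept) the result coincides with exact PCA. Each
#' basis column's largest-magnitude entry is made positive so results are
#' reproducible bit-for-bit.
#'
#' @param x Numeric sample matrix, rows = samples, columns = features.
#' @param n_components Number of output dimensions; default
#'   `min(64, ncol(x))`, reduced (with a warning) if the data have lower rank.
#' @param k Number of covariance columns retained; default
#'   `min(2 * n_components, ncol(x))`.
#' @return Object of class `ipca`: `mean`, `selected_columns`, `basis`
#'   (p x n_components, orthonormal), `explained_variance` (non-increasing
#'   singular values of the compressed covariance), `total_variance`, `k`.
#' @seealso [predict.ipca()] to project data onto the fitted basis.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' fit <- ipca(x, n_components = 2)
#' dim(predict(fit, x))
#' @export
ipca <- function(x, n_components = NULL, k = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit", call. = FALSE)
  p <- ncol(x)
  explicit_nc <- !is.null(n_components)
  if (is.null(n_components)) n_components <- min(64L, p)
  if (is.null(k)) k <- min(2L * n_components, p)
  stopifnot(n_components >= 1L, n_components <= k, k <= p)

  centred <- center_columns(x)
  C <- covariance_matrix(centred$x)
  sel <- select_columns(C, k)
  B <- C[, sel, drop = FALSE]
  Q <- qr.Q(qr(B))                      # p x k orthonormal
  C1 <- crossprod(Q, C %*% Q)
  C1 <- (C1 + t(C1)) / 2                # symmetrise rounding noise
  sv <- svd(C1)

  rank_eff <- sum(sv$d > max(sv$d[1L], 0) * 1e-12)
  if (rank_eff < n_components && rank_eff > 0L) {
    # Silent cap at the data's rank for the automatic default; warn only when
    # the caller asked for more components than the data support.
    if (explicit_nc) {
      warning(sprintf("rank-deficient input: reducing n_components from %d to %d",
                      n_components, rank_eff), call. = FALSE)
    }
    n_components <- rank_eff
  }
  basis <- Q %*% sv$u[, seq_len(n_components), drop = FALSE]
  # Deterministic sign: largest-magnitude entry of each component positive.
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  colnames(basis) <- paste0("PC", seq_len(ncol(basis)))

  structure(list(mean = centred$mean,
                 selected_columns = sel,
                 basis = basis,
                 n_components = ncol(basis),
                 explained_variance = sv$d[seq_len(ncol(basis))],
                 total_variance = sum(diag(C)),
                 k = k, p = p),
            class = "ipca")
}

# Subtract column means; rows are samples.
center_columns <- function(x) {
  if (nrow(x) < 2L) stop("need at least 2 rows to centre", call. = FALSE)
  m <- colMeans(x)
  list(x = sweep(x, 2L, m), mean = m)
}

# Feature covariance of a centred sample matrix, 1/(n-1) normalisation.
covariance_matrix <- function(xc) {
  if (nrow(xc) < 2L) stop("need at least 2 rows", call. = FALSE)
  crossprod(xc) / (nrow(xc) - 1L)
}

# Indices of the k covariance columns with largest l2 norm; ties -> lower index.
select_columns <- function(C, k) {
  p <- ncol(C)
  if (k < 1L || k > p) stop("k out of range [1, ", p, "]", call. = FALSE)
  norms <- sqrt(colSums(C^2))
  order(-norms, seq_len(p))[seq_len(k)]
}

#' Project data onto a fitted IPCA basis
#'
#' @param object A fitted [ipca()] model.
#' @param newdata Matrix with the same number of columns as the training data.
#' @param ... Unused.
#' @return Matrix of size `nrow(newdata) x n_components`.
#' @export
predict.ipca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop("newdata has ", ncol(newdata), " columns; expected ", object$p,
         call. = FALSE)
  }
  out <- sweep(newdata, 2L, object$mean) %*% object$basis
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.ipca <- function(x, ...) {
  ratio <- if (x$total_variance > 0) sum(x$explained_variance) / x$total_variance else 0
  cat(sprintf("ipca reduction: %d features -> %d components (k = %d)\n",
              x$p, x$n_components, x$k))
  cat(sprintf("  variance captured: %.1f%%\n", 100 * ratio))
  invisible(x)
}
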