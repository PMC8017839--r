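#' Sample labelled lncRNA-disease pairs from the association matrix
#'
#' Every known association becomes a positive sample; negatives are drawn
#' uniformly without replacement from the unassociated (zero) cells,
#' `ceiling(neg_ratio * positives)` of them. Sampling is reproducible under a
#' fixed seed.
#'
#' @param A Binary association matrix.
#' @param neg_ratio Negatives per positive (default 1, a balanced set).
#' @param seed Integer seed controlling the negative draw.
#' @return Data frame with columns `lncrna`, `disease`, `label` (1/0).
#' @export
sample_pairs <- function(A, neg_ratio = 1, seed = 1) {
  stopifnot_binary_matrix(A)
  stopifnot(neg_ratio > 0)
  pos <- which(A == 1L, arr.ind = TRUE)
  zero <- which(A == 0L, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("no positive entries to sample", call. = FALSE)
  n_neg <- ceiling(neg_ratio * nrow(pos))
  if (n_neg > nrow(zero)) {
    stop(sprintf("requested %d negatives but only %d zero cells available",
                 n_neg, nrow(zero)), call. = FALSE)
  }
  neg <- zero[with_seed(seed, sample.int(nrow(zero), n_neg)), , drop = FALSE]
  idx <- rbind(pos, neg)
  data.frame(lncrna = rownames(A)[idx[, 1L]],
             disease = colnames(A)[idx[, 2L]],
             label = rep(c(1L, 0L), c(nrow(pos), n_neg)),
             stringsAsFactors = FALSE)
}

#' Build per-pair feature vectors from similarity matrices
#'
#' The feature vector of a pair (l, d) is the lncRNA similarity row of l
#' (length = number of lncRNAs) concatenated with the disease similarity row
#' of d (length = number of diseases); column order follows the matrices'
#' label order.
#'
#' @param pairs Data frame with columns `lncrna`, `disease` and optionally
#'   `label` (see [sample_pairs()]).
#' @param sim_lnc lncRNA similarity matrix.
#' @param sim_dis Disease similarity matrix.
#' @return List of class `pair_features` with `x` (numeric matrix, one row per
#'   pair), `y` (integer labels or `NULL`), and `pairs`.
#' @export
pair_features <- function(pairs, sim_lnc, sim_dis) {
  stopifnot_similarity(sim_lnc, "sim_lnc")
  stopifnot_similarity(sim_dis, "sim_dis")
  bad_l <- setdiff(pairs$lncrna, rownames(sim_lnc))
  bad_d <- setdiff(pairs$disease, rownames(sim_dis))
  if (length(bad_l) || length(bad_d)) {
    stop("labels missing from similarity matrices: ",
         paste(c(bad_l, bad_d), collapse = ", "), call. = FALSE)
  }
  x <- cbind(sim_lnc[pairs$lncrna, , drop = FALSE],
             sim_dis[pairs$disease, , drop = FALSE])
  dimnames(x) <- list(paste(pairs$lncrna, pairs$disease, sep = "|"),
                      c(paste0("L.", colnames(sim_lnc)),
                        paste0("D.", colnames(sim_dis))))
  structure(list(x = x,
                 y = if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL,
                 pairs = pairs),
            class = "pair_features")
}

#' @export
print.pair_features <- function(x, ...) {
  cat("pair features:", nrow(x$x), "samples x", ncol(x$x), "features")
  if (!is.null(x$y)) cat(sprintf(" (%d positive / %d negative)",
                                 sum(x$y == 1L), sum(x$y == 0L)))
  cat("\n")
  invisible(x)
}
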