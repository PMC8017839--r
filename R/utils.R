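# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions do not clobber user scripts.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Collapse runs of whitespace and trim; optionally lower-case.
normalize_name <- function(x, lower = TRUE) {
  x <- gsub("[[:space:]]+", " ", trimws(x))
  if (lower) x <- tolower(x)
  x
}

stopifnot_binary_matrix <- function(A, arg = "A") {
  if (!is.matrix(A) || !is.numeric(A)) {
    stop("`", arg, "` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop("`", arg, "` must carry lncRNA row names and disease column names",
         call. = FALSE)
  }
  if (!all(A %in% c(0, 1))) {
    stop("`", arg, "` must be binary (entries 0/1)", call. = FALSE)
  }
  invisible(A)
}

stopifnot_similarity <- function(S, arg = "S") {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop("`", arg, "` must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S))) {
    stop("`", arg, "` must have identical row and column labels", call. = FALSE)
  }
  invisible(S)
}

check_same_labels <- function(a, b, what = "matrices") {
  if (!identical(rownames(a), rownames(b))) {
    stop("label mismatch between ", what, call. = FALSE)
  }
  invisible(TRUE)
}

zero_pad_labels <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(n)), "d"), seq_len(n))
}
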