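#' Read an lncRNA-disease association list
#'
#' Reads a two- or three-column table of known lncRNA-disease associations
#' (columns: lncRNA name, disease name, optional dysfunction type). Tab- or
#' comma-separated files are auto-detected, as is a header row naming the
#' columns. Names are whitespace-trimmed, internal runs of spaces collapsed,
#' and (by default) lower-cased so that entries from different sources match;
#' duplicated pairs collapse to one record.
#'
#' @param path Path to the association file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param normalize Lower-case names in addition to whitespace normalisation.
#' @return A data frame of class `association_table` with columns `lncrna`,
#'   `disease` and `dysfunction` (`NA` when the file has two columns).
#' @examples
#' f <- tempfile()
#' writeLines(c("l1\td1\tregulation", "l1\td1\tregulation", "l2\td2"), f)
#' read_associations(f)
#' @export
read_associations <- function(path, sep = NULL, normalize = TRUE) {
  if (!file.exists(path)) stop("association file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("association file is empty: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (any(grepl("\t", lines[keep]))) "\t" else ","
  fields <- strsplit(lines[keep], sep, fixed = TRUE)

  bad <- keep[lengths(fields) < 2L]
  if (length(bad) > 0L) {
    stop("rows with fewer than 2 fields at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # Header row: first line whose first two fields name the lncRNA/disease columns.
  first <- tolower(trimws(fields[[1L]]))
  has_header <- length(first) >= 2L &&
    grepl("lnc", first[1L]) && grepl("disease", first[2L])
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) stop("no data rows in ", path, call. = FALSE)

  lnc <- normalize_name(vapply(fields, `[`, "", 1L), lower = normalize)
  dis <- normalize_name(vapply(fields, `[`, "", 2L), lower = normalize)
  dys <- vapply(fields, function(f) if (length(f) >= 3L) trimws(f[3L]) else NA_character_, "")
  if (any(!nzchar(lnc)) || any(!nzchar(dis))) {
    stop("empty lncRNA or disease name after trimming", call. = FALSE)
  }

  dup <- duplicated(paste(lnc, dis, sep = "\r"))
  out <- data.frame(lncrna = lnc[!dup], disease = dis[!dup],
                    dysfunction = dys[!dup], stringsAsFactors = FALSE)
  message(sprintf("read %d rows, %d unique associations (%d duplicates dropped)",
                  length(lnc), nrow(out), sum(dup)))
  class(out) <- c("association_table", "data.frame")
  out
}

#' Build the binary lncRNA x disease association matrix
#'
#' The association matrix is the pipeline's central object: rows are lncRNAs,
#' columns diseases, entry 1 marks a known association. Labels are sorted
#' lexicographically so the matrix is reproducible across runs.
#'
#' @param table An `association_table` (see [read_associations()]) or any data
#'   frame with columns `lncrna` and `disease`.
#' @return Binary integer matrix with lncRNA row names and disease column names.
#' @examples
#' tab <- data.frame(lncrna = c("l1", "l2"), disease = c("d1", "d2"))
#' association_matrix(tab)
#' @export
association_matrix <- function(table) {
  if (!is.data.frame(table) || !all(c("lncrna", "disease") %in% names(table))) {
    stop("`table` must have columns `lncrna` and `disease`", call. = FALSE)
  }
  if (nrow(table) == 0L) stop("empty association table", call. = FALSE)
  lnc <- sort(unique(table$lncrna))
  dis <- sort(unique(table$disease))
  A <- matrix(0L, length(lnc), length(dis), dimnames = list(lnc, dis))
  A[cbind(match(table$lncrna, lnc), match(table$disease, dis))] <- 1L
  A
}

#' Read a disease ontology as a child-parent edge list
#'
#' The ontology file holds one `child<TAB>parent` edge per line; lines starting
#' with `#` are comments. The loaded graph is verified to be acyclic (a
#' directed acyclic graph of disease terms) and its roots — terms with no
#' parent — are identified.
#'
#' @param path Path to the edge-list file.
#' @return A `disease_ontology`: list with `terms`, `parents` (named list,
#'   child to parents), `children` (parent to children), and `roots`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("ontology lines must be child<TAB>parent", call. = FALSE)
  }
  child <- trimws(vapply(fields, `[`, "", 1L))
  parent <- trimws(vapply(fields, `[`, "", 2L))
  make_ontology(child, parent)
}

# Construct and validate a disease_ontology from parallel child/parent vectors.
make_ontology <- function(child, parent) {
  edges <- unique(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE))
  terms <- sort(unique(c(edges$child, edges$parent)))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))

  # Kahn's algorithm: any leftover nodes after peeling zero-out-degree
  # (childless w.r.t. remaining edges) terms form a cycle.
  indeg <- lengths(children)  # edges run child -> parent; peel parents of none left
  remaining <- setNames(lengths(children), terms)
  queue <- terms[remaining == 0L]
  seen <- character(0)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- c(seen, t)
    for (p in parents[[t]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(seen) < length(terms)) {
    cyc <- setdiff(terms, seen)
    stop("ontology contains a cycle involving: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }

  roots <- terms[lengths(parents) == 0L]
  structure(list(terms = terms, parents = parents, children = children,
                 roots = roots),
            class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat("disease ontology:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "edges,", length(x$roots), "root(s)\n")
  invisible(x)
}

#' Read or write a labelled numeric matrix as TSV
#'
#' Matrices (similarity, feature, association) are exchanged as TSV with a
#' header row of column labels and a first column of row labels. The
#' round trip `read_matrix_tsv(write_matrix_tsv(M, f))` preserves values to
#' 12 significant digits and labels exactly.
#'
#' @param path File path.
#' @return For `read_matrix_tsv`, a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_body <- lengths(fields[-1L])
  if (length(unique(ncol_body)) > 1L) {
    stop("ragged matrix file at line(s): ",
         paste(1L + which(ncol_body != ncol_body[1L]), collapse = ", "),
         call. = FALSE)
  }
  col_labels <- fields[[1L]]
  # Header may or may not carry a leading cell for the row-label column.
  if (length(col_labels) == ncol_body[1L]) col_labels <- col_labels[-1L] else
    if (length(col_labels) != ncol_body[1L] - 1L) {
      stop("header width does not match body width", call. = FALSE)
    }
  row_labels <- vapply(fields[-1L], `[`, "", 1L)
  vals <- suppressWarnings(
    vapply(fields[-1L], function(f) as.numeric(f[-1L]), numeric(length(col_labels)))
  )
  if (anyNA(vals)) stop("non-numeric cell in matrix file", call. = FALSE)
  M <- t(matrix(vals, nrow = length(col_labels)))
  dimnames(M) <- list(row_labels, col_labels)
  M
}

#' @rdname read_matrix_tsv
#' @param M Numeric matrix with row and column names.
#' @export
write_matrix_tsv <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  header <- paste(c("", colnames(M)), collapse = "\t")
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], format(M[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
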