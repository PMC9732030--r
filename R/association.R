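#' Construct a small molecule--miRNA association dataset
#'
#' Bundles a binary association matrix with its identifier lists.  Rows are
#' small molecules (SMs), columns are miRNAs; entry 1 marks an
#' experimentally supported association.
#'
#' @param A numeric matrix with entries in \{0, 1\}; `ns` rows (SMs) by
#'   `nm` columns (miRNAs).
#' @param sm_ids character vector of SM identifiers (e.g. `"CID 3385"`),
#'   one per row of `A`.  Defaults to `rownames(A)`.
#' @param mirna_ids character vector of miRNA identifiers (e.g.
#'   `"hsa-mir-23a"`), one per column of `A`.  Defaults to `colnames(A)`.
#'
#' @return An object of class `smma_association`: a list with elements
#'   `A` (the binary matrix, dimnames set), `sm_ids` and `mirna_ids`.
#' @export
#' @examples
#' A <- matrix(c(1, 0, 1, 0), 2, 2)
#' association_data(A, c("CID 1", "CID 2"), c("hsa-mir-21", "hsa-mir-155"))
association_data <- function(A, sm_ids = rownames(A), mirna_ids = colnames(A)) {
  A <- as.matrix(A)
  if (is.null(sm_ids) || is.null(mirna_ids))
    stop("sm_ids and mirna_ids must be supplied or present as dimnames")
  sm_ids <- as.character(sm_ids)
  mirna_ids <- as.character(mirna_ids)
  if (nrow(A) != length(sm_ids))
    stop("row count (", nrow(A), ") != number of SM ids (", length(sm_ids), ")")
  if (ncol(A) != length(mirna_ids))
    stop("column count (", ncol(A), ") != number of miRNA ids (",
         length(mirna_ids), ")")
  if (anyDuplicated(sm_ids)) stop("duplicate SM identifiers")
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA identifiers")
  if (!all(A %in% c(0, 1))) stop("association matrix entries must be 0 or 1")
  storage.mode(A) <- "double"
  dimnames(A) <- list(sm_ids, mirna_ids)
  structure(list(A = A, sm_ids = sm_ids, mirna_ids = mirna_ids),
            class = "smma_association")
}

#' @export
print.smma_association <- function(x, ...) {
  cat(sprintf(
    "smma_association: %d SMs x %d miRNAs, %d known associations\n",
    length(x$sm_ids), length(x$mirna_ids), sum(x$A)))
  invisible(x)
}

#' Read SM--miRNA association pairs from a delimited file
#'
#' Reads a two-or-more column delimited text file of (SM id, miRNA id)
#' pairs and builds the binary association matrix.  When identifier
#' universes are supplied, SMs/miRNAs with no association are retained as
#' all-zero rows/columns (the convention of keeping entities that never
#' occur in a known pair).
#'
#' @param path path to a TSV/CSV file; the first two columns are read as
#'   SM and miRNA identifiers.  A header line is not expected.
#' @param sm_universe optional character vector: complete ordered SM
#'   identifier list (a superset of the SM ids in the file).
#' @param mirna_universe optional character vector: complete ordered
#'   miRNA identifier list.
#' @param sep field separator, default tab.
#'
#' @return An [association_data] object.  Duplicated pairs are kept once
#'   with a warning; a pair identifier missing from a supplied universe
#'   is an error naming the identifier.
#' @export
read_association_pairs <- function(path, sm_universe = NULL,
                                   mirna_universe = NULL, sep = "\t") {
  raw <- readLines(path)
  df <- if (any(nzchar(trimws(raw)))) {
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "", blank.lines.skip = TRUE)
  } else data.frame()
  if (nrow(df) > 0 && ncol(df) < 2)
    stop("pair file must have at least two columns")
  sm <- if (nrow(df) > 0) df[[1]] else character(0)
  mi <- if (nrow(df) > 0) df[[2]] else character(0)
  key <- paste(sm, mi, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate association pair(s) kept once")
    keep <- !duplicated(key)
    sm <- sm[keep]; mi <- mi[keep]
  }
  sm_ids <- if (is.null(sm_universe)) unique(sm) else as.character(sm_universe)
  mirna_ids <- if (is.null(mirna_universe)) unique(mi) else as.character(mirna_universe)
  bad_sm <- setdiff(sm, sm_ids)
  if (length(bad_sm))
    stop("SM id(s) not in supplied universe: ", paste(bad_sm, collapse = ", "))
  bad_mi <- setdiff(mi, mirna_ids)
  if (length(bad_mi))
    stop("miRNA id(s) not in supplied universe: ", paste(bad_mi, collapse = ", "))
  A <- matrix(0, length(sm_ids), length(mirna_ids),
              dimnames = list(sm_ids, mirna_ids))
  if (length(sm)) A[cbind(match(sm, sm_ids), match(mi, mirna_ids))] <- 1
  association_data(A, sm_ids, mirna_ids)
}

#' Write association pairs to a delimited file
#'
#' Inverse of [read_association_pairs()]: writes one `(SM id, miRNA id)`
#' line per known association, in row-major matrix order.
#'
#' @param data an [association_data] object.
#' @param path output path.
#' @param sep field separator, default tab.
#' @export
write_association_pairs <- function(data, path, sep = "\t") {
  stopifnot(inherits(data, "smma_association"))
  idx <- which(t(data$A) == 1)  # row-major over A
  nm <- length(data$mirna_ids)
  s <- data$sm_ids[(idx - 1) %/% nm + 1]
  m <- data$mirna_ids[(idx - 1) %% nm + 1]
  utils::write.table(data.frame(s, m), path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write identifier-headed numeric matrices
#'
#' The on-disk form is delimited text whose first row and first column
#' carry identifiers, with a numeric body.  `read_matrix_tsv` /
#' `write_matrix_tsv` handle any such matrix (e.g. denoised association
#' or score matrices); `read_similarity_matrix` additionally enforces
#' the similarity-matrix contract: a square body whose row identifiers
#' equal its column identifiers in order.
#'
#' @param path path to the matrix file.
#' @param S numeric matrix with dimnames (for writing).
#' @param sep field separator, default tab.
#' @return the numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "", comment.char = "")
  S <- as.matrix(df)
  storage.mode(S) <- "double"
  S
}

#' @rdname read_matrix_tsv
#' @export
read_similarity_matrix <- function(path, sep = "\t") {
  S <- read_matrix_tsv(path, sep)
  if (nrow(S) != ncol(S))
    stop("similarity matrix body is not square: ", nrow(S), "x", ncol(S))
  if (!identical(rownames(S), colnames(S)))
    stop("row identifiers do not match column identifiers in order")
  S
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(S, path, sep = "\t") {
  utils::write.table(S, path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write the ranked miRNA list for one small molecule
#'
#' Orders the miRNAs by descending score for the given SM and writes a
#' `(rank, miRNA id, score)` table.  Ties are broken by lexicographic
#' miRNA identifier order so that reported rankings are reproducible.
#'
#' @param scores numeric score matrix in association orientation
#'   (`ns` SMs x `nm` miRNAs).
#' @param data the [association_data] the scores refer to.
#' @param sm_id the SM whose ranking is written; must be in
#'   `data$sm_ids`.
#' @param path output path.
#' @param top_n optional: truncate to the first `top_n` rows.
#' @param sep field separator, default tab.
#' @return invisibly, the data.frame that was written.
#' @export
write_rankings <- function(scores, data, sm_id, path, top_n = NULL,
                           sep = "\t") {
  stopifnot(inherits(data, "smma_association"))
  i <- match(sm_id, data$sm_ids)
  if (is.na(i)) stop("unknown SM id: ", sm_id)
  s <- scores[i, ]
  ord <- order(-s, data$mirna_ids)
  out <- data.frame(rank = seq_along(ord),
                    mirna_id = data$mirna_ids[ord],
                    score = s[ord], row.names = NULL)
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(out)
}
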