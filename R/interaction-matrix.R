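#' Labelled plant x pollinator interaction-count matrix
#'
#' The central container of the package: a non-negative integer matrix with
#' plants on the rows and pollinators on the columns. Cell \eqn{a_{ij}} holds
#' the number of specimens of pollinator \eqn{j} captured on plant \eqn{i}.
#' Rows and columns whose marginal total is zero are trimmed at construction,
#' so every downstream index sees a matrix with strictly positive marginals.
#'
#' @param counts numeric matrix (or object coercible to one) of non-negative
#'   integer counts; rows are plants, columns pollinators.
#' @param plants,pollinators optional character vectors of row/column labels;
#'   default to the dimnames of `counts`. Labels are whitespace-trimmed and
#'   must be unique within each axis.
#' @return an `interaction_matrix`: an integer matrix with dimnames and class
#'   attribute.
#' @examples
#' M <- interaction_matrix(matrix(c(2, 1, 0, 3), 2, 2,
#'   dimnames = list(c("p1", "p2"), c("a", "b"))))
#' total_interactions(M)
#' @export
interaction_matrix <- function(counts, plants = rownames(counts),
                               pollinators = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("interaction counts must be numeric")
  if (anyNA(counts)) stop("interaction counts contain NA")
  if (any(counts < 0)) stop("interaction counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("interaction counts must be integers")
  if (is.null(plants)) plants <- paste0("plant_", seq_len(nrow(counts)))
  if (is.null(pollinators)) pollinators <- paste0("poll_", seq_len(ncol(counts)))
  plants <- trimws(as.character(plants))
  pollinators <- trimws(as.character(pollinators))
  if (anyDuplicated(plants)) stop("duplicate plant labels: ",
    paste(unique(plants[duplicated(plants)]), collapse = ", "))
  if (anyDuplicated(pollinators)) stop("duplicate pollinator labels: ",
    paste(unique(pollinators[duplicated(pollinators)]), collapse = ", "))
  if (length(plants) != nrow(counts) || length(pollinators) != ncol(counts))
    stop("label lengths do not match matrix dimensions")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(plants, pollinators)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  counts <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("no interactions: matrix is empty after trimming zero marginals")
  structure(counts, class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d plants x %d pollinators, %d links, m = %d\n",
              nrow(x), ncol(x), n_links(x), total_interactions(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Subsetting keeps the class only through the constructor; a plain drop to
#' base matrix avoids invariants silently breaking on zero-marginal slices.
#' @export
`[.interaction_matrix` <- function(x, ...) unclass(x)[...]

#' Matrix summary accessors
#'
#' @param M an [interaction_matrix()]
#' @return integer scalar: number of plant rows, pollinator columns, realized
#'   links (non-zero cells) or total interaction count \eqn{m = \sum a_{ij}}.
#' @export
n_plants <- function(M) nrow(M)

#' @rdname n_plants
#' @export
n_pollinators <- function(M) ncol(M)

#' @rdname n_plants
#' @export
n_links <- function(M) sum(M > 0)

#' @rdname n_plants
#' @export
total_interactions <- function(M) as.integer(sum(M))

as_interaction_matrix <- function(x) {
  if (inherits(x, "interaction_matrix")) x else interaction_matrix(x)
}

#' Read / write a labelled interaction matrix as CSV
#'
#' Format: first column holds the plant labels, header row the pollinator
#' labels, cells the integer counts. `read_matrix(write_matrix(M, f))`
#' reproduces `M` exactly.
#'
#' @param path file path
#' @param M an [interaction_matrix()]
#' @return `read_matrix`: an `interaction_matrix`; `write_matrix`: `path`,
#'   invisibly.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("no interactions: matrix file is empty or has no pollinator columns")
  plants <- trimws(as.character(df[[1]]))
  cells <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(cells)) stop("non-numeric cell in matrix file")
  if (any(cells < 0) || any(abs(cells - round(cells)) > 1e-8))
    stop("matrix cells must be non-negative integers")
  interaction_matrix(cells, plants = plants, pollinators = colnames(df)[-1])
}

#' @rdname read_matrix
#' @export
write_matrix <- function(M, path) {
  M <- as_interaction_matrix(M)
  df <- data.frame(plant = rownames(M), unclass(M),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
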