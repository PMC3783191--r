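#' Clone evolution tree
#'
#' A rooted tree over clones `1..N` encoded as a parent array. Clone 1 is the
#' wildtype root (the clone defined by the dummy aberration); clone `j > 1`
#' arose from clone `parent[j]` through a single new aberration. Because the
#' aggregate frequencies are sorted non-increasing and an aberration can never
#' be lost, a clone's parent always has a smaller index (`parent[j] < j`, the
#' descent-ordering property), which is what makes exhaustive enumeration by
#' insertion order possible.
#'
#' @param parent integer vector; `parent[1]` is `NA` (root), `parent[j] < j`
#'   for all `j > 1`.
#' @return object of class `clone_tree` with fields `parent` and `children`
#'   (list of integer vectors).
#' @examples
#' clone_tree(c(NA, 1, 2))  # chain
#' clone_tree(c(NA, 1, 1))  # star
#' @export
clone_tree <- function(parent) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n < 1L) stop_input_error("parent array must be non-empty")
  if (!is.na(parent[1])) stop_input_error("parent[1] must be NA (root)")
  if (n > 1L) {
    p <- parent[-1]
    if (anyNA(p) || any(p < 1L) || any(p >= seq(2L, n)))
      stop_input_error("parent[j] must satisfy 1 <= parent[j] < j for j > 1")
  }
  children <- vector("list", n)
  for (j in seq_len(n)[-1]) {
    pj <- parent[j]
    children[[pj]] <- c(children[[pj]], j)
  }
  structure(list(parent = parent, children = children), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree on", length(x$parent), "clones; parent array: [",
      paste(ifelse(is.na(x$parent), "-", x$parent), collapse = ","), "]\n")
  invisible(x)
}

#' Subclone frequencies by back-substitution
#'
#' In the exact model each clone's mixture fraction is its aggregate
#' frequency minus the aggregate frequencies of its direct descendants:
#' `x[i] = y[i] - sum_{j: parent[j] = i} y[j]`. The result may contain
#' negative entries; the caller decides feasibility.
#'
#' @param tree a [clone_tree()]
#' @param signal an [aggregate_signal()] of matching length
#' @return numeric vector `x` of length `N`
#' @examples
#' s <- aggregate_signal(c(1, 0.6, 0.4), labels = c("d", "a", "b"))
#' clone_frequencies(clone_tree(c(NA, 1, 2)), s)
#' @export
clone_frequencies <- function(tree, signal) {
  y <- signal$y
  if (length(tree$parent) != length(y))
    stop_input_error("tree and signal have different lengths")
  x <- y
  for (j in seq_along(y)[-1]) x[tree$parent[j]] <- x[tree$parent[j]] - y[j]
  x
}

#' Binary genotype matrix of a clone tree
#'
#' `C[i, j] = 1` iff aberration `i` is present in clone `j`, i.e. iff clone
#' `i` is an ancestor-or-self of clone `j`. The dummy row (`i = 1`) is all
#' ones. Under the sorted clone ordering the matrix is upper triangular.
#'
#' @param tree a [clone_tree()]
#' @return an `N x N` 0/1 integer matrix
#' @examples
#' genotype_matrix(clone_tree(c(NA, 1, 1)))
#' @export
genotype_matrix <- function(tree) {
  n <- length(tree$parent)
  C <- diag(1L, n)
  for (j in seq_len(n)[-1]) {
    p <- tree$parent[j]
    C[, j] <- C[, j] + C[, p]   # root path of parent plus self
  }
  C
}

#' Forward mixture model: aggregate signal of a genotype/frequency pair
#'
#' Computes `y = C %*% x`: the aggregate frequency of each aberration given
#' subclone genotypes and mixing fractions. Used for round-trip checks and
#' for generating synthetic mixtures.
#'
#' @param C binary genotype matrix (aberrations x clones)
#' @param x nonnegative clone frequencies
#' @return numeric vector `y`
#' @export
aggregate_from_solution <- function(C, x) {
  if (!is.matrix(C) || ncol(C) != length(x))
    stop_input_error("dimension mismatch between genotype matrix and x")
  if (any(x < -.decon_tol)) stop_input_error("x must be nonnegative")
  as.numeric(C %*% x)
}

#' Tree depth (number of generations)
#'
#' Maximum number of edges on any root-to-clone path; the wildtype-only tree
#' has depth 0. Used as the shallowness criterion when ranking solutions.
#'
#' @param tree a [clone_tree()]
#' @return integer depth
#' @export
tree_depth <- function(tree) {
  n <- length(tree$parent)
  d <- integer(n)
  for (j in seq_len(n)[-1]) d[j] <- d[tree$parent[j]] + 1L
  max(d)
}

#' Per-clone depths (edges from root)
#' @keywords internal
clone_depths <- function(tree) {
  n <- length(tree$parent)
  d <- integer(n)
  for (j in seq_len(n)[-1]) d[j] <- d[tree$parent[j]] + 1L
  d
}

#' Ancestor indices of a clone (excluding itself)
#' @keywords internal
clone_ancestors <- function(tree, j) {
  out <- integer(0)
  p <- tree$parent[j]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[p]
  }
  out
}

#' A deconvolution solution
#'
#' Bundles a clone tree with its fitted frequencies and ranking statistics.
#' Normally produced by [deconvolve()]; this constructor is exported for the
#' simulation harness and tests.
#'
#' @param tree a [clone_tree()]
#' @param x clone frequencies (length N)
#' @param signal the [aggregate_signal()] the solution explains
#' @param populated integer count of populated subclones (P)
#' @param method one of `"exact"`, `"bound"`, `"normal"`
#' @param unpopulated indices forced to zero during fitting (FG parents)
#' @return object of class `clone_solution` with fields `tree`, `x`, `C`,
#'   `populated`, `depth`, `fit_residual`, `method`, `labels`.
#' @export
clone_solution <- function(tree, x, signal, populated = NULL,
                           method = "exact", unpopulated = integer(0)) {
  C <- genotype_matrix(tree)
  y_hat <- as.numeric(C %*% x)
  res <- sqrt(sum((signal$y - y_hat)^2))
  if (is.null(populated)) populated <- sum(x > .decon_tol)
  structure(
    list(tree = tree, x = x, C = C,
         populated = as.integer(populated),
         depth = tree_depth(tree),
         fit_residual = res,
         method = method,
         unpopulated = sort(unique(as.integer(unpopulated))),
         labels = signal$labels),
    class = "clone_solution"
  )
}

#' @export
print.clone_solution <- function(x, ...) {
  cat(sprintf("Solution: P = %d populated subclones, depth D = %d, residual = %.3g\n",
              x$populated, x$depth, x$fit_residual))
  par <- ifelse(is.na(x$tree$parent), "-", x$tree$parent)
  df <- data.frame(clone = seq_along(x$x), parent = par,
                   label = x$labels, x = round(x$x, 6))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Genotypes of populated clones as label sets
#'
#' @param solution a `clone_solution`
#' @param threshold populated means `x > threshold`
#' @param drop_dummy drop the dummy aberration from each genotype
#' @return named list mapping clone index to a character vector of aberration
#'   labels, one entry per populated clone
#' @export
populated_genotypes <- function(solution, threshold = .decon_tol,
                                drop_dummy = TRUE) {
  idx <- which(solution$x > threshold)
  out <- lapply(idx, function(j) {
    rows <- which(solution$C[, j] == 1L)
    if (drop_dummy) rows <- setdiff(rows, 1L)
    sort(solution$labels[rows])
  })
  names(out) <- as.character(idx)
  out
}
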