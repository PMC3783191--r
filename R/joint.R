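#' Pairwise ancestry relations implied by a solution
#'
#' For every unordered pair of aberration labels in the solution, records
#' whether the first (alphabetically) is an ancestor of the second (`anc`),
#' a descendant (`desc`), or on a separate branch (`sep`). The dummy is
#' skipped.
#' @param solution a `clone_solution`
#' @return named character vector keyed `"labA|labB"` with `labA < labB`
#' @keywords internal
solution_relations <- function(solution) {
  n <- length(solution$labels)
  if (n <= 2L) return(stats::setNames(character(0), character(0)))
  C <- solution$C
  out <- character(0)
  for (i in 2:(n - 1L)) for (j in (i + 1L):n) {
    la <- solution$labels[i]; lb <- solution$labels[j]
    swap <- la > lb
    i_anc_j <- C[i, j] == 1L
    j_anc_i <- C[j, i] == 1L
    rel <- if (i_anc_j) "anc" else if (j_anc_i) "desc" else "sep"
    if (swap) rel <- switch(rel, anc = "desc", desc = "anc", sep = "sep")
    key <- if (swap) paste(lb, la, sep = "|") else paste(la, lb, sep = "|")
    out[key] <- rel
  }
  out
}

#' Assemble a global tree from merged pairwise relations
#'
#' Takes the transitive closure of the ancestor relation, checks consistency
#' (antisymmetry; no pair both ancestral and separate-branch) and builds the
#' tree: each label's parent is the unique deepest element of its ancestor
#' set. Returns NULL when the relations conflict or do not determine a tree.
#' @param rels named relation vector (as from [solution_relations()], keys
#'   over the union label universe)
#' @param labels all aberration labels
#' @return list(`labels`, `parent`) in depth-then-label order, or NULL
#' @keywords internal
assemble_global_tree <- function(rels, labels) {
  labels <- sort(unique(labels))
  anc <- stats::setNames(vector("list", length(labels)), labels)
  sep <- list()
  for (key in names(rels)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    switch(rels[[key]],
      anc = anc[[ab[2]]] <- union(anc[[ab[2]]], ab[1]),
      desc = anc[[ab[1]]] <- union(anc[[ab[1]]], ab[2]),
      sep = sep[[length(sep) + 1L]] <- ab)
  }
  repeat {                                        # transitive closure
    changed <- FALSE
    for (v in labels) {
      before <- anc[[v]]
      anc[[v]] <- union(before, unlist(anc[before]))
      if (length(anc[[v]]) > length(before)) changed <- TRUE
    }
    if (!changed) break
  }
  for (v in labels) if (v %in% anc[[v]]) return(NULL)       # cycle
  for (ab in sep)
    if (ab[1] %in% anc[[ab[2]]] || ab[2] %in% anc[[ab[1]]]) return(NULL)
  parent <- stats::setNames(rep("dummy", length(labels)), labels)
  for (v in labels) {
    A <- anc[[v]]
    if (length(A) == 0L) next
    depth_a <- lengths(anc[A])
    top <- A[depth_a == max(depth_a)]
    if (length(top) > 1L) return(NULL)            # incomparable deepest ancestors
    if (max(depth_a) != length(A) - 1L) return(NULL)  # ancestors not a chain
    parent[v] <- top
  }
  depth <- stats::setNames(integer(length(labels)), labels)
  for (v in labels) depth[v] <- length(anc[[v]]) + 1L
  ord <- order(depth, labels)
  list(labels = c("dummy", labels[ord]),
       parent = c(NA_character_, parent[labels[ord]]))
}

#' Jointly deconvolve related samples under one global evolutionary tree
#'
#' Solves each sample separately, then keeps only those per-sample solutions
#' that can coexist: a tuple (one optimal solution per sample) is compatible
#' when no two samples disagree on the ancestry relation of any shared
#' aberration pair and the merged relations assemble into a single global
#' tree over the label union.
#'
#' @param signals list of [aggregate_signal()] objects over a shared label
#'   universe (labels missing from a sample are allowed)
#' @param model an [error_model()]
#' @param max_tuples refuse when the product of per-sample solution counts
#'   exceeds this
#' @param ... passed to [deconvolve()]
#' @return object of class `joint_result`: `per_sample` (filtered solution
#'   lists), `results` (full per-sample `decon_result`s), `global_trees`
#'   (deduplicated assembled trees), `n_compatible` tuples, and `conflicts`
#'   (diagnostic relation conflicts when nothing is compatible)
#' @export
joint_deconvolve <- function(signals, model = error_model("exact"),
                             max_tuples = 1e5, ...) {
  stopifnot(length(signals) >= 1L)
  results <- lapply(signals, deconvolve, model = model, ...)
  if (length(signals) == 1L) {
    r <- results[[1]]
    g <- assemble_global_tree(
      if (length(r$solutions)) solution_relations(r$solutions[[1]]) else character(0),
      setdiff(signals[[1]]$labels, "dummy"))
    return(structure(list(per_sample = list(r$solutions), results = results,
                          global_trees = if (is.null(g)) list() else list(g),
                          n_compatible = length(r$solutions),
                          conflicts = NULL),
                     class = "joint_result"))
  }
  sol_sets <- lapply(results, `[[`, "solutions")
  sizes <- lengths(sol_sets)
  if (any(sizes == 0L))
    return(structure(list(per_sample = lapply(sizes, function(.) list()),
                          results = results, global_trees = list(),
                          n_compatible = 0L,
                          conflicts = "a sample has no solutions"),
                     class = "joint_result"))
  if (prod(sizes) > max_tuples)
    stop_cap_error(sprintf("%.0f solution tuples exceed cap %g",
                           prod(sizes), max_tuples))
  rels <- lapply(sol_sets, function(set) lapply(set, solution_relations))
  all_labels <- sort(unique(unlist(lapply(signals, function(s)
    setdiff(s$labels, "dummy")))))

  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  keep <- lapply(sol_sets, function(.) logical(length(.)))
  global_trees <- list()
  gkeys <- character(0)
  conflicts <- character(0)
  n_compat <- 0L
  for (t in seq_len(nrow(grid))) {
    merged <- character(0)
    ok <- TRUE
    for (k in seq_along(signals)) {
      rk <- rels[[k]][[grid[t, k]]]
      shared <- intersect(names(merged), names(rk))
      bad <- shared[merged[shared] != rk[shared]]
      if (length(bad)) {
        conflicts <- union(conflicts, paste0(bad, ": ", merged[bad],
                                             " vs ", rk[bad]))
        ok <- FALSE
        break
      }
      merged[names(rk)] <- rk
    }
    if (!ok) next
    g <- assemble_global_tree(merged, all_labels)
    if (is.null(g)) {
      conflicts <- union(conflicts, "merged relations do not form a tree")
      next
    }
    n_compat <- n_compat + 1L
    for (k in seq_along(signals)) keep[[k]][grid[t, k]] <- TRUE
    gk <- paste(g$parent, collapse = ",")
    if (!gk %in% gkeys) {
      gkeys <- c(gkeys, gk)
      global_trees[[length(global_trees) + 1L]] <- g
    }
  }
  structure(list(
    per_sample = Map(function(set, kp) set[kp], sol_sets, keep),
    results = results,
    global_trees = global_trees,
    n_compatible = n_compat,
    conflicts = if (n_compat == 0L) conflicts else NULL),
    class = "joint_result")
}

#' @export
print.joint_result <- function(x, ...) {
  cat("Joint deconvolution over", length(x$per_sample), "sample(s):",
      x$n_compatible, "compatible tuple(s),",
      length(x$global_trees), "global tree(s)\n")
  cat("surviving solutions per sample:",
      paste(lengths(x$per_sample), collapse = ", "), "\n")
  if (!is.null(x$conflicts) && length(x$conflicts))
    cat("conflicts:\n ", paste(utils::head(x$conflicts, 10), collapse = "\n  "), "\n")
  invisible(x)
}
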