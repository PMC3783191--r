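#' Enumerate every ordered clone tree on N clones
#'
#' Brute-force generator of all parent arrays with `parent[j] < j`. Because
#' the aggregate frequencies are sorted, every admissible evolutionary tree
#' has this form, so the generator is exhaustive; there are exactly
#' `(N-1)!` of them. Intentionally naive: it exists as an independent oracle
#' for testing the staged solver.
#'
#' @param n clone count, `1 <= n <= 9` (factorial growth)
#' @return list of parent integer vectors (NA at the root)
#' @examples
#' length(enumerate_all_trees(4))  # 3! = 6
#' @export
enumerate_all_trees <- function(n) {
  if (n < 1L || n > 9L)
    stop_cap_error("brute-force enumeration supports 1 <= n <= 9")
  trees <- list(NA_integer_)
  if (n == 1L) return(trees)
  for (j in 2:n) {
    trees <- unlist(lapply(trees, function(p)
      lapply(seq_len(j - 1L), function(q) c(p, q))), recursive = FALSE)
  }
  trees
}

#' Brute-force deconvolution by exhaustive tree evaluation
#'
#' Evaluates every ordered tree: computes back-substitution frequencies,
#' keeps trees feasible under the error model's slack, and scores each by
#' its populated count (frequencies distinguishable from zero under the
#' model - deliberately a different code path from the staged solver's
#' first-generation bookkeeping) and depth.
#'
#' @param signal an [aggregate_signal()] with at most 9 entries
#' @param model an [error_model()]
#' @return list of `clone_solution` objects (all feasible trees, unranked)
#' @export
brute_force_solve <- function(signal, model = error_model("exact")) {
  n <- length(signal$y)
  eps <- signal$eps
  out <- list()
  for (par in enumerate_all_trees(n)) {
    tree <- clone_tree(par)
    x <- clone_frequencies(tree, signal)
    slack <- vapply(seq_len(n), function(j)
      em_allowance(model, eps[j], eps[tree$children[[j]]]), numeric(1))
    if (any(x < -slack)) next
    pop <- x > slack
    sol <- clone_solution(tree, pmax(x, 0), signal,
                          populated = sum(pop), method = model$kind,
                          unpopulated = which(!pop))
    out[[length(out) + 1L]] <- sol
  }
  out
}

#' Optimal subset of brute-force solutions (min P, then min D)
#' @param solutions output of [brute_force_solve()]
#' @return the optimal sub-list in canonical order
#' @export
brute_force_optimal <- function(solutions) {
  P <- vapply(solutions, `[[`, integer(1), "populated")
  top <- solutions[P == min(P)]
  D <- vapply(top, `[[`, integer(1), "depth")
  top <- top[D == min(D)]
  key <- vapply(top, function(s)
    paste(sprintf("%03d", ifelse(is.na(s$tree$parent), 0L, s$tree$parent)),
          collapse = ""), character(1))
  top[order(key)]
}
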