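#' User-supplied topology constraints
#'
#' Constraints restrict the trees considered during enumeration: an ancestor
#' pair `(a, b)` requires clone `a` on the root path of clone `b`; an
#' exclusive pair requires the two clones to sit on separate branches
#' (neither an ancestor of the other). Pairs may be given as clone indices
#' or as aberration labels (resolved against a signal inside [deconvolve()]).
#'
#' @param ancestor two-column matrix (or NULL); each row `(a, b)` = "a is an
#'   ancestor of b".
#' @param exclusive two-column matrix (or NULL); each row = "on separate
#'   branches".
#' @return object of class `constraint_set`
#' @export
constraint_set <- function(ancestor = NULL, exclusive = NULL) {
  norm <- function(p) {
    if (is.null(p) || NROW(p) == 0L) return(NULL)
    p <- if (is.matrix(p) || is.data.frame(p)) as.matrix(p) else matrix(p, ncol = 2, byrow = TRUE)
    if (ncol(p) != 2L) stop_input_error("constraint pairs must have two columns")
    p
  }
  structure(list(ancestor = norm(ancestor), exclusive = norm(exclusive)),
            class = "constraint_set")
}

#' Resolve label-based constraints to clone indices for a given signal
#' @keywords internal
resolve_constraints <- function(constraints, signal) {
  if (is.null(constraints)) return(constraint_set())
  res <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.character(p)) {
      idx <- match(p, signal$labels)
      if (anyNA(idx))
        stop_input_error(paste("unknown constraint label(s):",
                               paste(p[is.na(idx)], collapse = ", "),
                               "(was a constrained label merged by clustering?)"))
      p <- idx
    }
    matrix(as.integer(p), ncol = 2)
  }
  constraint_set(res(constraints$ancestor), res(constraints$exclusive))
}

#' Detect all first-generation trees of an aggregate signal
#'
#' A first-generation tree is an unpopulated clone `i0` together with the
#' complete set `S` of its direct descendants, certified by the frequency-sum
#' criterion: clone `i0` carries no cells of its own exactly when its
#' aggregate frequency equals the summed aggregate frequencies of its
#' children. Under the bound model the criterion becomes
#' `|y_i0 - sum(y_S)| <= eps_i0 + sum(eps_S)`; under the normal model, 0 must
#' lie inside the two-sided `1 - alpha` interval of
#' `Normal(y_i0 - sum(y_S), eps_i0^2 + sum(eps_S^2))`.
#'
#' The subset search runs over children sorted by descending frequency with
#' two-sided partial-sum pruning, so only subsets whose running sum can still
#' land inside the allowance are explored.
#'
#' @param signal an [aggregate_signal()]
#' @param model an [error_model()]
#' @param max_n refuse signals larger than this (cluster first); default 25.
#' @return list of first-generation trees, each `list(parent = i0,
#'   children = sorted indices)`
#' @examples
#' s <- aggregate_signal(c(1, 0.6, 0.4), labels = c("d", "a", "b"))
#' find_first_generation_trees(s)   # (1; {2,3}) since 0.6 + 0.4 = 1
#' @export
find_first_generation_trees <- function(signal, model = error_model("exact"),
                                        max_n = 25) {
  n <- length(signal$y)
  if (n > max_n)
    stop_cap_error(sprintf(
      "signal has %d entries (cap %d); cluster similar frequencies first", n, max_n))
  y <- signal$y
  eps <- signal$eps
  out <- vector("list", 0L)
  if (n < 2L) return(out)
  for (i0 in seq_len(n - 1L)) {
    cand <- seq.int(i0 + 1L, n)
    k <- length(cand)
    target <- y[i0]
    suffix <- rev(cumsum(rev(y[cand])))            # sum of y over cand[t..k]
    allow_max <- em_allowance(model, eps[i0], eps[cand])
    acc <- function(chosen, s, esum, esq) {
      allow <- switch(model$kind,
        exact  = .decon_tol,
        bound  = eps[i0] + esum + .decon_tol,
        normal = model$z * sqrt(eps[i0]^2 + esq) + .decon_tol)
      abs(target - s) <= allow
    }
    dfs <- function(t, chosen, s, esum, esq) {
      if (length(chosen) && acc(chosen, s, esum, esq))
        out[[length(out) + 1L]] <<- list(parent = i0, children = cand[chosen])
      if (t > k) return()
      if (s - target > allow_max) return()         # sums only grow
      if (target - (s + suffix[t]) > allow_max) return()  # unreachable
      for (tt in t:k) {
        j <- cand[tt]
        s2 <- s + y[j]
        if (s2 - target > allow_max) next          # later cands are smaller, keep trying
        dfs(tt + 1L, c(chosen, tt), s2, esum + eps[j], esq + eps[j]^2)
      }
    }
    dfs(1L, integer(0), 0, 0, 0)
  }
  out
}

#' Combine first-generation trees into partial trees
#'
#' A partial tree is a mutually compatible collection of first-generation
#' trees: no two members share a parent, no clone is claimed as a child by
#' two members (edges always run from lower to higher index, so acyclicity is
#' automatic). Every sparsest full solution must contain one of the partial
#' trees of maximum size `h*`, so this step fixes the search seeds. With
#' `slack > 0` all compatible collections of size at least `h* - slack` are
#' retained, which later yields the less-sparse solutions too.
#'
#' @param fg_trees output of [find_first_generation_trees()]
#' @param slack sparsity relaxation (default 0: maximum-size collections only)
#' @return list of partial trees, each `list(fg = list of FG trees, h = size)`,
#'   sorted by decreasing `h`
#' @export
combine_partial_trees <- function(fg_trees, slack = 0) {
  if (length(fg_trees) == 0L)
    return(list(list(fg = list(), h = 0L)))
  parents <- vapply(fg_trees, `[[`, integer(1) + 0L, "parent")
  masks <- vapply(fg_trees, function(f) sum(bitwShiftL(1L, f$children - 1L)),
                  integer(1))
  groups <- split(seq_along(fg_trees), parents)   # ascending parent order
  G <- length(groups)

  best <- 0L
  pass1 <- function(gi, len, used) {
    if (len > best) best <<- len
    if (gi > G || len + (G - gi + 1L) <= best) return()
    pass1(gi + 1L, len, used)                      # skip this parent
    for (v in groups[[gi]])
      if (bitwAnd(used, masks[v]) == 0L)
        pass1(gi + 1L, len + 1L, bitwOr(used, masks[v]))
  }
  pass1(1L, 0L, 0L)

  thr <- max(best - as.integer(slack), 0L)
  res <- list()
  pass2 <- function(gi, cur, used) {
    if (gi > G) {
      if (length(cur) >= thr && length(cur) > 0L)
        res[[length(res) + 1L]] <<- list(fg = fg_trees[cur],
                                         h = length(cur))
      return()
    }
    if (length(cur) + (G - gi + 1L) < thr) return()
    pass2(gi + 1L, cur, used)
    for (v in groups[[gi]])
      if (bitwAnd(used, masks[v]) == 0L)
        pass2(gi + 1L, c(cur, v), bitwOr(used, masks[v]))
  }
  pass2(1L, integer(0), 0L)
  if (thr == 0L) res[[length(res) + 1L]] <- list(fg = list(), h = 0L)
  res[order(-vapply(res, `[[`, integer(1), "h"))]
}

#' Enumerate all full clone trees consistent with a partial tree
#'
#' Builds trees by inserting clones in index order. Parents of member
#' first-generation trees have frozen child sets: their children attach to
#' them automatically, and no other clone may attach beneath them. Every
#' other clone may attach to any already-placed unfrozen clone, subject to
#' (i) feasibility - the parent's running frequency stays above the negative
#' slack tolerated by the error model, (ii) user ancestor/exclusivity
#' constraints, and (iii) in the exact model, the attachment must not drive a
#' non-frozen parent's frequency to zero, since such a tree belongs to a
#' larger partial tree and would be enumerated twice.
#'
#' @param signal an [aggregate_signal()]
#' @param partial a partial tree from [combine_partial_trees()]
#' @param constraints a [constraint_set()] with index pairs, or NULL
#' @param model an [error_model()]
#' @param max_solutions stop after this many trees (marks truncation)
#' @return list of parent integer vectors; attribute `truncated` is TRUE if
#'   the cap was hit
#' @export
enumerate_solutions <- function(signal, partial, constraints = NULL,
                                model = error_model("exact"),
                                max_solutions = Inf) {
  n <- length(signal$y)
  y <- signal$y
  eps <- signal$eps
  cs <- if (is.null(constraints)) constraint_set() else constraints

  fg_parent_of <- rep(NA_integer_, n)
  frozen <- logical(n)
  for (f in partial$fg) {
    frozen[f$parent] <- TRUE
    if (any(!is.na(fg_parent_of[f$children])))
      stop_input_error("partial tree claims a clone as child twice")
    fg_parent_of[f$children] <- f$parent
  }

  anc_req <- cs$ancestor     # rows (a, b): a ancestor of b
  if (!is.null(anc_req) && any(anc_req[, 1] >= anc_req[, 2]))
    return(structure(list(), truncated = FALSE))
  exc <- cs$exclusive
  if (!is.null(exc)) {
    exc <- t(apply(exc, 1L, sort))                 # normalize a < b
    if (any(exc[, 1] == exc[, 2]))
      stop_input_error("exclusive constraint pairs a clone with itself")
  }
  anc_by_child <- if (is.null(anc_req)) NULL else split(anc_req[, 1], anc_req[, 2])
  exc_by_child <- if (is.null(exc)) NULL else split(exc[, 1], exc[, 2])

  out <- list()
  truncated <- FALSE
  bit <- bitwShiftL(1L, 0:(n - 1L))

  place <- function(i, parent, x, esum, esq, amask) {
    if (truncated) return()
    if (i > n) {
      if (length(out) >= max_solutions) { truncated <<- TRUE; return() }
      out[[length(out) + 1L]] <<- parent
      return()
    }
    attach_ok <- function(j) {
      pm <- bitwOr(amask[j], bit[i])               # root path of i after attach
      a <- anc_by_child[[as.character(i)]]
      if (!is.null(a) && any(bitwAnd(amask[j], bit[a]) == 0L)) return(NULL)
      e <- exc_by_child[[as.character(i)]]
      if (!is.null(e) && any(bitwAnd(amask[j], bit[e]) != 0L)) return(NULL)
      pm
    }
    fgp <- fg_parent_of[i]
    if (!is.na(fgp)) {
      pm <- attach_ok(fgp)
      if (is.null(pm)) return()
      parent[i] <- fgp
      x[fgp] <- x[fgp] - y[i]
      esum[fgp] <- esum[fgp] + eps[i]
      esq[fgp] <- esq[fgp] + eps[i]^2
      amask[i] <- pm
      place(i + 1L, parent, x, esum, esq, amask)
      return()
    }
    for (j in seq_len(i - 1L)) {
      if (frozen[j]) next
      xj <- x[j] - y[i]
      if (model$kind == "exact") {
        if (xj <= .decon_tol) next                 # infeasible or duplicate zero
      } else {
        slack <- switch(model$kind,
          bound  = eps[j] + esum[j] + eps[i] + .decon_tol,
          normal = model$z * sqrt(eps[j]^2 + esq[j] + eps[i]^2) + .decon_tol)
        if (xj < -slack) next
      }
      pm <- attach_ok(j)
      if (is.null(pm)) next
      parent2 <- parent; parent2[i] <- j
      x2 <- x; x2[j] <- xj
      esum2 <- esum; esum2[j] <- esum[j] + eps[i]
      esq2 <- esq; esq2[j] <- esq[j] + eps[i]^2
      amask2 <- amask; amask2[i] <- pm
      place(i + 1L, parent2, x2, esum2, esq2, amask2)
      if (truncated) return()
    }
  }

  amask0 <- integer(n); amask0[1] <- bit[1]
  place(2L, rep(NA_integer_, n), y, numeric(n), numeric(n), amask0)
  structure(out, truncated = truncated)
}

#' Fit subclone frequencies by constrained nonnegative least squares
#'
#' Minimizes `||y - C x||_2` subject to `x >= 0` and `x[k] = 0` exactly for
#' every unpopulated clone `k` (the parents of the chosen partial tree's
#' first-generation trees). With noise-free input this reproduces the
#' back-substitution values; with noisy input it distributes measurement
#' error across the populated clones while keeping the unpopulated ones at
#' exactly zero.
#'
#' @param signal an [aggregate_signal()]
#' @param tree a [clone_tree()]
#' @param unpopulated indices forced to zero
#' @return list with `x` (length-N vector) and `residual` (L2 norm)
#' @export
fit_frequencies_nnls <- function(signal, tree, unpopulated = integer(0)) {
  n <- length(signal$y)
  C <- genotype_matrix(tree)
  free <- setdiff(seq_len(n), unpopulated)
  fit <- nnls_lawson_hanson(C[, free, drop = FALSE], signal$y)
  x <- numeric(n)
  x[free] <- fit$x
  list(x = x, residual = fit$residual)
}

#' Deconvolve an aggregate signal into optimal subclonal structures
#'
#' The five-step algorithm: (1) detect all first-generation trees under the
#' active error model; (2) combine them into partial trees; (3) keep the
#' partial trees with the maximum number `h*` of first-generation trees -
#' every sparsest solution (minimum number `P = N - h*` of populated
#' subclones) must contain one of them; (4) grow each partial tree into all
#' consistent full evolutionary trees by ordered insertion; (5) fit
#' frequencies (back-substitution in the exact model, constrained NNLS
#' otherwise), then rank by sparsity `P`, then shallowness `D` (tree depth),
#' returning all optima in canonical order (ascending depth, then
#' lexicographic parent arrays).
#'
#' @param signal an [aggregate_signal()]
#' @param model an [error_model()]
#' @param constraints optional [constraint_set()] (indices or labels)
#' @param sparsity_slack also keep partial trees of size >= `h* - slack`,
#'   yielding solutions with up to `slack` extra populated subclones among
#'   the candidates.
#' @param max_n refuse larger signals (default 25; cluster first)
#' @param max_solutions cap on enumerated trees (default 10000)
#' @param count_populated_from_fit if TRUE, count `P` from post-fit nonzeros
#'   instead of `N - h` (differs only under noisy models)
#' @param rescore optional function `(solution, signal) -> numeric score`
#'   (lower is better) replacing the default (P, D, residual) ranking
#' @return object of class `decon_result`: `solutions` (the optimal set),
#'   `candidates` (every enumerated solution, ranked), `h_star`, `p_min`,
#'   `fg_count`, `truncated`, plus the signal and model
#' @examples
#' s <- build_signal(data.frame(label = c("a", "b"), y = c(0.6, 0.4)))
#' deconvolve(s)
#' @export
deconvolve <- function(signal, model = error_model("exact"),
                       constraints = NULL, sparsity_slack = 0,
                       max_n = 25, max_solutions = 10000,
                       count_populated_from_fit = FALSE, rescore = NULL) {
  stopifnot(inherits(signal, "aggregate_signal"))
  n <- length(signal$y)
  if (n > max_n)
    stop_cap_error(sprintf(
      "signal has %d entries (cap %d); cluster similar frequencies first", n, max_n))
  cs <- resolve_constraints(constraints, signal)

  if (n == 1L) {
    sol <- clone_solution(clone_tree(NA), x = 1, signal = signal,
                          populated = 1L, method = model$kind)
    return(structure(list(solutions = list(sol), candidates = list(sol),
                          h_star = 0L, p_min = 1L, fg_count = 0L,
                          truncated = FALSE, signal = signal, model = model),
                     class = "decon_result"))
  }

  fg <- find_first_generation_trees(signal, model, max_n = max_n)
  partials <- combine_partial_trees(fg, slack = sparsity_slack)
  h_star <- max(vapply(partials, `[[`, integer(1), "h"))

  seen <- new.env(parent = emptyenv())
  cands <- list()
  truncated <- FALSE
  build_from <- function(partial) {
    trees <- enumerate_solutions(signal, partial, cs, model,
                                 max_solutions = max_solutions - length(cands))
    if (isTRUE(attr(trees, "truncated"))) truncated <<- TRUE
    frozen <- vapply(partial$fg, `[[`, integer(1) + 0L, "parent")
    for (par in trees) {
      key <- paste(par, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      tree <- clone_tree(par)
      if (model$kind == "exact") {
        x <- clone_frequencies(tree, signal)
        x[abs(x) <= .decon_tol] <- 0
        resid <- 0
      } else {
        fit <- fit_frequencies_nnls(signal, tree, unpopulated = frozen)
        x <- fit$x
        resid <- fit$residual
      }
      P <- if (count_populated_from_fit) sum(x > .decon_tol) else n - partial$h
      sol <- clone_solution(tree, x, signal, populated = P,
                            method = model$kind, unpopulated = frozen)
      sol$fit_residual <- resid
      cands[[length(cands) + 1L]] <<- sol
    }
  }
  for (p in partials) build_from(p)

  if (length(cands) == 0L) {
    # all maximal partial trees infeasible to complete; relax until something
    # completes (an unconstrained chain always exists at h = 0)
    hdone <- min(vapply(partials, `[[`, integer(1), "h"))
    while (length(cands) == 0L && hdone > 0L) {
      widened <- combine_partial_trees(fg, slack = h_star - hdone + 1L)
      hs <- vapply(widened, `[[`, integer(1), "h")
      for (p in widened[hs == hdone - 1L]) build_from(p)
      hdone <- hdone - 1L
    }
  }
  if (length(cands) == 0L) {
    if (is.null(cs$ancestor) && is.null(cs$exclusive))
      stop("internal error: no feasible tree found (a chain should always exist)")
    # user constraints excluded every tree: an empty result, not an error
    return(structure(list(solutions = list(), candidates = list(),
                          h_star = h_star, p_min = NA_integer_,
                          fg_count = length(fg), truncated = truncated,
                          signal = signal, model = model),
                     class = "decon_result"))
  }

  ord_key <- function(s) paste(sprintf("%03d", c(s$populated, s$depth,
                                                 ifelse(is.na(s$tree$parent), 0L,
                                                        s$tree$parent))),
                               collapse = "")
  cands <- cands[order(vapply(cands, ord_key, character(1)))]

  if (is.null(rescore)) {
    P <- vapply(cands, `[[`, integer(1), "populated")
    p_min <- min(P)
    top <- cands[P == p_min]
    D <- vapply(top, `[[`, integer(1), "depth")
    sols <- top[D == min(D)]
  } else {
    sc <- vapply(cands, function(s) as.numeric(rescore(s, signal)[1]), numeric(1))
    cands <- cands[order(sc)]
    sc <- sort(sc)
    sols <- cands[sc <= min(sc) + .decon_tol]
    p_min <- min(vapply(cands, `[[`, integer(1), "populated"))
  }

  structure(list(solutions = sols, candidates = cands,
                 h_star = h_star, p_min = p_min,
                 fg_count = length(fg), truncated = truncated,
                 signal = signal, model = model),
            class = "decon_result")
}

#' @export
print.decon_result <- function(x, ...) {
  cat(sprintf(
    "Deconvolution: N = %d, %d first-generation trees, h* = %d, min P = %d\n",
    length(x$signal$y), x$fg_count, x$h_star, x$p_min))
  cat(sprintf("%d optimal solution(s) of %d candidate(s)%s\n",
              length(x$solutions), length(x$candidates),
              if (x$truncated) " [TRUNCATED at cap]" else ""))
  if (length(x$solutions)) print(x$solutions[[1]])
  if (length(x$solutions) > 1L)
    cat("... and", length(x$solutions) - 1L, "more optimal solution(s)\n")
  invisible(x)
}
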