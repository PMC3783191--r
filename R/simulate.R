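#' Simulate a random clone tree with a planted sparse solution
#'
#' Generates the ground truth used by the noisy-aggregate benchmarks: a
#' uniformly random ordered tree (`parent[i]` uniform on `1..i-1`), a
#' populated set consisting of all leaves plus uniformly chosen extra clones
#' to reach `P`, populated frequencies from a flat (symmetric, parameter 1)
#' Dirichlet, and the exact aggregate signal of that tree. If a sampled tree
#' has more leaves than `P` it is resampled, keeping the tree distribution
#' uniform conditional on the leaf bound.
#'
#' Clones are relabelled so the aggregate is non-increasing (ties broken by
#' original index, which keeps parents before children); the returned truth
#' is expressed in the sorted index space of its `signal`.
#'
#' Uses R's global RNG stream; call `set.seed()` for reproducibility.
#'
#' @param n aberration count including the dummy (N >= 1)
#' @param p populated subclone count, `1 <= p <= n`
#' @param max_attempts resampling cap before refusal
#' @return list of class `sim_truth`: `tree`, `x`, `y_clean`, `signal`
#'   (an [aggregate_signal()] with labels `m01..`), `populated` (indices),
#'   `p`, `n`
#' @export
simulate_clone_tree <- function(n, p = n, max_attempts = 1000) {
  if (p < 1L || p > n) stop_input_error("need 1 <= p <= n")
  if (n == 1L) {
    sig <- aggregate_signal(1, 0, "dummy")
    return(structure(list(tree = clone_tree(NA), x = 1, y_clean = 1,
                          signal = sig, populated = 1L, p = 1L, n = 1L),
                     class = "sim_truth"))
  }
  parent <- NULL
  for (attempt in seq_len(max_attempts)) {
    par <- c(NA_integer_, vapply(2:n, function(i)
      sample.int(i - 1L, 1L), integer(1)))
    tr <- clone_tree(par)
    leaves <- which(lengths(tr$children) == 0L)
    if (length(leaves) <= p) { parent <- par; break }
  }
  if (is.null(parent))
    stop_input_error(sprintf(
      "could not sample a tree with <= %d leaves in %d attempts", p, max_attempts))
  tree <- clone_tree(parent)
  leaves <- which(lengths(tree$children) == 0L)
  extra <- setdiff(seq_len(n), leaves)
  populated <- sort(c(leaves,
                      if (p > length(leaves))
                        sample(extra, p - length(leaves))))
  x <- numeric(n)
  g <- stats::rgamma(p, shape = 1)
  x[populated] <- g / sum(g)
  y <- as.numeric(genotype_matrix(tree) %*% x)

  ord <- order(-y, seq_len(n), method = "radix")    # parents stay first on ties
  rank <- match(seq_len(n), ord)
  par2 <- rep(NA_integer_, n)
  for (j in seq_len(n)[-1]) par2[rank[j]] <- rank[tree$parent[j]]
  tree2 <- clone_tree(par2)
  labels <- c("dummy", sprintf("m%02d", seq_len(n)[-1]))[ord]
  sig <- aggregate_signal(y[ord], numeric(n), labels)
  structure(list(tree = tree2, x = x[ord], y_clean = y[ord], signal = sig,
                 populated = sort(rank[populated]), p = as.integer(p),
                 n = as.integer(n)),
            class = "sim_truth")
}

#' Perturb an aggregate signal with uniform measurement noise
#'
#' Adds independent `Uniform(-E, E)` noise to every entry except the dummy
#' and clips to `[0, 1]`. The paired error vector (all `E`, dummy 0) is the
#' natural input for the bound error model.
#'
#' @param y clean aggregate vector (`y[1] = 1`)
#' @param E noise half-width (>= 0)
#' @return list with `y` (noisy, clipped) and `eps`
#' @export
perturb_signal <- function(y, E) {
  if (E < 0) stop_input_error("E must be nonnegative")
  n <- length(y)
  noise <- c(0, stats::runif(n - 1L, -E, E))
  list(y = pmin(pmax(y + noise, 0), 1), eps = c(0, rep(E, n - 1L)))
}

#' Noisy signal of a simulated truth, re-sorted for the solver
#'
#' Perturbs the truth's clean aggregate, re-sorts (noise can reorder
#' entries) and remaps the truth tree into the new index space when the
#' remapped parents still respect descent ordering.
#'
#' @param truth a `sim_truth`
#' @param E noise half-width
#' @return list: `signal` (sorted noisy [aggregate_signal()]), `truth_parent`
#'   (remapped parent array, or NULL if noise broke the ordering),
#'   `truth_x` (remapped), `perm`
#' @export
noisy_instance <- function(truth, E) {
  pert <- perturb_signal(truth$y_clean, E)
  n <- length(pert$y)
  ord <- order(-pert$y, seq_len(n), method = "radix")
  rank <- match(seq_len(n), ord)
  sig <- aggregate_signal(pert$y[ord], pert$eps[ord], truth$signal$labels[ord])
  par2 <- rep(NA_integer_, n)
  ok <- TRUE
  for (j in seq_len(n)[-1]) {
    pj <- rank[truth$tree$parent[j]]
    par2[rank[j]] <- pj
    if (pj >= rank[j]) ok <- FALSE
  }
  C <- genotype_matrix(truth$tree)
  pop <- which(truth$x > .decon_tol)
  gsets <- lapply(pop, function(j)
    sort(setdiff(truth$signal$labels[C[, j] == 1L], "dummy")))
  list(signal = sig,
       truth_parent = if (ok) par2 else NULL,
       truth_x = truth$x[ord],
       truth_genotypes = gsets,
       truth_w = truth$x[pop],
       perm = ord)
}

#' Mix known subclone genotypes into an aggregate signal
#'
#' Forward-simulates the bulk measurement of a sample composed of known
#' subclones: `y_i = sum_j G[i, j] w_j` for a binary genotype matrix `G`
#' (rows aberrations, columns subclones) and nonnegative weights `w`. If
#' weights are omitted they are drawn from a flat Dirichlet over the
#' subclones, optionally with an extra wildtype component.
#'
#' @param genotypes binary matrix, rows = aberrations (rownames = labels),
#'   columns = subclones
#' @param weights optional nonnegative weights, one per column (normalized);
#'   if `include_wildtype`, an extra final weight for the wildtype may be
#'   supplied, otherwise the wildtype weight is drawn too
#' @param include_wildtype add an aberration-free component (default TRUE)
#' @return list: `signal` (sorted [aggregate_signal()]), `weights` (named,
#'   normalized, incl. `wildtype` if requested), `genotypes`
#' @export
mix_genotypes <- function(genotypes, weights = NULL, include_wildtype = TRUE) {
  G <- as.matrix(genotypes)
  if (is.null(rownames(G))) rownames(G) <- sprintf("a%02d", seq_len(nrow(G)))
  if (is.null(colnames(G))) colnames(G) <- sprintf("S%d", seq_len(ncol(G)))
  if (any(colSums(G) == 0))
    stop_input_error("genotype matrix has an empty (all-zero) subclone column")
  k <- ncol(G) + as.integer(include_wildtype)
  if (is.null(weights)) {
    g <- stats::rgamma(k, shape = 1)
    w <- g / sum(g)
  } else {
    if (any(weights < 0)) stop_input_error("weights must be nonnegative")
    if (length(weights) == ncol(G) && include_wildtype)
      weights <- c(weights, max(0, 1 - sum(weights)))
    if (length(weights) != k) stop_input_error("one weight per subclone required")
    w <- weights / sum(weights)
  }
  wsub <- w[seq_len(ncol(G))]
  y <- as.numeric(G %*% wsub)
  names(w) <- c(colnames(G), if (include_wildtype) "wildtype")
  sig <- build_signal(data.frame(label = rownames(G), y = y))
  list(signal = sig, weights = w, genotypes = G)
}

#' Score one simulation run against the planted truth
#'
#' Returns the three success indicators of the noisy-aggregate benchmark:
#' * `sparsest` - the truth's populated count equals the minimum over all
#'   candidate solutions;
#' * `in_solutions` - the truth's tree appears in the optimal set with
#'   frequencies within `tol`;
#' * `unique` - the optimal set is a single solution equal to the truth.
#'
#' @param inst a [noisy_instance()] (or a list with `truth_parent`,
#'   `truth_x`)
#' @param result a `decon_result` computed on `inst$signal`
#' @param tol frequency tolerance for matching `x` (default: the noise
#'   half-width is a natural choice; 1e-6 for noise-free runs)
#' @param candidates optional independently computed candidate list (e.g.
#'   from [brute_force_solve()]) for the sparsest check; defaults to the
#'   solver's candidates
#' A solution "equals the truth" when its parent array and frequencies match,
#' or - robust to noise swapping the sort order of tied (equal-frequency)
#' entries - when its populated clones carry exactly the truth's genotypes
#' at the truth's frequencies. The two notions coincide whenever no
#' frequencies tie.
#'
#' @return logical vector `c(sparsest, in_solutions, unique)`
#' @export
evaluate_run <- function(inst, result, tol = 1e-6, candidates = NULL) {
  truth_p <- sum(inst$truth_x > .decon_tol)
  if (is.null(candidates)) candidates <- result$candidates
  min_p <- min(vapply(candidates, `[[`, integer(1), "populated"))
  sparsest <- truth_p == min_p
  tkey <- sort(vapply(seq_along(inst$truth_genotypes), function(k)
    paste(inst$truth_genotypes[[k]], collapse = "+"), character(1)))
  matches <- function(sol) {
    if (!is.null(inst$truth_parent) &&
        identical(ifelse(is.na(sol$tree$parent), 0L, sol$tree$parent),
                  ifelse(is.na(inst$truth_parent), 0L, as.integer(inst$truth_parent))) &&
        max(abs(sol$x - inst$truth_x)) <= tol + .decon_tol)
      return(TRUE)
    gt <- populated_genotypes(sol)
    if (length(gt) != length(inst$truth_genotypes)) return(FALSE)
    skey <- sort(unname(vapply(gt, paste, character(1), collapse = "+")))
    if (!identical(skey, tkey)) return(FALSE)
    for (k in seq_along(inst$truth_genotypes)) {
      key <- paste(inst$truth_genotypes[[k]], collapse = "+")
      j <- as.integer(names(gt)[vapply(gt, paste, character(1),
                                       collapse = "+") == key][1])
      if (abs(sol$x[j] - inst$truth_w[k]) > tol + .decon_tol) return(FALSE)
    }
    TRUE
  }
  in_sols <- any(vapply(result$solutions, matches, logical(1)))
  c(sparsest = sparsest, in_solutions = in_sols,
    unique = in_sols && length(result$solutions) == 1L)
}

#' Did a deconvolution recover all true subclones in correct proportions?
#'
#' TRUE iff at least one returned solution contains every true subclone
#' genotype (as the aberration set of a populated clone) with fitted
#' frequency within `tol` of the true mixing weight.
#'
#' @param result a `decon_result`
#' @param genotypes true binary genotype matrix (as in [mix_genotypes()])
#' @param weights named true weights (a `wildtype` entry, if present, is
#'   checked against the solution's wildtype clone)
#' @param tol absolute frequency tolerance
#' @return logical scalar
#' @export
recovery_check <- function(result, genotypes, weights, tol = 1e-6) {
  G <- as.matrix(genotypes)
  truth <- lapply(seq_len(ncol(G)), function(j)
    sort(rownames(G)[G[, j] == 1]))
  wsub <- weights[seq_len(ncol(G))]
  for (sol in result$solutions) {
    gt <- populated_genotypes(sol, threshold = .decon_tol)
    ok <- TRUE
    for (j in seq_along(truth)) {
      hit <- which(vapply(gt, identical, logical(1), truth[[j]]))
      if (length(hit) == 0L ||
          abs(sol$x[as.integer(names(gt)[hit[1]])] - wsub[j]) > tol) {
        ok <- FALSE; break
      }
    }
    if (ok && "wildtype" %in% names(weights)) {
      if (abs(sol$x[1] - weights[["wildtype"]]) > tol) ok <- FALSE
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Fraction of solution co-occurrences confirmed by reference genotypes
#'
#' Over all unordered aberration pairs that co-occur in at least one
#' populated clone of the solution, the fraction that also co-occur in at
#' least one reference genotype (e.g. single-cell profiles).
#'
#' @param solution a `clone_solution`
#' @param reference list of character vectors (aberration label sets), or a
#'   binary matrix with rownames as labels (columns = cells)
#' @return fraction in `[0, 1]`; `NA` (flagged via attribute `undefined`)
#'   when the solution has no co-occurring pairs; 0 with a warning for an
#'   empty reference
#' @export
cooccurrence_fraction <- function(solution, reference) {
  if (is.matrix(reference))
    reference <- lapply(seq_len(ncol(reference)), function(j)
      rownames(reference)[reference[, j] == 1])
  gt <- populated_genotypes(solution)
  pairs <- unique(do.call(rbind, lapply(gt, function(g) {
    if (length(g) < 2L) return(NULL)
    t(utils::combn(sort(g), 2L))
  })))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(structure(NA_real_, undefined = TRUE))
  if (length(reference) == 0L) {
    warning("empty reference genotype set")
    return(0)
  }
  hit <- apply(pairs, 1L, function(pr)
    any(vapply(reference, function(r) all(pr %in% r), logical(1))))
  mean(hit)
}

#' Benchmark grid over tree size, sparsity and noise
#'
#' For each cell `(N, P, E)` runs `runs` simulations through
#' [simulate_clone_tree()], [perturb_signal()] and [deconvolve()] (bound
#' model with `eps = E`; exact model when `E = 0`), scoring each with
#' [evaluate_run()]. Reproducible bit-for-bit for a fixed `seed`.
#'
#' @param Ns,Ps,Es vectors of tree sizes, populated counts and noise
#'   half-widths; cells with `P > N` are skipped
#' @param runs simulations per cell
#' @param seed RNG seed
#' @param out_csv optional path: write the table as CSV
#' @param max_attempts passed to [simulate_clone_tree()]
#' @return data.frame with columns `N`, `P`, `E`, `runs`, `pct_sparsest`,
#'   `pct_in_solutions`, `pct_unique`
#' @export
benchmark_grid <- function(Ns, Ps, Es, runs = 100, seed = 1,
                           out_csv = NULL, max_attempts = 5000) {
  set.seed(seed)
  rows <- list()
  for (N in Ns) for (P in Ps[Ps <= N]) for (E in Es) {
    hits <- matrix(FALSE, runs, 3L)
    for (r in seq_len(runs)) {
      truth <- simulate_clone_tree(N, P, max_attempts = max_attempts)
      inst <- noisy_instance(truth, E)
      model <- if (E == 0) error_model("exact") else error_model("bound")
      res <- deconvolve(inst$signal, model = model)
      hits[r, ] <- evaluate_run(inst, res, tol = max(E, 1e-6))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, P = P, E = E, runs = runs,
      pct_sparsest = 100 * mean(hits[, 1]),
      pct_in_solutions = 100 * mean(hits[, 2]),
      pct_unique = 100 * mean(hits[, 3]))
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
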