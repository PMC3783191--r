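#' A locus carrying several distinct derived alleles
#'
#' Polyallelic sites arise when the same nucleotide mutates more than once in
#' a cell population - either in parallel on sibling branches (two
#' independent origins from the reference) or serially along one lineage
#' (e.g. A to G, then G to C, written `170:A>G>C`). Each phasing hypothesis
#' reduces to a different binary problem; the solver tries all of them.
#'
#' @param position locus identifier (string or number)
#' @param ref reference allele
#' @param alleles data.frame with columns `allele`, `freq`, optional `eps`:
#'   the observed frequency of each derived allele (frequency of cells whose
#'   current state is that allele)
#' @param known_chains optional character vector of declared serial orders,
#'   e.g. `"A>G>C"` (leading reference allele optional); hypotheses not
#'   containing each declared order as a consecutive subchain are pruned
#' @return object of class `multiallelic_site`
#' @export
multiallelic_site <- function(position, ref, alleles, known_chains = NULL) {
  alleles <- as.data.frame(alleles)
  if (!all(c("allele", "freq") %in% names(alleles)))
    stop_input_error("alleles need columns 'allele' and 'freq'")
  if (is.null(alleles$eps)) alleles$eps <- 0
  if (NROW(alleles) < 1L) stop_input_error("site needs at least one derived allele")
  if (anyDuplicated(alleles$allele)) stop_input_error("duplicate derived alleles")
  if (any(alleles$freq < 0) || any(alleles$freq > 1))
    stop_input_error("allele frequencies must lie in [0, 1]")
  if (sum(alleles$freq) > 1 + sum(alleles$eps) + .decon_tol)
    stop_input_error("derived allele frequencies jointly exceed 1")
  structure(list(position = as.character(position), ref = as.character(ref),
                 alleles = alleles,
                 known_chains = as.character(known_chains %||% character(0))),
            class = "multiallelic_site")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All ways to arrange items into an unordered set of ordered chains
#' @noRd
chain_partitions <- function(items) {
  if (length(items) == 0L) return(list(list()))
  first <- items[1]
  out <- list()
  for (h in chain_partitions(items[-1])) {
    out[[length(out) + 1L]] <- c(h, list(first))    # new singleton chain
    for (ci in seq_along(h)) {
      chain <- h[[ci]]
      for (pos in 0:length(chain)) {
        h2 <- h
        h2[[ci]] <- append(chain, first, after = pos)
        out[[length(out) + 1L]] <- h2
      }
    }
  }
  out
}

#' @noRd
chain_contains <- function(chain, sub) {
  k <- length(sub)
  if (k > length(chain)) return(FALSE)
  for (s in seq_len(length(chain) - k + 1L))
    if (identical(chain[s:(s + k - 1L)], sub)) return(TRUE)
  FALSE
}

#' Reduce polyallelic sites to binary deconvolution problems
#'
#' Each site is expanded into its phasing hypotheses: every arrangement of
#' its derived alleles into chains (parallel chains = independent origins,
#' mutually exclusive branches; a chain `ref>B>C` = serial mutation). Under
#' a serial hypothesis the upstream event's frequency is the sum of its own
#' and all downstream allele frequencies - cells that mutated onward still
#' carry the earlier event. Hypotheses across sites combine by Cartesian
#' product, capped.
#'
#' A site with one derived allele yields a single unconstrained event; a
#' biallelic site yields three hypotheses (parallel, serial either way).
#'
#' @param sites list of [multiallelic_site()] objects
#' @param cap refuse when the hypothesis product exceeds this (default 729)
#' @return list of reductions, each `list(events, ancestor, exclusive,
#'   hypothesis)` where `events` is a data.frame (`label`, `y`, `eps`) and
#'   the constraint entries are two-column character matrices of labels
#' @export
expand_polyallelic <- function(sites, cap = 729) {
  if (inherits(sites, "multiallelic_site")) sites <- list(sites)
  per_site <- lapply(sites, function(site) {
    hyps <- chain_partitions(as.character(site$alleles$allele))
    for (kc in site$known_chains) {
      seqc <- strsplit(kc, ">", fixed = TRUE)[[1]]
      if (length(seqc) && seqc[1] == site$ref) seqc <- seqc[-1]
      hyps <- Filter(function(h)
        any(vapply(h, chain_contains, logical(1), seqc)), hyps)
    }
    if (length(hyps) == 0L)
      stop_input_error(sprintf("site %s: declared chains prune all hypotheses",
                               site$position))
    lapply(hyps, function(h) site_reduction(site, h))
  })
  total <- prod(lengths(per_site))
  if (total > cap)
    stop_cap_error(sprintf(
      "polyallelic expansion yields %d hypothesis combinations (cap %d); declare known chains or reduce sites",
      total, cap))
  combos <- list(list())
  for (ps in per_site)
    combos <- unlist(lapply(combos, function(cmb)
      lapply(ps, function(red) c(cmb, list(red)))), recursive = FALSE)
  lapply(combos, function(cmb) {
    list(events = do.call(rbind, lapply(cmb, `[[`, "events")),
         ancestor = do.call(rbind, lapply(cmb, `[[`, "ancestor")),
         exclusive = do.call(rbind, lapply(cmb, `[[`, "exclusive")),
         hypothesis = paste(vapply(cmb, `[[`, character(1), "hypothesis"),
                            collapse = "; "))
  })
}

#' Events and constraints of one site under one chain arrangement
#' @noRd
site_reduction <- function(site, chains) {
  freq <- stats::setNames(site$alleles$freq, site$alleles$allele)
  errs <- stats::setNames(site$alleles$eps, site$alleles$allele)
  events <- list(); anc <- NULL; firsts <- character(0)
  for (chain in chains) {
    prev <- NULL
    for (t in seq_along(chain)) {
      down <- chain[t:length(chain)]
      lab <- paste0(site$position, ":",
                    paste(c(site$ref, chain[seq_len(t)]), collapse = ">"))
      events[[length(events) + 1L]] <-
        data.frame(label = lab, y = sum(freq[down]), eps = sum(errs[down]))
      if (t == 1L) firsts <- c(firsts, lab)
      if (!is.null(prev)) anc <- rbind(anc, c(prev, lab))
      prev <- lab
    }
  }
  exc <- if (length(firsts) > 1L) t(utils::combn(firsts, 2L)) else NULL
  desc <- paste(vapply(chains, function(ch)
    paste(c(site$ref, ch), collapse = ">"), character(1)), collapse = "|")
  list(events = do.call(rbind, events), ancestor = anc, exclusive = exc,
       hypothesis = paste0(site$position, ":", desc))
}

#' Deconvolve a mixture containing polyallelic loci
#'
#' Runs [deconvolve()] on every binary reduction of the polyallelic sites
#' merged with the ordinary binary aberrations, pools the per-hypothesis
#' results and ranks hypotheses by the usual (P, D, residual) criterion.
#'
#' @param sites list of [multiallelic_site()] (may be empty: then this is
#'   exactly the binary pipeline)
#' @param records data.frame of ordinary binary aberrations
#'   (`label`, `y`, optional `eps`), or NULL
#' @param model an [error_model()]
#' @param cap hypothesis-combination cap (see [expand_polyallelic()])
#' @param ... further arguments for [deconvolve()]
#' @return object of class `nonbinary_result`: `runs` (one entry per
#'   hypothesis: `hypothesis`, `result` or `error`), `best` (indices of
#'   optimal hypotheses), `solutions` (optimal solutions across hypotheses,
#'   each carrying a `hypothesis` attribute)
#' @export
solve_nonbinary <- function(sites, records = NULL,
                            model = error_model("exact"), cap = 729, ...) {
  if (length(sites) == 0L) {
    res <- deconvolve(build_signal(records, model), model = model, ...)
    return(structure(list(runs = list(list(hypothesis = "binary",
                                           result = res, error = NULL)),
                          best = 1L, solutions = res$solutions),
                     class = "nonbinary_result"))
  }
  reductions <- expand_polyallelic(sites, cap = cap)
  base <- if (is.null(records)) NULL else {
    records <- as.data.frame(records)
    if (is.null(records$eps)) records$eps <- 0
    records[, c("label", "y", "eps")]
  }
  runs <- lapply(reductions, function(red) {
    recs <- rbind(base, red$events)
    out <- tryCatch({
      sig <- build_signal(recs, model)
      cs <- prune_constraints(red, sig)
      if (is.null(cs)) stop_input_error("hypothesis inconsistent with homogeneous entries")
      res <- deconvolve(sig, model = model, constraints = cs, ...)
      if (length(res$solutions) == 0L)
        stop_input_error("no tree satisfies the hypothesis constraints")
      list(hypothesis = red$hypothesis, result = res, error = NULL)
    }, decon_error = function(e)
      list(hypothesis = red$hypothesis, result = NULL,
           error = conditionMessage(e)))
    out
  })
  score <- vapply(runs, function(r) {
    if (is.null(r$result) || length(r$result$solutions) == 0L)
      return(c(Inf, Inf, Inf))
    sols <- r$result$solutions
    c(min(vapply(sols, `[[`, integer(1), "populated")),
      min(vapply(sols, `[[`, integer(1), "depth")),
      min(vapply(sols, `[[`, numeric(1), "fit_residual")))
  }, numeric(3))
  if (all(!is.finite(score[1, ])))
    return(structure(list(runs = runs, best = integer(0), solutions = list()),
                     class = "nonbinary_result"))
  key <- score[1, ] * 1e8 + score[2, ] * 1e4 + pmin(score[3, ], 999)
  best <- which(abs(key - min(key)) <= 1e-9)
  sols <- list()
  for (b in best) for (s in runs[[b]]$result$solutions) {
    attr(s, "hypothesis") <- runs[[b]]$hypothesis
    sols[[length(sols) + 1L]] <- s
  }
  structure(list(runs = runs, best = best, solutions = sols),
            class = "nonbinary_result")
}

#' Translate a reduction's label constraints to the built signal
#'
#' Events dropped as absent lose their constraints; an exclusivity involving
#' a ubiquitous (trunk) event, or an ancestor constraint whose descendant is
#' ubiquitous while the ancestor is not, is unsatisfiable and the hypothesis
#' is rejected (returns NULL).
#' @noRd
prune_constraints <- function(red, sig) {
  ubiq <- sig$provenance$ubiquitous %||% character(0)
  absent <- sig$provenance$absent %||% character(0)
  keep_pairs <- function(p, kind) {
    if (is.null(p)) return(NULL)
    rows <- list()
    for (r in seq_len(nrow(p))) {
      a <- p[r, 1]; b <- p[r, 2]
      if (kind == "exclusive") {
        if (a %in% ubiq || b %in% ubiq) return("infeasible")
        if (a %in% absent || b %in% absent) next
      } else {
        if (b %in% ubiq && !(a %in% ubiq)) return("infeasible")
        if (a %in% ubiq || a %in% absent) next      # trunk ancestor: trivial
        if (b %in% absent) next
      }
      rows[[length(rows) + 1L]] <- c(a, b)
    }
    if (length(rows) == 0L) NULL else do.call(rbind, rows)
  }
  anc <- keep_pairs(red$ancestor, "ancestor")
  exc <- keep_pairs(red$exclusive, "exclusive")
  if (identical(anc, "infeasible") || identical(exc, "infeasible")) return(NULL)
  constraint_set(ancestor = anc, exclusive = exc)
}

#' @export
print.nonbinary_result <- function(x, ...) {
  cat("Polyallelic deconvolution:", length(x$runs), "hypothesis combination(s),",
      length(x$best), "optimal\n")
  for (b in x$best)
    cat("  winning hypothesis:", x$runs[[b]]$hypothesis, "\n")
  cat(length(x$solutions), "optimal solution(s)\n")
  invisible(x)
}
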