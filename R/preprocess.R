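#' Build an aggregate signal from raw per-aberration measurements
#'
#' Applies the standard preprocessing pipeline: entries indistinguishable
#' from 0 under the active error model are dropped (recorded as absent),
#' entries indistinguishable from 1 are removed from deconvolution and
#' recorded as ubiquitous trunk annotations, a dummy entry (`y = 1`,
#' `eps = 0`) is prepended, and the remaining entries are sorted by
#' frequency, non-increasing, ties broken by ascending label so every
#' downstream enumeration is deterministic.
#'
#' @param records data.frame with columns `label`, `y` and optionally `eps`
#'   (defaults to 0).
#' @param model an [error_model()] governing the homogeneity thresholds.
#' @return an [aggregate_signal()] whose `provenance` records dropped entries
#'   and the original identifiers.
#' @examples
#' build_signal(data.frame(label = c("a2", "a3"), y = c(0.4, 0.6)))
#' @export
build_signal <- function(records, model = error_model("exact")) {
  if (is.null(records) || NROW(records) == 0L) {
    return(aggregate_signal(1, 0, "dummy",
                            provenance = list(absent = character(0),
                                              ubiquitous = character(0))))
  }
  records <- as.data.frame(records)
  if (!all(c("label", "y") %in% names(records)))
    stop_input_error("records need columns 'label' and 'y'")
  if (is.null(records$eps)) records$eps <- 0
  records$eps[is.na(records$eps)] <- 0
  lab <- as.character(records$label)
  y <- as.numeric(records$y)
  eps <- as.numeric(records$eps)
  if (anyNA(y) || any(y < 0) || any(y > 1))
    stop_input_error("frequencies must be numbers in [0, 1]")
  if (any(eps < 0)) stop_input_error("errors must be nonnegative")
  if (anyDuplicated(lab)) stop_input_error("duplicate aberration labels")
  if ("dummy" %in% lab) stop_input_error("'dummy' is a reserved label")

  absent <- mapply(function(yy, ee) abs(yy) <= em_allowance(model, ee, numeric(0)),
                   y, eps)
  ubiq <- !absent &
    mapply(function(yy, ee) abs(yy - 1) <= em_allowance(model, ee, numeric(0)),
           y, eps)
  keep <- !(absent | ubiq)
  ord <- order(-y[keep], lab[keep], method = "radix")
  aggregate_signal(
    y = c(1, y[keep][ord]),
    eps = c(0, eps[keep][ord]),
    labels = c("dummy", lab[keep][ord]),
    provenance = list(absent = lab[absent],
                      ubiquitous = lab[ubiq],
                      original = lab)
  )
}

#' Median / scaled-MAD summary of a frequency cluster
#'
#' Location is the median; scale is `1.4826 * median(|v - median|)`, the
#' usual consistency-scaled median absolute deviation that estimates a
#' normal standard deviation. The median of an even-sized set is the
#' midpoint of the two central values.
#'
#' @param values non-empty numeric vector of member frequencies
#' @return named numeric vector `c(y = ..., eps = ...)`
#' @examples
#' cluster_stats_median_mad(c(0.45, 0.47, 0.50))
#' @export
cluster_stats_median_mad <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop_input_error("empty cluster")
  m <- stats::median(values)
  c(y = m, eps = 1.4826 * stats::median(abs(values - m)))
}

#' Merge aberrations with indistinguishable frequencies
#'
#' Single-linkage transitive closure of pairwise indistinguishability under
#' the active error model (bound: `|y_i - y_j| <= eps_i + eps_j`; normal:
#' the two-sided test of `y_i - y_j` at level `alpha` fails to exclude 0;
#' exact: equality within machine tolerance). Each multi-member cluster is
#' replaced by one representative entry whose statistics come from
#' [cluster_stats_median_mad()]. The dummy is never clustered.
#'
#' @param signal an [aggregate_signal()]
#' @param model an [error_model()]
#' @return list with elements `signal` (the possibly reduced signal) and
#'   `clusters` (list of `list(members, y, eps)`, multi-member merges only)
#' @export
cluster_frequencies <- function(signal, model = error_model("bound")) {
  n <- length(signal$y)
  if (n <= 2L) return(list(signal = signal, clusters = list()))
  idx <- 2:n
  comp <- seq_along(idx)            # union-find over non-dummy entries
  find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
  for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
    ia <- idx[a]; ib <- idx[b]
    if (em_indistinguishable(model, signal$y[ia], signal$eps[ia],
                             signal$y[ib], signal$eps[ib]))
      comp[find(a)] <- find(b)
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  groups <- split(idx, roots)
  clusters <- list()
  recs <- lapply(groups, function(g) {
    if (length(g) == 1L)
      return(data.frame(label = signal$labels[g], y = signal$y[g],
                        eps = signal$eps[g]))
    st <- cluster_stats_median_mad(signal$y[g])
    lab <- paste(sort(signal$labels[g]), collapse = "+")
    clusters[[length(clusters) + 1L]] <<-
      list(members = signal$labels[g], y = unname(st["y"]),
           eps = unname(st["eps"]))
    data.frame(label = lab, y = unname(st["y"]), eps = unname(st["eps"]))
  })
  recs <- do.call(rbind, recs)
  out <- build_signal(recs, model = error_model("exact"))
  out$provenance <- c(signal$provenance, list(clusters = clusters))
  list(signal = out, clusters = clusters)
}

#' Frequency and error of a variant from read counts
#'
#' Point estimate `y = m/n` with the normal approximation of the binomial
#' proportion, `eps = sqrt(y (1 - y) / n)`.
#'
#' @param m mutated read count
#' @param n total read count (>= 1)
#' @return named numeric vector `c(y = ..., eps = ...)`
#' @examples
#' binomial_stats(50, 200)
#' @export
binomial_stats <- function(m, n) {
  if (any(n < 1)) stop_input_error("total read count must be >= 1")
  if (any(m < 0) || any(m > n)) stop_input_error("need 0 <= m <= n")
  y <- m / n
  c(y = y, eps = sqrt(y * (1 - y) / n))
}

#' Filter variant records by coverage, region and sample presence
#'
#' @param records data.frame with columns `label`, `n` (coverage), optionally
#'   `m` (mutated reads), `chrom`, `pos`, `sample`.
#' @param min_coverage keep records with `n > min_coverage` (strict).
#' @param region optional `"chr"` or `"chr:start-end"` string.
#' @param presence_in optional character vector of sample names: keep only
#'   labels observed mutated (`m > 0`) in every named sample.
#' @return the filtered data.frame, input order preserved.
#' @export
filter_variants <- function(records, min_coverage = 0, region = NULL,
                            presence_in = NULL) {
  records <- as.data.frame(records)
  keep <- records$n > min_coverage
  if (!is.null(region)) {
    if (is.null(records$chrom)) stop_input_error("records lack 'chrom' for region filter")
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0L || m[1] == "") stop_input_error(paste("malformed region:", region))
    keep <- keep & records$chrom == m[2]
    if (m[3] != "") {
      if (is.null(records$pos)) stop_input_error("records lack 'pos' for region filter")
      keep <- keep & records$pos >= as.numeric(m[4]) & records$pos <= as.numeric(m[5])
    }
  }
  if (!is.null(presence_in)) {
    if (is.null(records$sample) || is.null(records$m))
      stop_input_error("presence filter needs 'sample' and 'm' columns")
    for (s in presence_in) {
      present <- unique(records$label[records$sample == s & records$m > 0])
      keep <- keep & records$label %in% present
    }
  }
  records[keep, , drop = FALSE]
}
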