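# Shared fixtures and small utilities for the suite.
#
# The "WEX" fixture is a hand-constructed whole-exome-style aggregate with a
# unique optimum (four populated subclones): parents [-,1,2,1,3,3],
# x = (0, 0.32, 0, 0.28, 0.25, 0.15).

wex_signal <- function(eps = 0) {
  aggregate_signal(c(1, 0.72, 0.40, 0.28, 0.25, 0.15),
                   eps = rep(eps, 6),
                   labels = c("dummy", "a2", "a3", "a4", "a5", "a6"))
}

wex_parent <- c(NA, 1L, 2L, 1L, 3L, 3L)
wex_x <- c(0, 0.32, 0, 0.28, 0.25, 0.15)

tree_key <- function(parent) {
  paste(ifelse(is.na(parent), 0L, as.integer(parent)), collapse = ",")
}

sol_keys <- function(sols) {
  sort(vapply(sols, function(s) tree_key(s$tree$parent), character(1)))
}

fg_keys <- function(fg) {
  sort(vapply(fg, function(f)
    paste0(f$parent, ";", paste(f$children, collapse = ",")), character(1)))
}

# Independent oracle for FG detection: scan every (parent, subset) pair.
fg_scan <- function(signal, model) {
  n <- length(signal$y)
  out <- character(0)
  for (i0 in seq_len(n - 1L)) {
    cand <- (i0 + 1L):n
    for (k in seq_along(cand)) {
      picks <- if (length(cand) == 1L) list(cand)
               else utils::combn(cand, k, simplify = FALSE)
      for (pick in picks) {
        allow <- em_allowance(model, signal$eps[i0], signal$eps[pick])
        if (abs(signal$y[i0] - sum(signal$y[pick])) <= allow)
          out <- c(out, paste0(i0, ";", paste(pick, collapse = ",")))
      }
    }
  }
  sort(out)
}

# A sorted random signal with no planted structure (generic frequencies).
random_generic_signal <- function(n) {
  y <- sort(stats::runif(n - 1L), decreasing = TRUE)
  aggregate_signal(c(1, y), labels = c("dummy", sprintf("r%02d", seq_len(n - 1L))))
}
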