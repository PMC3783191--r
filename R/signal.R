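#' @keywords internal
.decon_tol <- 1e-9

#' Conditions with machine-readable classes
#'
#' Input errors map to CLI exit code 2, cap errors to exit code 3.
#' @noRd
stop_input_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("decon_input_error", "decon_error")))
}

#' @noRd
stop_cap_error <- function(msg) {
  stop(errorCondition(msg, class = c("decon_cap_error", "decon_error")))
}

#' Aggregate aberration-frequency signal
#'
#' The central input container: one aggregate frequency per aberration event,
#' sorted non-increasing, with an artificial "dummy" aberration of frequency 1
#' in the first slot. The dummy is present in every cell (tumor and normal)
#' and lets the linear mixture model carry the wildtype fraction. Entry `i`
#' names both an aberration and "the subclone in which aberration `i` first
#' occurred", so the vector length `N` is also the clone count.
#'
#' Most users should build signals with [build_signal()], which performs
#' homogeneous-entry removal, dummy insertion and sorting. This low-level
#' constructor validates an already well-formed vector.
#'
#' @param y numeric vector of aggregate frequencies in `[0,1]`, non-increasing,
#'   with `y[1] == 1` (the dummy).
#' @param eps nonnegative per-entry measurement errors, same length as `y`.
#'   The dummy's error is 0 by construction when the signal comes from
#'   [build_signal()], but an explicit nonzero value is honored by the
#'   interval-bound arithmetic.
#' @param labels unique aberration identifiers; first entry labels the dummy.
#' @param provenance free-form list recording what preprocessing did
#'   (entries dropped as absent, recorded as ubiquitous, cluster members).
#' @return an object of class `aggregate_signal` with fields
#'   `labels`, `y`, `eps`, `provenance`.
#' @examples
#' s <- aggregate_signal(y = c(1, 0.6, 0.4), labels = c("dummy", "a", "b"))
#' n_aberrations(s)
#' @export
aggregate_signal <- function(y, eps = NULL, labels = NULL, provenance = list()) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop_input_error("signal must contain at least the dummy entry")
  if (is.null(eps)) eps <- numeric(n)
  eps <- as.numeric(eps)
  if (is.null(labels)) labels <- c("dummy", paste0("a", seq_len(n))[-1])
  labels <- as.character(labels)
  if (length(eps) != n || length(labels) != n)
    stop_input_error("y, eps and labels must have equal length")
  if (anyDuplicated(labels)) stop_input_error("aberration labels must be unique")
  if (abs(y[1] - 1) > .decon_tol)
    stop_input_error("the first (dummy) entry must have frequency 1")
  y[1] <- 1
  if (any(y < -.decon_tol) || any(y > 1 + .decon_tol))
    stop_input_error("frequencies must lie in [0, 1]")
  y <- pmin(pmax(y, 0), 1)
  if (any(eps < 0)) stop_input_error("measurement errors must be nonnegative")
  if (is.unsorted(rev(y), strictly = FALSE))
    stop_input_error("frequencies must be sorted non-increasing (see build_signal)")
  structure(
    list(labels = labels, y = y, eps = eps, provenance = provenance),
    class = "aggregate_signal"
  )
}

#' Number of entries (clones) in a signal, dummy included
#' @param signal an [aggregate_signal()]
#' @return integer `N`
#' @export
n_aberrations <- function(signal) length(signal$y)

#' @export
print.aggregate_signal <- function(x, ...) {
  cat("Aggregate signal:", length(x$y), "entries (incl. dummy)\n")
  df <- data.frame(label = x$labels, y = x$y, eps = x$eps)
  print(df, row.names = FALSE)
  if (length(x$provenance$ubiquitous))
    cat("ubiquitous (removed):", paste(x$provenance$ubiquitous, collapse = ", "), "\n")
  if (length(x$provenance$absent))
    cat("absent (removed):", paste(x$provenance$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Measurement-error models
#'
#' Governs every "is this distinguishable from zero" decision: detection of
#' first-generation trees, feasibility slack during tree enumeration, and
#' homogeneity thresholds during preprocessing.
#'
#' * `exact` — frequencies are noise-free; comparisons at machine tolerance.
#' * `bound` — each measurement lies within `y_i +/- eps_i`; interval
#'   arithmetic, so a sum criterion gets the additive allowance
#'   `eps_i + sum(eps_j)`.
#' * `normal` — errors are independent Gaussians with sd `eps_i`; a residual
#'   is indistinguishable from zero when 0 lies inside its two-sided
#'   `1 - alpha` confidence interval.
#'
#' @param kind one of `"exact"`, `"bound"`, `"normal"`.
#' @param alpha confidence level parameter for the normal model (default 0.05).
#' @return an object of class `error_model`.
#' @examples
#' error_model("bound")
#' error_model("normal", alpha = 0.01)
#' @export
error_model <- function(kind = c("exact", "bound", "normal"), alpha = 0.05) {
  kind <- match.arg(kind)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_input_error("alpha must be a single number in (0, 1)")
  structure(
    list(kind = kind, alpha = alpha,
         z = if (kind == "normal") stats::qnorm(1 - alpha / 2) else NA_real_),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat("Error model:", x$kind,
      if (x$kind == "normal") sprintf("(alpha = %g)", x$alpha) else "", "\n")
  invisible(x)
}

#' Allowance for a sum residual under an error model
#'
#' Returns the largest |residual| still indistinguishable from zero for a
#' quantity of the form `y_parent - sum(y_children)`.
#'
#' @param model error_model
#' @param eps_parent scalar error of the parent entry
#' @param eps_children vector of child errors (possibly empty)
#' @return scalar allowance (>= 0)
#' @keywords internal
em_allowance <- function(model, eps_parent, eps_children) {
  switch(model$kind,
    exact  = .decon_tol,
    bound  = eps_parent + sum(eps_children) + .decon_tol,
    normal = model$z * sqrt(eps_parent^2 + sum(eps_children^2)) + .decon_tol
  )
}

#' Are two measured frequencies indistinguishable under the model?
#' @keywords internal
em_indistinguishable <- function(model, y1, e1, y2, e2) {
  abs(y1 - y2) <= em_allowance(model, e1, e2)
}
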