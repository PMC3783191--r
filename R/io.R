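#' Read a per-aberration frequency table
#'
#' Tab-separated, header required, columns `id` and `freq`, optional `err`
#' and `sample`. Errors name the offending line (1-based, header = line 1).
#'
#' @param path file path
#' @return data.frame with columns `label`, `y`, `eps` and, when present,
#'   `sample`
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop_input_error(paste("no such file:", path))
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop_input_error(paste("cannot parse", path, ":",
                                               conditionMessage(e))))
  need <- setdiff(c("id", "freq"), names(df))
  if (length(need))
    stop_input_error(paste("missing column(s):", paste(need, collapse = ", ")))
  freq <- suppressWarnings(as.numeric(df$freq))
  bad <- which(is.na(freq) | freq < 0 | freq > 1)
  if (length(bad))
    stop_input_error(sprintf(
      "invalid frequency %s on line %d (must be a number in [0,1])",
      df$freq[bad[1]], bad[1] + 1L))
  eps <- if (is.null(df$err)) rep(0, nrow(df)) else {
    e <- suppressWarnings(as.numeric(df$err))
    badE <- which(is.na(e) | e < 0)
    if (length(badE))
      stop_input_error(sprintf("invalid error on line %d", badE[1] + 1L))
    e
  }
  out <- data.frame(label = as.character(df$id), y = freq, eps = eps,
                    stringsAsFactors = FALSE)
  if (!is.null(df$sample)) out$sample <- as.character(df$sample)
  out
}

#' Read a constraint table
#'
#' Tab-separated with columns `type` (`ancestor` or `exclusive`), `a`, `b`
#' holding aberration labels.
#' @param path file path
#' @return a [constraint_set()] with label pairs
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop_input_error(paste("no such file:", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("type", "a", "b") %in% names(df)))
    stop_input_error("constraint file needs columns type, a, b")
  bad <- !df$type %in% c("ancestor", "exclusive")
  if (any(bad))
    stop_input_error(paste("unknown constraint type:", df$type[bad][1]))
  constraint_set(
    ancestor = if (any(df$type == "ancestor"))
      as.matrix(df[df$type == "ancestor", c("a", "b")]),
    exclusive = if (any(df$type == "exclusive"))
      as.matrix(df[df$type == "exclusive", c("a", "b")]))
}

#' Read a genotype matrix (aberrations x subclones) from TSV
#'
#' First column = aberration label, remaining columns = 0/1 genotype of each
#' subclone; an optional final row labelled `weight` carries mixing weights.
#' @param path file path
#' @return list(`genotypes` = binary matrix with dimnames, `weights` =
#'   numeric vector or NULL)
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop_input_error(paste("no such file:", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  labs <- as.character(df[[1]])
  wrow <- which(labs == "weight")
  weights <- NULL
  if (length(wrow)) {
    weights <- as.numeric(df[wrow[1], -1])
    df <- df[-wrow, , drop = FALSE]
    labs <- labs[-wrow]
  }
  G <- as.matrix(df[, -1, drop = FALSE])
  mode(G) <- "numeric"
  if (!all(G %in% c(0, 1))) stop_input_error("genotype entries must be 0/1")
  rownames(G) <- labs
  list(genotypes = G, weights = weights)
}

#' Extract per-variant read counts from a VCF
#'
#' Uses Bioconductor's VariantAnnotation (a suggested dependency) to pull
#' per-sample depth (`DP`) and allelic depths (`AD`, or `AO`/`RO`). Biallelic
#' SNVs become read-count records labelled `chrom:pos:ref>alt`; multiallelic
#' records become [multiallelic_site()] inputs with [binomial_stats()]
#' frequencies.
#'
#' @param path VCF path (plain or bgzipped)
#' @param sample sample name (defaults to the first sample)
#' @return list with `counts` (data.frame `label`, `chrom`, `pos`, `n`, `m`)
#'   and `sites` (list of [multiallelic_site()]); records lacking depth
#'   fields are skipped with a warning tally
#' @export
read_vcf_counts <- function(path, sample = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_input_error("reading VCFs requires the VariantAnnotation package")
  if (!file.exists(path)) stop_input_error(paste("no such file:", path))
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (is.null(sample)) sample <- samples[1]
  if (!sample %in% samples)
    stop_input_error(paste0("sample '", sample, "' not in VCF; available: ",
                            paste(samples, collapse = ", ")))
  gen <- VariantAnnotation::geno(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  counts <- list(); sites <- list(); skipped <- 0L
  for (i in seq_along(rr)) {
    alts <- as.character(altL[[i]])
    ad <- if ("AD" %in% names(gen)) gen$AD[i, sample][[1]] else NULL
    dp <- if ("DP" %in% names(gen)) gen$DP[i, sample] else NULL
    if (is.null(ad) && all(c("AO", "RO") %in% names(gen)))
      ad <- c(gen$RO[i, sample], unlist(gen$AO[i, sample]))
    if (is.null(ad) || anyNA(ad)) { skipped <- skipped + 1L; next }
    n <- if (!is.null(dp) && !is.na(dp)) dp else sum(ad)
    if (length(alts) == 1L) {
      counts[[length(counts) + 1L]] <- data.frame(
        label = paste0(chrom[i], ":", pos[i], ":", ref[i], ">", alts),
        chrom = chrom[i], pos = pos[i], n = as.integer(n),
        m = as.integer(ad[2]))
    } else {
      st <- lapply(seq_along(alts), function(k) binomial_stats(ad[k + 1L], n))
      sites[[length(sites) + 1L]] <- multiallelic_site(
        position = paste0(chrom[i], ":", pos[i]), ref = ref[i],
        alleles = data.frame(allele = alts,
                             freq = vapply(st, `[[`, numeric(1), "y"),
                             eps = vapply(st, `[[`, numeric(1), "eps")))
    }
  }
  if (skipped) warning(skipped, " record(s) skipped for missing depth fields")
  list(counts = do.call(rbind, counts) %||% data.frame(), sites = sites)
}

#' Newick string for a clone tree
#'
#' Dialect (documented here and in the README, since no standard exists for
#' clone trees): every node is named by its aberration label, children are
#' ordered by clone index, and the clone frequency rides in a bracketed
#' comment, e.g. `((C3[x=0.4])C2[x=0.2])C1[x=0.4];`.
#' @param tree a [clone_tree()]
#' @param labels node names (defaults to `C1..CN`)
#' @param x optional frequencies for the comments
#' @return a single Newick string
#' @export
newick_string <- function(tree, labels = NULL, x = NULL) {
  n <- length(tree$parent)
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  labels <- gsub("[();,:\\[\\] ]", "_", labels)
  fmt <- function(j) {
    kids <- tree$children[[j]]
    com <- if (is.null(x)) "" else sprintf("[x=%.6g]", x[j])
    if (length(kids) == 0L) paste0(labels[j], com)
    else paste0("(", paste(vapply(kids, fmt, character(1)), collapse = ","),
                ")", labels[j], com)
  }
  paste0(fmt(1L), ";")
}

#' DOT (graphviz) rendering of a solution
#'
#' One digraph per solution; each node lists the aberration newly acquired
#' by that clone and its fitted frequency; unpopulated clones are drawn
#' hollow (dashed).
#' @param solution a `clone_solution`
#' @param name graph name
#' @return character vector of DOT lines
#' @export
solution_dot <- function(solution, name = "clonetree") {
  n <- length(solution$x)
  lab <- solution$labels
  lines <- c(sprintf("digraph %s {", name), "  node [shape=box];")
  for (j in seq_len(n)) {
    style <- if (solution$x[j] > .decon_tol) "solid" else "dashed"
    lines <- c(lines, sprintf(
      "  n%d [label=\"%s\\nx=%.4f\", style=%s];", j,
      if (j == 1L) "wildtype" else lab[j], solution$x[j], style))
  }
  for (j in seq_len(n)[-1])
    lines <- c(lines, sprintf("  n%d -> n%d;", solution$tree$parent[j], j))
  c(lines, "}")
}

#' Write solutions as JSON / DOT / Newick files
#'
#' `PREFIX.json` holds the full machine-readable result (signal, parent
#' arrays, x, P, D, residual, provenance); `PREFIX.dot` one graph per
#' solution; `PREFIX.nwk` one Newick line per solution. Deterministic
#' ordering throughout.
#'
#' @param result a `decon_result`
#' @param prefix output path prefix
#' @param formats subset of `c("json", "dot", "newick")`
#' @return (invisibly) the paths written
#' @export
write_solutions <- function(result, prefix,
                            formats = c("json", "dot", "newick")) {
  formats <- match.arg(formats, several.ok = TRUE)
  sols <- result$solutions
  paths <- character(0)
  if ("json" %in% formats) {
    p <- paste0(prefix, ".json")
    obj <- list(
      signal = list(labels = result$signal$labels, y = result$signal$y,
                    eps = result$signal$eps,
                    provenance = result$signal$provenance),
      model = list(kind = result$model$kind, alpha = result$model$alpha),
      h_star = result$h_star, p_min = result$p_min,
      fg_count = result$fg_count, truncated = result$truncated,
      solutions = lapply(sols, function(s) list(
        parent = ifelse(is.na(s$tree$parent), NA, s$tree$parent),
        x = s$x, populated = s$populated, depth = s$depth,
        fit_residual = s$fit_residual, method = s$method,
        unpopulated = s$unpopulated)))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("dot" %in% formats) {
    p <- paste0(prefix, ".dot")
    writeLines(unlist(lapply(seq_along(sols), function(i)
      solution_dot(sols[[i]], sprintf("solution%d", i)))), p)
    paths <- c(paths, p)
  }
  if ("newick" %in% formats) {
    p <- paste0(prefix, ".nwk")
    writeLines(vapply(sols, function(s)
      newick_string(s$tree, s$labels, s$x), character(1)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Reload a JSON solutions file
#'
#' Inverse of the JSON branch of [write_solutions()]: reconstructs the
#' signal and each solution losslessly.
#' @param path JSON path
#' @return a `decon_result`
#' @export
read_solutions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sig <- aggregate_signal(obj$signal$y, obj$signal$eps, obj$signal$labels,
                          provenance = obj$signal$provenance %||% list())
  model <- error_model(obj$model$kind, obj$model$alpha)
  sols <- lapply(obj$solutions, function(s) {
    par <- s$parent
    par[1] <- NA
    sol <- clone_solution(clone_tree(as.integer(par)), as.numeric(s$x), sig,
                          populated = s$populated, method = s$method,
                          unpopulated = as.integer(s$unpopulated %||% integer(0)))
    sol$fit_residual <- s$fit_residual
    sol
  })
  structure(list(solutions = sols, candidates = sols,
                 h_star = obj$h_star, p_min = obj$p_min,
                 fg_count = obj$fg_count, truncated = isTRUE(obj$truncated),
                 signal = sig, model = model),
            class = "decon_result")
}
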