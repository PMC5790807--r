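#' Filter gene sets by measured-gene support
#'
#' Keeps only processes annotated with at least `min_genes` measured
#' genes in every species x tissue stratum of the supplied studies. A
#' gene counts as measured in a stratum when its expression is positive
#' in all samples of that stratum (for studies already passed through
#' [filter_unexpressed_genes()] this is simply membership in the study).
#'
#' @param sets a [gene_set_collection()].
#' @param studies a single [expression_study()] or a list of them
#'   (e.g. one per species).
#' @param min_genes minimum measured genes per stratum (default 5).
#' @return The filtered collection.
#' @export
filter_gene_sets_min_genes <- function(sets, studies, min_genes = 5) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (inherits(studies, "expression_study")) studies <- list(studies)
  measured <- list()  # one gene vector per species x tissue stratum
  for (st in studies) {
    strat <- interaction(st$meta$species, st$meta$tissue, drop = TRUE)
    for (s in levels(strat)) {
      idx <- which(strat == s)
      ok <- rowSums(st$values[, idx, drop = FALSE] > 0) == length(idx)
      measured[[paste0(s)]] <- rownames(st$values)[ok]
    }
  }
  keep <- vapply(sets$sets, function(genes) {
    all(vapply(measured, function(m) sum(genes %in% m) >= min_genes,
               logical(1)))
  }, logical(1))
  if (!any(keep))
    stop("no gene set has >= ", min_genes,
         " measured genes in every stratum")
  gene_set_collection(sets$sets[keep], name = sets$name,
                      labels = sets$labels[keep])
}

#' Compute raw process activities
#'
#' The activity of a process in a sample is the sum of the expression
#' values of its measured genes in that sample (equivalent to the mean up
#' to the subsequent normalization, which is rank-based per process).
#'
#' @param study an [expression_study()] (gene-filtered, RPKM scale).
#' @param sets a filtered [gene_set_collection()].
#' @return A `process_activity` object: process x sample matrix plus the
#'   sample metadata, ontology name and normalization state `"raw"`.
#' @export
compute_process_activity <- function(study, sets) {
  stopifnot(inherits(study, "expression_study"),
            inherits(sets, "gene_set_collection"))
  genes <- rownames(study$values)
  act <- t(vapply(sets$sets, function(g) {
    g <- intersect(g, genes)
    if (!length(g))
      stop("process with no measured genes; run ",
           "filter_gene_sets_min_genes() first")
    colSums(study$values[g, , drop = FALSE])
  }, numeric(ncol(study$values))))
  dimnames(act) <- list(names(sets$sets), colnames(study$values))
  structure(list(activity = act, meta = study$meta,
                 ontology = sets$name, state = "raw"),
            class = "process_activity")
}

#' @export
print.process_activity <- function(x, ...) {
  cat(sprintf("process_activity [%s]: %d processes x %d samples (%s)\n",
              x$ontology, nrow(x$activity), ncol(x$activity), x$state))
  invisible(x)
}

# Quantile-normalize columns of a matrix: each column's sorted values are
# replaced by the across-column means of sorted values; ties within a
# column keep input order (deterministic).
quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort, method = "radix"))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# Average ranks scaled to min 0 / max 1. Without ties this equals
# (rank - 1) / (n - 1); with ties the extremes are still attained, so
# every stratum spans exactly [0, 1]. All-tied input maps to 0.5.
scale_ranks <- function(x) {
  if (length(x) < 2) stop("rank scaling needs >= 2 values")
  r <- rank(x, ties.method = "average")
  if (max(r) == min(r)) return(rep(0.5, length(x)))
  (r - min(r)) / (max(r) - min(r))
}

#' Normalize process activities
#'
#' Two-step cascade: (1) quantile normalization of the process x sample
#' matrix across all samples jointly, making every sample's value
#' distribution identical; (2) within each species x tissue stratum,
#' each process's activities are rank-normalized and the ranks scaled to
#' min 0 / max 1 (average ranks for ties). The quantile-normalized matrix
#' is retained (`$activity_qn`) as the response for downstream ANOVA;
#' the rank-scaled matrix (`$activity`) feeds foldchanges.
#'
#' @param pa a `process_activity` in state `"raw"`.
#' @return The object with state `"rank_scaled"`, the rank-scaled matrix
#'   in `$activity`, the intermediate in `$activity_qn` and the stratum
#'   factor in `$stratum`.
#' @export
normalize_activities <- function(pa) {
  stopifnot(inherits(pa, "process_activity"))
  if (pa$state != "raw")
    stop("normalize_activities() expects state 'raw', got '", pa$state, "'")
  qn <- quantile_normalize(pa$activity)
  stratum <- interaction(pa$meta$species, pa$meta$tissue, drop = TRUE)
  if (any(table(stratum) < 2))
    stop("rank scaling undefined for stratum with a single sample")
  rs <- qn
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    rs[, idx] <- t(apply(qn[, idx, drop = FALSE], 1, scale_ranks))
  }
  pa$activity_qn <- qn
  pa$activity <- rs
  pa$stratum <- stratum
  pa$state <- "rank_scaled"
  pa
}

#' Write a normalized activity matrix as TSV
#'
#' @param pa a normalized `process_activity`.
#' @param path output path; a provenance header line is prepended.
#' @export
write_process_activity <- function(pa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# process activity | ontology=%s | state=%s",
                     pa$ontology, pa$state), con)
  write.table(data.frame(process = rownames(pa$activity), pa$activity,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pa)
}
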