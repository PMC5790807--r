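#' Rank-normalize disease foldchanges to \[-1, +1\]
#'
#' Genes are rank-transformed over the data set (average ranks for ties)
#' and mapped linearly onto \[-1, +1\]:
#' `norm = 2 * (rank - 1) / (N - 1) - 1`. The transform is invariant
#' under any strictly monotone transform of the raw foldchanges, bounded
#' by construction, and gives the alignment score below its full
#' theoretical range.
#'
#' @param sig a [disease_signature()].
#' @return The signature with `$normalized` filled in. All-identical
#'   foldchanges yield all zeros with a warning.
#' @export
normalize_disease_foldchanges <- function(sig) {
  stopifnot(inherits(sig, "disease_signature"))
  fc <- sig$foldchange
  if (length(fc) < 2) stop("need >= 2 genes")
  if (length(unique(fc)) == 1) {
    warning("all foldchanges identical; normalized values set to 0")
    sig$normalized <- setNames(rep(0, length(fc)), names(fc))
    return(sig)
  }
  r <- rank(fc, ties.method = "average")
  sig$normalized <- setNames(2 * (r - 1) / (length(fc) - 1) - 1, names(fc))
  sig
}

# shared precondition handling for AMDA-type computations: restrict U/R
# to genes measured in the disease set, minus exclusions and U/R overlap
amda_gene_sets <- function(U, R, sig, exclude = NULL) {
  if (is.null(sig$normalized))
    stop("disease signature must be normalized first")
  both <- intersect(U, R)
  if (length(both)) {
    message("dropping ", length(both),
            " gene(s) present in both induced and repressed sets")
    U <- setdiff(U, both)
    R <- setdiff(R, both)
  }
  drop <- unique(unlist(exclude))
  U <- setdiff(intersect(U, names(sig$normalized)), drop)
  R <- setdiff(intersect(R, names(sig$normalized)), drop)
  list(U = U, R = R)
}

#' Ageing-mediated disease alignment (AMDA) score
#'
#' Difference between the mean normalized disease foldchange over
#' ageing-induced genes and over ageing-repressed genes, restricted to
#' genes measured in the disease data set. Positive scores mean ageing
#' shifts the transcriptome toward the disease signature, negative ones
#' away from it. With normalized foldchanges in \[-1, +1\] the score is
#' bounded by \[-2, +2\].
#'
#' @param U,R character vectors of ageing-induced / ageing-repressed
#'   genes.
#' @param sig a normalized [disease_signature()].
#' @param exclude optional list (or vector) of gene ids to exclude, e.g.
#'   a senescence gene set for sensitivity analysis.
#' @return The AMDA score, or `NA` (with a warning) when either side has
#'   no measured genes.
#' @export
amda_score <- function(U, R, sig, exclude = NULL) {
  gs <- amda_gene_sets(U, R, sig, exclude)
  if (!length(gs$U) || !length(gs$R)) {
    warning("AMDA undefined: no measured genes on one side")
    return(NA_real_)
  }
  mean(sig$normalized[gs$U]) - mean(sig$normalized[gs$R])
}

#' AMDA scores with Wilcoxon significance over many pairs
#'
#' For every (ageing data set, disease data set) pair, computes the AMDA
#' score and a two-sided Wilcoxon rank-sum test comparing the normalized
#' disease foldchanges of the induced vs the repressed genes; BH-FDR is
#' applied across all pairs tested together.
#'
#' @param ageing named list of ageing gene sets, each a list with
#'   elements `U` and `R`.
#' @param diseases named list of normalized [disease_signature()]s.
#' @param exclude optional gene exclusion list applied to every pair.
#' @param fdr_alpha significance threshold on the adjusted p (0.05).
#' @return data.frame with one row per pair: `ageing`, `disease`,
#'   `category`, `score`, `n_U`, `n_R`, `p`, `fdr`, `significant`.
#'   Pairs with fewer than 2 genes on either side get `NA` statistics.
#' @export
amda_significance <- function(ageing, diseases, exclude = NULL,
                              fdr_alpha = 0.05) {
  rows <- list()
  for (a in names(ageing)) {
    for (d in names(diseases)) {
      sig <- diseases[[d]]
      gs <- amda_gene_sets(ageing[[a]]$U, ageing[[a]]$R, sig, exclude)
      nu <- length(gs$U); nr <- length(gs$R)
      if (nu < 2 || nr < 2) {
        rows[[paste(a, d)]] <- data.frame(
          ageing = a, disease = d, category = sig$category,
          score = NA_real_, n_U = nu, n_R = nr, p = NA_real_)
        next
      }
      score <- mean(sig$normalized[gs$U]) - mean(sig$normalized[gs$R])
      p <- suppressWarnings(
        wilcox.test(sig$normalized[gs$U], sig$normalized[gs$R])$p.value)
      rows[[paste(a, d)]] <- data.frame(
        ageing = a, disease = d, category = sig$category,
        score = score, n_U = nu, n_R = nr, p = p)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$fdr <- NA_real_
  tested <- !is.na(out$p)
  out$fdr[tested] <- p.adjust(out$p[tested], method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_alpha
  out
}

#' Induced/repressed swap randomization of the AMDA analysis
#'
#' Each replicate randomly reassigns the induced/repressed labels over
#' the union U + R of every ageing data set (preserving the two set
#' sizes) and recomputes the full AMDA significance analysis, recording
#' how many pairs come out significant.
#'
#' @inheritParams amda_significance
#' @param n_reps number of label swaps (default 100).
#' @param seed RNG seed.
#' @return list with `counts` (significant pairs per replicate) and the
#'   `observed` count on the unpermuted labels.
#' @export
amda_randomization <- function(ageing, diseases, n_reps = 100, seed = 1,
                               exclude = NULL, fdr_alpha = 0.05) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  obs <- sum(amda_significance(ageing, diseases, exclude,
                               fdr_alpha)$significant)
  set.seed(seed)
  counts <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    perm <- lapply(ageing, function(s) {
      pool <- sample(c(s$U, s$R))
      list(U = pool[seq_along(s$U)], R = pool[-seq_along(s$U)])
    })
    counts[r] <- sum(amda_significance(perm, diseases, exclude,
                                       fdr_alpha)$significant)
  }
  list(counts = counts, observed = obs)
}

#' Disease alignment contribution (DAC) scores
#'
#' The crude DAC of a process for a disease category is the summed shift
#' in AMDA score across all (ageing, disease) pairs of that category when
#' the process's genes are removed:
#' `crude(p, C) = sum over pairs [AMDA - AMDA without genes of p]`.
#' Normalization divides by the number of pairs and scales to an
#' absolute maximum of 1 (per category by default, or globally), giving
#' a theoretical range of -1 to +1: positive scores mark processes whose
#' genes shift the ageing signature toward the disease category, negative
#' ones processes that pull it away.
#'
#' @param processes a [gene_set_collection()].
#' @param ageing named list of ageing gene sets (elements `U`, `R`).
#' @param diseases named list of normalized [disease_signature()]s;
#'   categories are taken from the signatures.
#' @param scale `"category"` (default) scales within each disease
#'   category, `"global"` over the whole table.
#' @return list with matrices `crude` and `normalized` (process x
#'   category) and `n_pairs` per category.
#' @export
dac_scores <- function(processes, ageing, diseases,
                       scale = c("category", "global")) {
  scale <- match.arg(scale)
  stopifnot(inherits(processes, "gene_set_collection"))
  cats <- vapply(diseases, `[[`, character(1), "category")
  ucats <- unique(cats)
  procs <- names(processes$sets)
  crude <- matrix(0, length(procs), length(ucats),
                  dimnames = list(procs, ucats))
  n_pairs <- setNames(integer(length(ucats)), ucats)
  for (a in names(ageing)) {
    U <- ageing[[a]]$U; R <- ageing[[a]]$R
    for (d in names(diseases)) {
      sig <- diseases[[d]]
      base <- amda_score(U, R, sig)
      if (is.na(base)) next
      n_pairs[sig$category] <- n_pairs[sig$category] + 1L
      for (p in procs) {
        g <- processes$sets[[p]]
        if (!length(intersect(g, c(U, R)))) next  # no-op removal
        reduced <- suppressWarnings(amda_score(U, R, sig, exclude = g))
        if (is.na(reduced)) {
          message("process ", p, " empties one gene side for pair (",
                  a, ", ", d, "); pair skipped for this process")
          next
        }
        crude[p, sig$category] <- crude[p, sig$category] + (base - reduced)
      }
    }
  }
  norm <- sweep(crude, 2, pmax(n_pairs, 1L), "/")
  if (scale == "category") {
    mx <- apply(abs(norm), 2, max)
    norm <- sweep(norm, 2, ifelse(mx > 0, mx, 1), "/")
  } else {
    mx <- max(abs(norm))
    if (mx > 0) norm <- norm / mx
  }
  list(crude = crude, normalized = norm, n_pairs = n_pairs)
}

#' Classical MDS embedding of condition foldchange profiles
#'
#' Torgerson (classical) multi-dimensional scaling of the Euclidean
#' distances between conditions (rows), as used to co-embed disease and
#' ageing expression changes. Variance explained per axis is the
#' eigenvalue divided by the sum of positive eigenvalues.
#'
#' @param profiles condition x feature numeric matrix (process- or
#'   gene-level foldchanges). `NA` features are handled pairwise-complete
#'   by [stats::dist()].
#' @param k number of axes requested (default 2).
#' @return list with `points` (condition x axis coordinates) and
#'   `variance_explained` (fraction per returned axis). When fewer
#'   positive eigenvalues than `k` exist, the available axes are
#'   returned with a warning.
#' @export
mds_embedding <- function(profiles, k = 2) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stop("need >= 3 conditions")
  d <- dist(profiles)
  fit <- cmdscale(d, k = min(k, nrow(profiles) - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))]
  n_axes <- min(k, length(pos))
  if (n_axes < k)
    warning("only ", n_axes, " positive eigenvalue(s); returning ",
            n_axes, " axis/axes")
  pts <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(n_axes))
  list(points = pts,
       variance_explained = fit$eig[seq_len(n_axes)] / sum(pos))
}

#' Write AMDA or DAC results as TSV
#'
#' @param x the `amda_significance()` data.frame or the `dac_scores()`
#'   normalized matrix.
#' @param path output path.
#' @export
write_alignment_table <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(process = rownames(x), x, check.names = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
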