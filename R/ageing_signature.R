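#' Detect ageing-regulated processes
#'
#' Runs the full process-level detection cascade on a normalized activity
#' matrix: per-process assumption filtering (Shapiro-Wilk on full-model
#' residuals, Levene across design cells, both at `assumption_alpha`),
#' type-II ANOVA with marginality-respecting backward selection, BH-FDR
#' across the assumption-passing processes, rank-scale foldchanges
#' (mean of pooled old minus mean of young) overall and per species, and
#' the cross-clade conservation rule of [derive_signature()].
#'
#' The ANOVA response is the quantile-normalized activity; foldchanges
#' and directions are taken on the per-stratum rank scale. Processes
#' whose age term is removed by backward selection stay in the FDR family
#' with p = 1 and are flagged `age_removed`.
#'
#' @param pa a normalized `process_activity` (see
#'   [normalize_activities()]).
#' @param fish,mammals species labels counting as fish / mammals for the
#'   conservation rule.
#' @param age_levels age groups entering the ANOVA (default young and the
#'   two old groups; other samples are ignored).
#' @param assumption_alpha threshold of the assumption filter (0.005).
#' @param reduce_alpha backward-selection threshold (0.05).
#' @param fdr_alpha BH-FDR threshold for signature membership (0.05).
#' @return An `ageing_signature` object whose `$processes` data.frame has
#'   one row per process: p, fdr, foldchange, direction, per-species
#'   directions, filter flags and signature membership.
#' @export
ageing_signature <- function(pa,
                             fish = c("zebrafish", "nfurzeri"),
                             mammals = c("mouse", "human"),
                             age_levels = c("young", "old_1", "old_2"),
                             assumption_alpha = 0.005,
                             reduce_alpha = 0.05,
                             fdr_alpha = 0.05) {
  stopifnot(inherits(pa, "process_activity"))
  if (pa$state != "rank_scaled")
    stop("run normalize_activities() first")
  idx <- which(pa$meta$age_group %in% age_levels)
  meta <- pa$meta[idx, , drop = FALSE]
  design <- anova_design(meta, age_levels = age_levels)
  stats <- anova_process_stats(pa$activity_qn[, idx, drop = FALSE], design,
                               assumption_alpha, reduce_alpha)
  fc <- foldchanges_by_species(pa$activity[, idx, drop = FALSE], meta)
  stats <- cbind(stats, fc)
  sig <- derive_signature(stats, fdr_alpha = fdr_alpha, fish = fish,
                          mammals = mammals)
  structure(list(processes = sig, ontology = pa$ontology,
                 fish = fish, mammals = mammals,
                 fdr_alpha = fdr_alpha), class = "ageing_signature")
}

# assumption check + backward-selection ANOVA for every process (rows)
anova_process_stats <- function(act_qn, design, assumption_alpha,
                                reduce_alpha) {
  res <- lapply(rownames(act_qn), function(p) {
    y <- act_qn[p, ]
    chk <- check_model_assumptions(y, design, alpha = assumption_alpha)
    if (!chk$pass) {
      return(data.frame(process = p, assumption_pass = FALSE,
                        shapiro_p = chk$shapiro_p, levene_p = chk$levene_p,
                        age_removed = NA, p = NA_real_))
    }
    fit <- fit_age_anova(y, design, reduce_alpha = reduce_alpha)
    data.frame(process = p, assumption_pass = TRUE,
               shapiro_p = chk$shapiro_p, levene_p = chk$levene_p,
               age_removed = fit$age_removed,
               p = if (fit$age_removed) 1 else fit$p_age)
  })
  do.call(rbind, res)
}

# rank-scale foldchange (pooled old minus young), overall and per species
foldchanges_by_species <- function(act_rs, meta) {
  old <- meta$age_group %in% OLD_LEVELS
  young <- meta$age_group == "young"
  out <- data.frame(
    foldchange = rowMeans(act_rs[, old, drop = FALSE]) -
      rowMeans(act_rs[, young, drop = FALSE]))
  for (sp in unique(meta$species)) {
    s <- meta$species == sp
    out[[paste0("fc_", sp)]] <-
      rowMeans(act_rs[, old & s, drop = FALSE]) -
      rowMeans(act_rs[, young & s, drop = FALSE])
  }
  out
}

#' Apply FDR correction and the cross-clade conservation rule
#'
#' A process belongs to the ageing signature when (1) its BH-adjusted age
#' p-value is at most `fdr_alpha` in the joint (all species) analysis
#' and (2) its direction of regulation agrees with the overall direction
#' in at least one fish and at least one mammal.
#'
#' @param stats data.frame with columns `process`, `p` (NA = filtered
#'   out), `foldchange` and one `fc_<species>` column per species.
#' @param fdr_alpha BH threshold (default 0.05).
#' @param fish,mammals species labels of the two clades; their
#'   `fc_<species>` columns must exist.
#' @return The data.frame extended with `fdr`, `direction`, `conserved`
#'   and `significant` columns.
#' @export
derive_signature <- function(stats, fdr_alpha = 0.05,
                             fish = c("zebrafish", "nfurzeri"),
                             mammals = c("mouse", "human")) {
  need <- paste0("fc_", c(fish, mammals))
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("missing per-species stratification column(s): ",
         paste(miss, collapse = ", "))
  stats$fdr <- NA_real_
  tested <- !is.na(stats$p)
  stats$fdr[tested] <- p.adjust(stats$p[tested], method = "BH")
  dir <- sign(stats$foldchange)
  stats$direction <- ifelse(dir > 0, "up", ifelse(dir < 0, "down", "flat"))
  agree <- function(cols) {
    m <- sapply(cols, function(cc) sign(stats[[cc]]) == dir & dir != 0)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(stats))
    rowSums(m, na.rm = TRUE) >= 1
  }
  stats$conserved <- agree(paste0("fc_", fish)) &
    agree(paste0("fc_", mammals))
  stats$significant <- !is.na(stats$fdr) & stats$fdr <= fdr_alpha &
    stats$conserved
  stats
}

#' @export
print.ageing_signature <- function(x, ...) {
  pr <- x$processes
  cat(sprintf(
    "ageing_signature [%s]: %d processes, %d pass assumptions, %d in signature\n",
    x$ontology, nrow(pr), sum(pr$assumption_pass), sum(pr$significant)))
  invisible(x)
}

#' Age-label permutation null of the signature size
#'
#' Re-runs the complete detection cascade (assumption filter, backward
#' selection ANOVA, FDR, conservation rule) after randomly reassigning
#' age-group labels within each species x tissue stratum, and records the
#' resulting signature size per replicate.
#'
#' @param pa a normalized `process_activity`.
#' @param n_reps number of label permutations (default 100).
#' @param seed RNG seed (the run is reproducible given the seed).
#' @param ... passed on to [ageing_signature()].
#' @return list with `sizes` (integer vector, one per replicate) and
#'   `quantiles` (0/50/95/100% summary).
#' @export
age_label_permutation_null <- function(pa, n_reps = 100, seed = 1, ...) {
  stopifnot(inherits(pa, "process_activity"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(seed)
  strat <- interaction(pa$meta$species, pa$meta$tissue, drop = TRUE)
  sizes <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    perm <- pa
    for (s in levels(strat)) {
      i <- which(strat == s)
      perm$meta$age_group[i] <- sample(pa$meta$age_group[i])
    }
    sig <- ageing_signature(perm, ...)
    sizes[r] <- sum(sig$processes$significant)
  }
  list(sizes = sizes,
       quantiles = quantile(sizes, c(0, 0.5, 0.95, 1)))
}

#' Differentially expressed genes between young and pooled old samples
#'
#' Per-gene two-sided Wilcoxon rank-sum test of young vs pooled old
#' samples with BH-FDR, splitting significant genes into ageing-induced
#' (`U`, higher in old) and ageing-repressed (`R`) by the sign of the
#' log2 ratio of group medians. Genes constant across all samples get
#' p = 1.
#'
#' @param study an [expression_study()] on the RPKM scale.
#' @param fdr_alpha BH threshold (default 0.05).
#' @return list with gene-id vectors `U` and `R` and the per-gene
#'   `table` (p, fdr, lfc).
#' @export
differential_genes <- function(study, fdr_alpha = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  young <- study$meta$age_group == "young"
  old <- study$meta$age_group %in% OLD_LEVELS
  if (sum(young) < 3 || sum(old) < 3)
    stop("need >= 3 samples in each of young and pooled old")
  v <- study$values
  p <- apply(v, 1, function(x) {
    if (length(unique(x[young | old])) == 1) return(1)
    suppressWarnings(wilcox.test(x[old], x[young])$p.value)
  })
  lfc <- apply(v, 1, function(x)
    log2(median(x[old]) / median(x[young])))
  fdr <- p.adjust(p, method = "BH")
  sig <- fdr <= fdr_alpha & is.finite(lfc) & lfc != 0
  list(U = rownames(v)[sig & lfc > 0],
       R = rownames(v)[sig & lfc < 0],
       table = data.frame(gene = rownames(v), p = p, fdr = fdr,
                          lfc = lfc, row.names = NULL))
}

#' Per-individual activity change between two time points
#'
#' For longitudinal designs where each individual is sampled at two age
#' groups, returns the process x individual matrix of later-minus-earlier
#' activity together with the individuals' lifespans.
#'
#' @param pa a `process_activity` whose metadata carries `individual_id`
#'   and `lifespan`.
#' @param from,to age-group labels of the earlier / later time point.
#' @return list with `change` (process x individual matrix) and
#'   `lifespan` (named vector, days).
#' @export
activity_change <- function(pa, from = "young", to = "old_1") {
  stopifnot(inherits(pa, "process_activity"))
  meta <- pa$meta
  if (is.null(meta$individual_id))
    stop("metadata lacks 'individual_id'")
  if (is.null(meta$lifespan) || anyNA(meta$lifespan))
    stop("lifespan metadata is required but missing")
  ids <- unique(meta$individual_id)
  cols_from <- match(paste(ids, from), paste(meta$individual_id,
                                             meta$age_group))
  cols_to <- match(paste(ids, to), paste(meta$individual_id,
                                         meta$age_group))
  ok <- !is.na(cols_from) & !is.na(cols_to)
  if (sum(ok) < 3) stop("need >= 3 individuals with both time points")
  ch <- pa$activity[, cols_to[ok], drop = FALSE] -
    pa$activity[, cols_from[ok], drop = FALSE]
  colnames(ch) <- ids[ok]
  list(change = ch,
       lifespan = setNames(meta$lifespan[cols_from[ok]], ids[ok]))
}

#' Correlate activity changes with lifespan
#'
#' Pearson correlation, per process, between each individual's activity
#' change during ageing and that individual's lifespan.
#'
#' @param change process x individual matrix of activity changes.
#' @param lifespan numeric vector of lifespans, one per individual.
#' @return data.frame with `process`, `r`, `p` and `flag` (set to
#'   `"zero variance"` where the correlation is undefined).
#' @export
lifespan_correlation <- function(change, lifespan) {
  change <- as.matrix(change)
  if (ncol(change) != length(lifespan))
    stop("need one lifespan per individual")
  if (ncol(change) < 3) stop("need >= 3 individuals")
  rows <- lapply(rownames(change), function(p) {
    x <- change[p, ]
    if (sd(x) == 0 || sd(lifespan) == 0) {
      return(data.frame(process = p, r = NA_real_, p = NA_real_,
                        flag = "zero variance"))
    }
    ct <- cor.test(x, lifespan, method = "pearson")
    data.frame(process = p, r = unname(ct$estimate), p = ct$p.value,
               flag = NA_character_)
  })
  do.call(rbind, rows)
}

#' Write an ageing signature table as TSV
#'
#' @param sig an `ageing_signature`.
#' @param path output path.
#' @export
write_ageing_signature <- function(sig, path) {
  write.table(sig$processes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(sig)
}
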