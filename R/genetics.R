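#' Default trait keyword map
#'
#' Case-insensitive substring keywords assigning GWAS trait strings to
#' the four ageing-disease categories; traits matching none join the
#' non-ageing pool.
#'
#' @return named list of keyword vectors.
#' @export
default_keyword_map <- function() {
  list(
    cancer = c("cancer", "carcinoma", "melanoma", "leukemia", "lymphoma",
               "glioma", "neoplasm", "adenoma", "myeloma"),
    CVD = c("coronary", "cardiovascular", "myocardial", "stroke",
            "hypertension", "atherosclerosis", "heart"),
    NDD = c("alzheimer", "parkinson", "dementia", "amyotrophic",
            "cognitive impairment", "neurodegener"),
    T2D = c("type 2 diabetes", "type ii diabetes", "insulin resistance")
  )
}

#' Partition a SNP catalog into per-category trait sets
#'
#' Matches each record's trait string case-insensitively against the
#' keyword lists. A record matching several disease categories is
#' assigned to all of them; a record matching none joins the
#' `non_ageing` pool.
#'
#' @param catalog a [snp_catalog()].
#' @param keyword_map named list of keyword vectors (see
#'   [default_keyword_map()]).
#' @return named list of `snp_catalog` subsets, one per category plus
#'   `non_ageing`.
#' @export
build_trait_snp_sets <- function(catalog, keyword_map = default_keyword_map()) {
  stopifnot(inherits(catalog, "snp_catalog"))
  trait <- tolower(catalog$trait)
  hit <- matrix(FALSE, nrow(catalog), length(keyword_map),
                dimnames = list(NULL, names(keyword_map)))
  for (cat_ in names(keyword_map)) {
    for (kw in keyword_map[[cat_]]) {
      hit[, cat_] <- hit[, cat_] | grepl(tolower(kw), trait, fixed = TRUE)
    }
  }
  out <- lapply(names(keyword_map), function(cat_) {
    sub <- catalog[hit[, cat_], , drop = FALSE]
    if (!nrow(sub)) warning("no trait matched category '", cat_, "'")
    class(sub) <- c("snp_catalog", "data.frame")
    sub
  })
  names(out) <- names(keyword_map)
  pool <- catalog[rowSums(hit) == 0, , drop = FALSE]
  class(pool) <- c("snp_catalog", "data.frame")
  out$non_ageing <- pool
  out
}

#' Find risk SNPs shared between two SNP sets
#'
#' Shared risk SNPs are either identical rsIDs present in both sets
#' (mode `identical`) or cross-set pairs co-inherited through strong
#' linkage disequilibrium, r-squared at or above `r2_min` (mode `LD`).
#' Pairs of a SNP with itself across sets are the identical mode; LD of
#' a SNP with itself is not considered. Pairs absent from the LD table
#' are treated as unlinked.
#'
#' @param set1,set2 [snp_catalog()] subsets (e.g. two disease
#'   categories).
#' @param ld an [ld_table()].
#' @param r2_min LD threshold for sharing (default 0.8).
#' @return A `shared_snp_set` data.frame: one row per shared pair with
#'   both records' rsIDs, alleles, positions and the sharing mode.
#' @export
find_shared_risk_snps <- function(set1, set2, ld = NULL, r2_min = 0.8) {
  rows <- list()
  add_pair <- function(i, j, mode, r2 = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      rsid_1 = set1$rsid[i], trait_1 = set1$trait[i],
      risk_1 = set1$risk_allele[i], alt_1 = set1$alt_allele[i],
      rsid_2 = set2$rsid[j], trait_2 = set2$trait[j],
      risk_2 = set2$risk_allele[j], alt_2 = set2$alt_allele[j],
      chrom = set1$chrom[i], pos = set1$pos[i],
      chrom_2 = set2$chrom[j], pos_2 = set2$pos[j],
      mode = mode, r2 = r2)
  }
  for (i in seq_len(nrow(set1))) {
    for (j in seq_len(nrow(set2))) {
      if (set1$rsid[i] == set2$rsid[j]) {
        add_pair(i, j, "identical")
      } else if (!is.null(ld)) {
        hit <- ld_lookup(ld, set1$rsid[i], set2$rsid[j])
        if (!is.null(hit) && hit$r2 >= r2_min) add_pair(i, j, "LD", hit$r2)
      }
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, make.row.names = FALSE))
  } else {
    data.frame(rsid_1 = character(), trait_1 = character(),
               risk_1 = character(), alt_1 = character(),
               rsid_2 = character(), trait_2 = character(),
               risk_2 = character(), alt_2 = character(),
               chrom = character(), pos = integer(),
               chrom_2 = character(), pos_2 = integer(),
               mode = character(), r2 = numeric())
  }
  class(out) <- c("shared_snp_set", "data.frame")
  out
}

#' Classify a shared risk-SNP pair
#'
#' Identical pairs: the same risk allele in both sets means
#' `synergistic`; the risk allele of one set equal to the alternative
#' allele of the other means `antagonistic`. LD pairs: the second SNP's
#' risk allele is mapped through the haplotype phase onto the first
#' SNP's alleles before applying the same rule. Alleles that cannot be
#' resolved (missing phase, allele outside the phase map, or mapped
#' allele matching neither allele of the first SNP) give `unclassified`.
#'
#' @param pair one row of a `shared_snp_set`.
#' @param ld the [ld_table()] supplying phase maps for LD-mode pairs.
#' @return `"synergistic"`, `"antagonistic"` or `"unclassified"`.
#' @export
classify_shared_snp <- function(pair, ld = NULL) {
  risk2 <- pair$risk_2
  if (pair$mode == "LD") {
    hit <- if (is.null(ld)) NULL else ld_lookup(ld, pair$rsid_1,
                                                pair$rsid_2)
    if (is.null(hit)) return("unclassified")
    back <- invert_phase_map(hit$phase)  # alleles of 2 -> alleles of 1
    if (!risk2 %in% names(back)) return("unclassified")
    risk2 <- unname(back[risk2])
  }
  if (risk2 == pair$risk_1) return("synergistic")
  if (risk2 == pair$alt_1) return("antagonistic")
  "unclassified"
}

#' Classify every pair of a shared SNP set
#'
#' @param shared a `shared_snp_set`.
#' @param ld the [ld_table()] used for LD-mode phase maps.
#' @return The set with a `label` column added.
#' @export
classify_shared_snps <- function(shared, ld = NULL) {
  shared$label <- vapply(seq_len(nrow(shared)), function(i)
    classify_shared_snp(shared[i, ], ld), character(1))
  shared
}

#' Count independent genomic loci among shared SNPs
#'
#' Builds a graph over the distinct shared SNPs, joining two SNPs when
#' their LD r-squared is at least `r2_cluster` or they lie within
#' `window_bp` on the same chromosome, and counts connected components.
#' Every SNP is assigned exactly one locus id.
#'
#' @param shared a `shared_snp_set` (both sides' SNPs are collected).
#' @param ld an [ld_table()].
#' @param r2_cluster LD threshold for clustering (default 0.5).
#' @param window_bp same-chromosome distance threshold (default 1e6).
#' @return list with `n_loci`, and `loci`: data.frame rsid / chrom /
#'   pos / locus.
#' @export
count_independent_loci <- function(shared, ld = NULL, r2_cluster = 0.5,
                                   window_bp = 1e6) {
  snps <- unique(rbind(
    data.frame(rsid = shared$rsid_1, chrom = shared$chrom,
               pos = shared$pos),
    data.frame(rsid = shared$rsid_2, chrom = shared$chrom_2,
               pos = shared$pos_2)))
  snps <- snps[!duplicated(snps$rsid), , drop = FALSE]
  n <- nrow(snps)
  if (n == 0) return(list(n_loci = 0L, loci = cbind(snps, locus = integer())))
  edges <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      linked <- snps$chrom[i] == snps$chrom[j] &&
        abs(snps$pos[i] - snps$pos[j]) <= window_bp
      if (!linked && !is.null(ld)) {
        hit <- ld_lookup(ld, snps$rsid[i], snps$rsid[j])
        linked <- !is.null(hit) && hit$r2 >= r2_cluster
      }
      if (linked) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  list(n_loci = comp$no,
       loci = cbind(snps, locus = comp$membership))
}

#' Exact binomial test for antagonism bias
#'
#' One-sided exact binomial tail probability of observing at least `k`
#' antagonistic SNPs among `n` shared SNPs when the background
#' antagonistic fraction is `p0` (supplied directly, or estimated from a
#' classified background shared set against non-ageing traits).
#'
#' @param k observed antagonistic count.
#' @param n total shared SNPs.
#' @param p0 background antagonistic fraction; alternatively give
#'   `background`.
#' @param background a classified `shared_snp_set` whose antagonistic
#'   fraction provides `p0`.
#' @return list with `p` (exact upper tail), `p0`, `k`, `n`.
#' @export
antagonism_bias_binomial <- function(k, n, p0 = NULL, background = NULL) {
  if (k > n) stop("k cannot exceed n")
  if (is.null(p0)) {
    if (is.null(background) || !nrow(background))
      stop("need either p0 or a non-empty classified background set")
    if (is.null(background$label))
      stop("background set is not classified")
    p0 <- mean(background$label == "antagonistic")
  }
  p <- sum(dbinom(k:n, n, p0))
  list(p = p, p0 = p0, k = k, n = n)
}

#' Randomization null for shared-SNP counts
#'
#' Replicates the sharing/classification analysis after replacing one
#' category's SNP set by an equally sized draw (without replacement)
#' from the non-ageing pool, recording the synergistic, antagonistic and
#' total shared counts per replicate. Empirical p-values use the
#' add-one correction `(1 + #reps >= observed) / (n_reps + 1)`.
#'
#' @param focal `snp_catalog` of the fixed category (e.g. cancer).
#' @param replaced `snp_catalog` of the category whose size the draws
#'   match (e.g. degenerative diseases).
#' @param pool `snp_catalog` of non-ageing records to draw from.
#' @param ld an [ld_table()].
#' @param r2_min LD sharing threshold passed on.
#' @param n_reps replicates (default 10000).
#' @param seed RNG seed.
#' @return list with `null` (replicate x 3 count matrix), `observed`
#'   counts and `p` (empirical upper-tail p per count).
#' @export
randomization_null_snps <- function(focal, replaced, pool, ld = NULL,
                                    r2_min = 0.8, n_reps = 10000,
                                    seed = 1) {
  if (nrow(pool) < nrow(replaced))
    stop("non-ageing pool smaller than the replaced set")
  count3 <- function(set2) {
    sh <- classify_shared_snps(find_shared_risk_snps(focal, set2, ld,
                                                     r2_min), ld)
    c(synergistic = sum(sh$label == "synergistic"),
      antagonistic = sum(sh$label == "antagonistic"),
      total = nrow(sh))
  }
  observed <- count3(replaced)
  set.seed(seed)
  null <- matrix(0L, n_reps, 3,
                 dimnames = list(NULL, names(observed)))
  for (r in seq_len(n_reps)) {
    draw <- pool[sample.int(nrow(pool), nrow(replaced)), , drop = FALSE]
    class(draw) <- c("snp_catalog", "data.frame")
    null[r, ] <- count3(draw)
  }
  p <- vapply(names(observed), function(s)
    (1 + sum(null[, s] >= observed[[s]])) / (n_reps + 1), numeric(1))
  list(null = null, observed = observed, p = p)
}
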