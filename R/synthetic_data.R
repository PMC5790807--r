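FISH_SPECIES <- c("zebrafish", "nfurzeri")
MAMMAL_SPECIES <- c("mouse", "human")

# Map a target rank-scale activity shift onto a count-scale log
# multiplier for one process, via a normal approximation of the
# two-sample rank statistic. `mu` are the process's gene means, `sig`
# flags its signal (core) genes, `w_old` the age-trend weights of the
# old groups, and the group sizes give the maximal attainable shift.
effect_to_beta <- function(effect, mu, sig, dispersion, w_old,
                           n_young, n_old_each) {
  if (effect == 0) return(0)
  n <- n_young + n_old_each * length(w_old)
  max_shift <- (mean(seq(n_young, n - 1)) - mean(seq(0, n_young - 1))) /
    (n - 1)
  if (effect >= max_shift)
    stop("effect ", effect, " exceeds the maximal rank shift ",
         round(max_shift, 3))
  p_star <- 0.5 + effect / (2 * max_shift)
  cv <- sqrt(sum(mu + dispersion * mu^2)) / sum(mu)
  gap <- function(beta) {
    p_old <- vapply(w_old, function(w) {
      m <- 1 + sum(mu[sig]) * (exp(w * beta) - 1) / sum(mu)
      pnorm((m - 1) / (cv * sqrt(1 + m^2)))
    }, numeric(1))
    mean(p_old) - p_star
  }
  uniroot(gap, c(1e-6, 10))$root
}

#' Generate a synthetic cross-species ageing expression study
#'
#' Emulates the statistical structure the detection pipeline assumes:
#' a fully crossed species x tissue x age-group design with negative
#' binomial counts, an ontology of overlapping gene sets, and a planted
#' monotone age trend (consistent across all species, hence in at least
#' one fish and one mammal) on the core genes of the regulated
#' processes. The `effect` is the target old-minus-young shift of the
#' mean rank-scaled process activity; it is translated to a count-scale
#' multiplier per process (see the methods vignette for the
#' approximation involved).
#'
#' @param n_species,n_tissues,age_groups,n_per_cell design dimensions
#'   (defaults 4 species -- two fish, two mammals -- x 4 tissues x 3 age
#'   groups x 6 samples per cell).
#' @param n_genes,n_processes ontology size (each process: a core of
#'   `n_genes/n_processes` private genes plus genes borrowed from
#'   unregulated processes up to `genes_per_set`).
#' @param n_regulated number of planted age-regulated processes (half
#'   up, half down).
#' @param effect target rank-scale activity shift of regulated
#'   processes.
#' @param genes_per_set total genes per set (default 30).
#' @param dispersion negative binomial dispersion (default 0.1).
#' @param mean_log,sd_log log-scale location/spread of gene mean counts.
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list with `study` (RPKM [expression_study()]), `counts`,
#'   `sets` (a [gene_set_collection()]) and `truth` (planted processes,
#'   directions, per-gene directions, parameters).
#' @export
generate_expression_study <- function(n_species = 4, n_tissues = 4,
                                      age_groups = 3, n_per_cell = 6,
                                      n_genes = 2000, n_processes = 200,
                                      n_regulated = 20, effect = 0.3,
                                      genes_per_set = 30,
                                      dispersion = 0.1,
                                      mean_log = log(200), sd_log = 0.3,
                                      seed = 1) {
  if (n_regulated > n_processes)
    stop("n_regulated cannot exceed n_processes")
  if (!age_groups %in% c(3, 5))
    stop("age_groups must be 3 (young/old_1/old_2) or 5")
  set.seed(seed)
  species <- if (n_species == 4) c(FISH_SPECIES, MAMMAL_SPECIES) else
    paste0(rep(c("fish_", "mammal_"), length.out = n_species),
           seq_len(n_species))
  tissues <- c("blood", "brain", "liver", "skin")[seq_len(min(n_tissues, 4))]
  if (n_tissues > 4) tissues <- c(tissues, paste0("tissue_", 5:n_tissues))
  ages <- if (age_groups == 3) c("young", "old_1", "old_2") else AGE_LEVELS
  w_by_age <- setNames(seq(0, 1, length.out = age_groups), ages)

  meta <- expand.grid(rep = seq_len(n_per_cell), age_group = ages,
                      tissue = tissues, species = species,
                      stringsAsFactors = FALSE)
  meta$sample <- sprintf("s%04d", seq_len(nrow(meta)))
  meta$individual_id <- meta$sample
  n <- nrow(meta)

  genes <- sprintf("g%04d", seq_len(n_genes))
  core_size <- n_genes %/% n_processes
  core_of <- rep(seq_len(n_processes), each = core_size,
                 length.out = n_genes)
  procs <- sprintf("P%03d", seq_len(n_processes))
  regulated <- sort(sample.int(n_processes, n_regulated))
  direction <- setNames(rep(0L, n_processes), procs)
  direction[regulated] <- rep(c(1L, -1L), length.out = n_regulated)
  gene_dir <- direction[core_of]
  names(gene_dir) <- genes

  null_genes <- genes[gene_dir == 0]
  sets <- lapply(seq_len(n_processes), function(p) {
    own <- genes[core_of == p]
    extra <- max(0, genes_per_set - length(own))
    c(own, sample(setdiff(null_genes, own), min(extra,
                                                length(null_genes))))
  })
  names(sets) <- procs
  collection <- gene_set_collection(sets, name = "synthetic_ontology")

  mu0 <- setNames(exp(rnorm(n_genes, mean_log, sd_log)), genes)
  # per-gene species offsets: species-specific baselines, absorbed by
  # the species factor downstream
  sp_off <- matrix(exp(rnorm(n_genes * length(species), 0, 0.2)),
                   n_genes, dimnames = list(genes, species))
  depth <- exp(rnorm(n, 0, 0.2))  # per-sample sequencing depth factor

  w_old <- w_by_age[ages %in% OLD_LEVELS]
  betas <- setNames(numeric(n_processes), procs)
  for (p in which(direction != 0)) {
    gs <- sets[[p]]
    betas[p] <- effect_to_beta(effect, mu0[gs], gene_dir[gs] != 0,
                               dispersion, w_old,
                               n_young = n_per_cell,
                               n_old_each = n_per_cell)
  }
  beta_gene <- ifelse(gene_dir != 0, betas[core_of], 0) * gene_dir

  agew <- w_by_age[meta$age_group]
  counts <- matrix(0L, n_genes, n, dimnames = list(genes, meta$sample))
  for (g in seq_len(n_genes)) {
    mu <- mu0[g] * sp_off[g, meta$species] * depth *
      exp(beta_gene[g] * agew)
    counts[g, ] <- rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  gene_lengths <- setNames(round(runif(n_genes, 500, 5000)), genes)
  rpkm <- rpkm_from_counts(counts, gene_lengths, colSums(counts))
  study <- expression_study(rpkm, meta, gene_lengths)

  truth <- list(
    regulated = data.frame(process = procs[regulated],
                           direction = direction[regulated],
                           effect = effect,
                           beta = betas[regulated], row.names = NULL),
    direction = direction, gene_direction = gene_dir,
    fish = species[grepl("fish|zebra|furzeri", species)],
    mammals = species[!grepl("fish|zebra|furzeri", species)],
    params = list(n_species = n_species, n_tissues = n_tissues,
                  age_groups = age_groups, n_per_cell = n_per_cell,
                  n_genes = n_genes, n_processes = n_processes,
                  n_regulated = n_regulated, effect = effect,
                  genes_per_set = genes_per_set,
                  dispersion = dispersion, seed = seed))
  list(study = study, counts = counts, sets = collection, truth = truth)
}

#' Generate a synthetic disease signature tied to an ageing truth
#'
#' Per-gene case-vs-control foldchange = `c_align` x (planted ageing
#' direction of the gene) + Gaussian noise; genes outside regulated
#' processes are pure noise. `c_align = +1` plants a disease whose
#' signature ageing aligns with, `c_align = -1` one that ageing reverts,
#' and `c_align = 0` a null disease.
#'
#' @param truth the `truth` element of [generate_expression_study()].
#' @param category disease category label.
#' @param c_align alignment coefficient (+1, -1 or 0).
#' @param noise_sd Gaussian noise on the foldchanges (default 0.3).
#' @param id signature id.
#' @param seed RNG seed.
#' @return A raw [disease_signature()] (normalize before scoring).
#' @export
generate_disease_signature <- function(truth, category = "CVD",
                                       c_align = 1, noise_sd = 0.3,
                                       id = NULL, seed = 1) {
  set.seed(seed)
  gd <- truth$gene_direction
  fc <- c_align * gd + rnorm(length(gd), 0, noise_sd)
  if (is.null(id))
    id <- sprintf("synthetic_%s_c%+d", category, c_align)
  disease_signature(setNames(fc, names(gd)), id = id,
                    category = category)
}

NON_AGEING_TRAITS <- c("Height", "Educational attainment", "Hair color",
                       "Coffee consumption", "Handedness",
                       "Freckle count", "Morning person")
CANCER_TRAITS <- c("Breast cancer", "Prostate cancer", "Lung cancer",
                   "Colorectal cancer", "Melanoma")
DEGEN_TRAITS <- c(CVD = "Coronary artery disease",
                  NDD = "Alzheimer's disease",
                  T2D = "Type 2 diabetes")

#' Generate a synthetic risk-SNP catalog with LD blocks
#'
#' Builds `n_loci` genomic loci (1-5 SNPs each, within-locus r-squared
#' at least 0.9 with consistent phase maps, loci separated by at least
#' 30 Mb or on different chromosomes). The first `n_shared_loci` loci
#' each carry exactly one shared risk-SNP pair between a cancer trait
#' and a degenerative-disease trait (identical rsID or an LD partner),
#' labeled antagonistic for a planted fraction of the pairs and
#' synergistic otherwise. Remaining loci belong to single categories,
#' and a non-ageing pool (with a small background sharing rate into the
#' cancer set) completes the catalog.
#'
#' @param n_loci total loci (default 30).
#' @param n_shared_loci loci carrying a shared cancer/degenerative pair
#'   (default 12).
#' @param antagonistic_fraction planted fraction of antagonistic shared
#'   pairs (default 0.9).
#' @param pool_size size of the non-ageing pool (default 500).
#' @param background_share fraction of pool SNPs duplicating a cancer
#'   SNP rsID (background sharing; default 0.02).
#' @param seed RNG seed.
#' @return list with `catalog` ([snp_catalog()]), `ld` ([ld_table()])
#'   and `truth` (planted labels and locus ids).
#' @export
generate_snp_catalog <- function(n_loci = 30, n_shared_loci = 12,
                                 antagonistic_fraction = 0.9,
                                 pool_size = 500,
                                 background_share = 0.02, seed = 1) {
  if (antagonistic_fraction < 0 || antagonistic_fraction > 1)
    stop("antagonistic_fraction must be in [0, 1]")
  if (n_shared_loci > n_loci) stop("n_shared_loci cannot exceed n_loci")
  set.seed(seed)
  rs_counter <- 0L
  next_rsid <- function() {
    rs_counter <<- rs_counter + 1L
    sprintf("rs%05d", rs_counter)
  }
  cat_rows <- list()
  ld_rows <- list()
  add_record <- function(rsid, chrom, pos, trait, risk, alt) {
    cat_rows[[length(cat_rows) + 1]] <<- data.frame(
      rsid = rsid, chrom = chrom, pos = pos, trait = trait,
      risk_allele = risk, alt_allele = alt)
  }
  make_locus <- function(chrom, base_pos, k) {
    # k SNPs within 50 kb; haplotype 1 carries each SNP's first allele
    pos <- sort(base_pos + sample.int(5e4, k))
    alleles <- replicate(k, sample(VALID_ALLELES, 2), simplify = FALSE)
    rsids <- replicate(k, next_rsid())
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        for (j in seq(i + 1, k)) {
          ld_rows[[length(ld_rows) + 1]] <<- data.frame(
            rsid_a = rsids[i], rsid_b = rsids[j],
            r2 = round(runif(1, 0.9, 1), 3),
            phase = sprintf("%s=%s,%s=%s",
                            alleles[[i]][1], alleles[[j]][1],
                            alleles[[i]][2], alleles[[j]][2]))
        }
      }
    }
    list(rsids = rsids, chrom = chrom, pos = pos, alleles = alleles)
  }
  loci <- lapply(seq_len(n_loci), function(i) {
    chrom <- as.character(((i - 1) %% 22) + 1)
    base <- 1e7 + ((i - 1) %/% 22) * 3e7
    make_locus(chrom, base, sample(1:5, 1))
  })
  n_ant <- round(antagonistic_fraction * n_shared_loci)
  planted <- data.frame(locus = seq_len(n_shared_loci),
                        label = rep(c("antagonistic", "synergistic"),
                                    c(n_ant, n_shared_loci - n_ant)),
                        mode = NA_character_, rsid_cancer = NA_character_,
                        rsid_degen = NA_character_)
  for (i in seq_len(n_shared_loci)) {
    loc <- loci[[i]]
    cancer_trait <- CANCER_TRAITS[(i - 1) %% length(CANCER_TRAITS) + 1]
    degen_cat <- names(DEGEN_TRAITS)[(i - 1) %% 3 + 1]
    degen_trait <- DEGEN_TRAITS[[degen_cat]]
    antag <- planted$label[i] == "antagonistic"
    use_ld <- length(loc$rsids) > 1 && i %% 2 == 0
    a1 <- loc$alleles[[1]]
    add_record(loc$rsids[1], loc$chrom, loc$pos[1], cancer_trait,
               a1[1], a1[2])
    if (use_ld) {
      a2 <- loc$alleles[[2]]
      # haplotype 1 pairs first alleles: same-haplotype risk alleles
      # are synergistic, opposite-haplotype antagonistic
      risk2 <- if (antag) a2[2] else a2[1]
      alt2 <- setdiff(a2, risk2)
      add_record(loc$rsids[2], loc$chrom, loc$pos[2], degen_trait,
                 risk2, alt2)
      planted$mode[i] <- "LD"
      planted$rsid_degen[i] <- loc$rsids[2]
    } else {
      risk2 <- if (antag) a1[2] else a1[1]
      add_record(loc$rsids[1], loc$chrom, loc$pos[1], degen_trait,
                 risk2, setdiff(a1, risk2))
      planted$mode[i] <- "identical"
      planted$rsid_degen[i] <- loc$rsids[1]
    }
    planted$rsid_cancer[i] <- loc$rsids[1]
    # remaining SNPs of the locus stay outside the disease categories
    for (j in seq_along(loc$rsids)[-seq_len(if (use_ld) 2 else 1)]) {
      add_record(loc$rsids[j], loc$chrom, loc$pos[j],
                 sample(NON_AGEING_TRAITS, 1),
                 loc$alleles[[j]][1], loc$alleles[[j]][2])
    }
  }
  for (i in seq(n_shared_loci + 1, length.out = n_loci - n_shared_loci)) {
    loc <- loci[[i]]
    cat_i <- c("cancer", names(DEGEN_TRAITS))[(i - 1) %% 4 + 1]
    trait <- if (cat_i == "cancer")
      CANCER_TRAITS[(i - 1) %% length(CANCER_TRAITS) + 1]
    else DEGEN_TRAITS[[cat_i]]
    add_record(loc$rsids[1], loc$chrom, loc$pos[1], trait,
               loc$alleles[[1]][1], loc$alleles[[1]][2])
    for (j in seq_along(loc$rsids)[-1]) {
      add_record(loc$rsids[j], loc$chrom, loc$pos[j],
                 sample(NON_AGEING_TRAITS, 1),
                 loc$alleles[[j]][1], loc$alleles[[j]][2])
    }
  }
  catalog_so_far <- do.call(rbind, cat_rows)
  n_pool_now <- sum(catalog_so_far$trait %in% NON_AGEING_TRAITS)
  n_extra <- max(0, pool_size - n_pool_now)
  n_dup <- round(background_share * n_extra)
  cancer_rows <- catalog_so_far[
    catalog_so_far$trait %in% CANCER_TRAITS, , drop = FALSE]
  dup_idx <- if (n_dup > 0 && nrow(cancer_rows))
    sample.int(nrow(cancer_rows), min(n_dup, nrow(cancer_rows)),
               replace = FALSE) else integer()
  for (i in dup_idx) {
    # background-shared SNP: same position, random risk orientation
    flip <- runif(1) < 0.5
    add_record(cancer_rows$rsid[i], cancer_rows$chrom[i],
               cancer_rows$pos[i], sample(NON_AGEING_TRAITS, 1),
               if (flip) cancer_rows$alt_allele[i] else
                 cancer_rows$risk_allele[i],
               if (flip) cancer_rows$risk_allele[i] else
                 cancer_rows$alt_allele[i])
  }
  for (i in seq_len(n_extra - length(dup_idx))) {
    al <- sample(VALID_ALLELES, 2)
    add_record(next_rsid(), as.character(sample(1:22, 1)),
               2e8 + i * 1e5, sample(NON_AGEING_TRAITS, 1),
               al[1], al[2])
  }
  catalog <- snp_catalog(do.call(rbind, cat_rows))
  ld <- if (length(ld_rows)) ld_table(do.call(rbind, ld_rows)) else
    ld_table(data.frame(rsid_a = character(), rsid_b = character(),
                        r2 = numeric(), phase = character()))
  truth <- list(planted = planted,
                n_shared = n_shared_loci,
                antagonistic_fraction = n_ant / n_shared_loci,
                params = list(n_loci = n_loci,
                              n_shared_loci = n_shared_loci,
                              antagonistic_fraction = antagonistic_fraction,
                              pool_size = pool_size,
                              background_share = background_share,
                              seed = seed))
  list(catalog = catalog, ld = ld, truth = truth)
}

#' Generate a longitudinal study with lifespan-coupled activity changes
#'
#' Each individual is sampled at two time points (young and old_1); for
#' lifespan-associated processes the old-timepoint expression multiplier
#' scales with the individual's (standardized) lifespan, so the
#' per-individual activity change correlates with lifespan. Other
#' processes change independently of lifespan.
#'
#' @param n_individuals individuals (default 30).
#' @param n_genes,n_processes ontology size (disjoint sets here).
#' @param n_assoc lifespan-associated processes (half positive, half
#'   negative association).
#' @param coupling strength of the lifespan dependence of the
#'   age-trend multiplier (default 0.5).
#' @param dispersion negative binomial dispersion.
#' @param seed RNG seed.
#' @return list with `study` (RPKM study incl. `individual_id` and
#'   `lifespan`), `sets` and `truth` (association signs).
#' @export
generate_longitudinal_study <- function(n_individuals = 30,
                                        n_genes = 400, n_processes = 40,
                                        n_assoc = 8, coupling = 0.5,
                                        dispersion = 0.1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  core <- rep(seq_len(n_processes), each = n_genes %/% n_processes,
              length.out = n_genes)
  procs <- sprintf("P%03d", seq_len(n_processes))
  assoc <- setNames(rep(0L, n_processes), procs)
  assoc[sample.int(n_processes, n_assoc)] <-
    rep(c(1L, -1L), length.out = n_assoc)
  lifespan <- round(runif(n_individuals, 400, 1200))
  z <- as.numeric(scale(lifespan))
  meta <- data.frame(
    sample = sprintf("i%03d_%s", rep(seq_len(n_individuals), each = 2),
                     rep(c("young", "old_1"), n_individuals)),
    species = "nfurzeri", tissue = "brain",
    age_group = rep(c("young", "old_1"), n_individuals),
    individual_id = sprintf("i%03d", rep(seq_len(n_individuals),
                                         each = 2)),
    lifespan = rep(lifespan, each = 2))
  mu0 <- exp(rnorm(n_genes, log(200), 0.3))
  beta <- 0.4  # baseline old-timepoint log multiplier of assoc genes
  counts <- matrix(0L, n_genes, nrow(meta),
                   dimnames = list(genes, meta$sample))
  old <- meta$age_group == "old_1"
  zi <- rep(z, each = 2)
  for (g in seq_len(n_genes)) {
    a <- assoc[core[g]]
    lmu <- log(mu0[g]) +
      ifelse(old & a != 0, a * beta * (1 + coupling * zi), 0)
    counts[g, ] <- rnbinom(nrow(meta), mu = exp(lmu),
                           size = 1 / dispersion)
  }
  gl <- setNames(round(runif(n_genes, 500, 5000)), genes)
  study <- expression_study(
    rpkm_from_counts(counts, gl, colSums(counts)), meta, gl)
  sets <- split(genes, core)
  names(sets) <- procs
  list(study = study,
       sets = gene_set_collection(sets, name = "synthetic_longitudinal"),
       truth = list(association = assoc, lifespan = lifespan,
                    params = list(n_individuals = n_individuals,
                                  n_assoc = n_assoc,
                                  coupling = coupling, seed = seed)))
}

#' Serialize a simulation truth object as JSON-like TSV
#'
#' Writes the planted-regulation table of an expression-study truth (or
#' the planted-label table of a SNP truth) so that generated data sets
#' travel with their ground truth.
#'
#' @param truth a `truth` element from a generator.
#' @param path output path.
#' @export
write_simulation_truth <- function(truth, path) {
  tab <- if (!is.null(truth$regulated)) truth$regulated else
    if (!is.null(truth$planted)) truth$planted else
      stop("unrecognized truth object")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
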