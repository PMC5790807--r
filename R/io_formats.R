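# Recognized age-group labels, youngest to oldest. The two old groups are
# pooled wherever an old-vs-young contrast is taken.
AGE_LEVELS <- c("young", "mature_1", "mature_2", "old_1", "old_2")
OLD_LEVELS <- c("old_1", "old_2")

#' Construct an expression study
#'
#' Bundles a gene x sample expression matrix (raw counts or RPKM) with
#' per-sample metadata. Every sample must carry complete `species`,
#' `tissue` and `age_group` annotation; `individual_id` and `lifespan`
#' (days) are optional.
#'
#' @param values numeric gene x sample matrix, non-negative, with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param meta data.frame with one row per sample (rownames = sample ids
#'   or a `sample` column) and columns `species`, `tissue`, `age_group`
#'   and optionally `individual_id`, `lifespan`.
#' @param gene_lengths optional named numeric vector of transcript
#'   lengths in base pairs.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, meta, gene_lengths = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("'values' must have unique gene rownames")
  if (is.null(colnames(values)))
    stop("'values' must have sample colnames")
  if (any(values < 0)) stop("expression values must be non-negative")
  meta <- as.data.frame(meta)
  if ("sample" %in% names(meta)) {
    rownames(meta) <- meta$sample
    meta$sample <- NULL
  }
  if (!all(colnames(values) %in% rownames(meta)))
    stop("every sample in 'values' needs a metadata row")
  meta <- meta[colnames(values), , drop = FALSE]
  req <- c("species", "tissue", "age_group")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  for (cc in req) {
    if (anyNA(meta[[cc]]) || any(!nzchar(as.character(meta[[cc]]))))
      stop("incomplete '", cc, "' metadata")
    meta[[cc]] <- as.character(meta[[cc]])
  }
  bad <- setdiff(unique(meta$age_group), AGE_LEVELS)
  if (length(bad))
    stop("unknown age_group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(AGE_LEVELS, collapse = "/"), ")")
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(values)]
    if (anyNA(gene_lengths)) stop("gene_lengths missing for some genes")
  }
  structure(list(values = values, meta = meta, gene_lengths = gene_lengths),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  species:", paste(unique(x$meta$species), collapse = ", "), "\n")
  cat("  tissues:", paste(unique(x$meta$tissue), collapse = ", "), "\n")
  cat("  age groups:",
      paste(intersect(AGE_LEVELS, unique(x$meta$age_group)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Convert raw counts to RPKM
#'
#' RPKM = reads per kilobase of transcript per million mapped reads:
#' `counts / ((length/1000) * (library_size/1e6))`.
#'
#' @param counts gene x sample matrix of read counts.
#' @param gene_lengths numeric vector of transcript lengths (bp), one per
#'   gene (recycled by name when named).
#' @param library_sizes numeric vector of mapped reads per sample.
#' @return gene x sample matrix of RPKM values.
#' @export
rpkm_from_counts <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (!is.null(names(library_sizes)) && !is.null(colnames(counts)))
    library_sizes <- library_sizes[colnames(counts)]
  if (length(gene_lengths) != nrow(counts))
    stop("need one gene length per row of 'counts'")
  if (length(library_sizes) != ncol(counts))
    stop("need one library size per column of 'counts'")
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("gene lengths must be positive")
  if (anyNA(library_sizes) || any(library_sizes <= 0))
    stop("library sizes must be positive")
  counts / ((gene_lengths / 1e3) %o% (library_sizes / 1e6))
}

#' Drop genes without detectable expression in every sample
#'
#' Removes genes whose value is zero in one or more samples of the study.
#' Intended for RPKM-scale values of a single organism; for multi-species
#' collections apply it to each organism's study separately.
#'
#' @param study an [expression_study()].
#' @return The filtered study (gene order preserved).
#' @export
filter_unexpressed_genes <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  keep <- rowSums(study$values == 0) == 0
  if (!any(keep)) warning("no gene is expressed in all samples")
  study$values <- study$values[keep, , drop = FALSE]
  if (!is.null(study$gene_lengths))
    study$gene_lengths <- study$gene_lengths[keep]
  study
}

#' Read / write an expression study as TSV
#'
#' The expression table is genes (rows) x samples (columns) with gene ids
#' in the first column; the metadata table has one row per sample with a
#' `sample` column plus `species`, `tissue`, `age_group` and optional
#' `individual_id`, `lifespan` columns.
#'
#' @param expr_path path of the expression TSV.
#' @param meta_path path of the metadata TSV.
#' @param lengths_path optional TSV (columns `gene`, `length`).
#' @return An [expression_study()].
#' @export
read_expression_study <- function(expr_path, meta_path, lengths_path = NULL) {
  ex <- read.delim(expr_path, check.names = FALSE)
  genes <- as.character(ex[[1]])
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- genes
  meta <- read.delim(meta_path, check.names = FALSE)
  gl <- NULL
  if (!is.null(lengths_path)) {
    lt <- read.delim(lengths_path)
    gl <- setNames(lt$length, lt$gene)
  }
  expression_study(m, meta, gl)
}

#' @rdname read_expression_study
#' @param study an [expression_study()] to serialize.
#' @export
write_expression_study <- function(study, expr_path, meta_path,
                                   lengths_path = NULL) {
  ex <- data.frame(gene = rownames(study$values), study$values,
                   check.names = FALSE)
  write.table(ex, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = rownames(study$meta), study$meta,
                     check.names = FALSE)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path) && !is.null(study$gene_lengths)) {
    lt <- data.frame(gene = names(study$gene_lengths),
                     length = unname(study$gene_lengths))
    write.table(lt, lengths_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(study)
}

#' Parse a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within
#' a line are removed; empty lines are skipped.
#'
#' @param path path to the GMT file.
#' @param name ontology name attached to the collection (defaults to the
#'   file name).
#' @return A `gene_set_collection`: list with `name`, `sets` (named list
#'   of unique gene-id vectors) and `labels` (set descriptions).
#' @export
parse_gene_sets <- function(path, name = basename(path)) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- list()
  labels <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", lineno[i], ": fewer than 3 tab-separated fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT line ", lineno[i], ": empty gene set '", f[1], "'")
    sets[[f[1]]] <- genes
    labels[[f[1]]] <- f[2]
  }
  gene_set_collection(sets, name = name, labels = labels)
}

#' Construct a gene-set collection
#'
#' @param sets named list of gene-id character vectors (deduplicated,
#'   non-empty).
#' @param name ontology name.
#' @param labels optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, name = "sets", labels = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must have unique names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  if (is.null(labels)) labels <- setNames(names(sets), names(sets))
  structure(list(name = name, sets = sets,
                 labels = labels[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, %d..%d genes\n",
              x$name, length(x$sets), min(lengths(x$sets)),
              max(lengths(x$sets))))
  invisible(x)
}

#' @rdname parse_gene_sets
#' @param collection a `gene_set_collection` to serialize.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$labels[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Construct / read a disease expression signature
#'
#' A disease signature carries per-gene case-vs-control foldchanges for
#' one disease data set, plus its disease-category label. Normalized
#' foldchanges in \[-1, +1\] are filled in by
#' [normalize_disease_foldchanges()].
#'
#' @param foldchange named numeric vector of raw case-vs-control
#'   foldchanges (unique gene names).
#' @param id disease data-set identifier.
#' @param category one of `cancer`, `CVD`, `NDD`, `T2D`, `other`.
#' @return A `disease_signature`.
#' @export
disease_signature <- function(foldchange, id,
                              category = c("cancer", "CVD", "NDD", "T2D",
                                           "other")) {
  category <- match.arg(category)
  if (is.null(names(foldchange)) || anyDuplicated(names(foldchange)))
    stop("'foldchange' must be named with unique gene ids")
  structure(list(id = id, category = category,
                 foldchange = foldchange, normalized = NULL),
            class = "disease_signature")
}

#' @rdname disease_signature
#' @param path TSV with columns `gene` and `foldchange`.
#' @export
read_disease_signature <- function(path, id = basename(path),
                                   category = "other") {
  d <- read.delim(path)
  disease_signature(setNames(d$foldchange, d$gene), id = id,
                    category = category)
}

#' @rdname disease_signature
#' @param sig a `disease_signature` to serialize (raw foldchanges).
#' @export
write_disease_signature <- function(sig, path) {
  write.table(data.frame(gene = names(sig$foldchange),
                         foldchange = unname(sig$foldchange)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sig)
}

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct / parse a risk-SNP catalog
#'
#' Records mirror a GWAS-catalog extract: rsID, chromosome, 1-based
#' position, reported trait string, risk allele and alternative allele.
#' Alleles must be single nucleotides with risk != alternative, and
#' (rsID, trait) pairs must be unique.
#'
#' @param records data.frame with columns `rsid`, `chrom`, `pos`,
#'   `trait`, `risk_allele`, `alt_allele`.
#' @return A `snp_catalog` (a validated data.frame).
#' @export
snp_catalog <- function(records) {
  req <- c("rsid", "chrom", "pos", "trait", "risk_allele", "alt_allele")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("SNP catalog lacks column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[req]
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  bad <- !(records$risk_allele %in% VALID_ALLELES) |
    !(records$alt_allele %in% VALID_ALLELES)
  if (any(bad))
    stop("invalid allele(s) in record(s): ",
         paste(records$rsid[bad], collapse = ", "))
  same <- records$risk_allele == records$alt_allele
  if (any(same))
    stop("risk allele equals alternative allele for: ",
         paste(records$rsid[same], collapse = ", "))
  if (anyDuplicated(records[c("rsid", "trait")]))
    stop("duplicated (rsid, trait) record(s)")
  class(records) <- c("snp_catalog", "data.frame")
  records
}

#' @rdname snp_catalog
#' @param path TSV with a header row and the catalog columns.
#' @export
parse_snp_catalog <- function(path) {
  snp_catalog(read.delim(path, colClasses = "character"))
}

#' @rdname snp_catalog
#' @param catalog a `snp_catalog` to serialize.
#' @export
write_snp_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(catalog)
}

#' Construct / parse a linkage-disequilibrium table
#'
#' Each row links two SNPs with their r-squared and the allele phase map:
#' which allele of SNP a travels with which allele of SNP b on the shared
#' haplotype, encoded `"A=T,G=C"` (allele of a `=` allele of b). Lookups
#' are symmetric: the pair can be queried in either order.
#'
#' @param pairs data.frame with columns `rsid_a`, `rsid_b`, `r2`,
#'   `phase`.
#' @return An `ld_table` (a validated data.frame).
#' @export
ld_table <- function(pairs) {
  req <- c("rsid_a", "rsid_b", "r2", "phase")
  miss <- setdiff(req, names(pairs))
  if (length(miss))
    stop("LD table lacks column(s): ", paste(miss, collapse = ", "))
  pairs <- as.data.frame(pairs)[req]
  pairs$r2 <- as.numeric(pairs$r2)
  if (anyNA(pairs$r2) || any(pairs$r2 < 0 | pairs$r2 > 1))
    stop("r2 outside [0, 1]")
  for (i in seq_len(nrow(pairs))) parse_phase(pairs$phase[i])  # validate
  class(pairs) <- c("ld_table", "data.frame")
  pairs
}

#' @rdname ld_table
#' @param path TSV with a header row and the LD columns.
#' @export
parse_ld_table <- function(path) {
  ld_table(read.delim(path, colClasses = "character"))
}

#' @rdname ld_table
#' @param ld an `ld_table` to serialize.
#' @export
write_ld_table <- function(ld, path) {
  write.table(as.data.frame(ld), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ld)
}

# "A=T,G=C" -> named chr c(A = "T", G = "C"); must be a bijection over
# two alleles of each SNP.
parse_phase <- function(phase) {
  parts <- strsplit(strsplit(phase, ",", fixed = TRUE)[[1]], "=",
                    fixed = TRUE)
  if (length(parts) != 2 || any(lengths(parts) != 2))
    stop("malformed phase map: '", phase, "'")
  map <- setNames(vapply(parts, `[`, character(1), 2),
                  vapply(parts, `[`, character(1), 1))
  if (anyDuplicated(names(map)) || anyDuplicated(unname(map)) ||
      !all(c(names(map), map) %in% VALID_ALLELES))
    stop("phase map is not an allele bijection: '", phase, "'")
  map
}

invert_phase_map <- function(map) setNames(names(map), unname(map))

#' Look up an LD pair symmetrically
#'
#' @param ld an [ld_table()].
#' @param rsid_a,rsid_b the two rsIDs, in any order.
#' @return `NULL` if the pair is absent, else a list with `r2` and
#'   `phase` (named character vector mapping alleles of `rsid_a` to
#'   alleles of `rsid_b`).
#' @export
ld_lookup <- function(ld, rsid_a, rsid_b) {
  i <- which(ld$rsid_a == rsid_a & ld$rsid_b == rsid_b)
  if (length(i)) {
    return(list(r2 = ld$r2[i[1]], phase = parse_phase(ld$phase[i[1]])))
  }
  i <- which(ld$rsid_a == rsid_b & ld$rsid_b == rsid_a)
  if (length(i)) {
    return(list(r2 = ld$r2[i[1]],
                phase = invert_phase_map(parse_phase(ld$phase[i[1]]))))
  }
  NULL
}

#' Map genes across species through a homolog table
#'
#' Renames the genes of a study according to a two-column homolog map
#' (`gene`, `homolog`). Only one-to-one mappings are used; genes mapping
#' to several homologs (or several genes mapping to the same homolog) are
#' dropped, with a message reporting the count.
#'
#' @param study an [expression_study()].
#' @param map data.frame with columns `gene` and `homolog`.
#' @return The study on the homolog namespace.
#' @export
map_homologs <- function(study, map) {
  stopifnot(inherits(study, "expression_study"))
  map <- map[map$gene %in% rownames(study$values), , drop = FALSE]
  ambig <- unique(c(map$gene[duplicated(map$gene) |
                               duplicated(map$gene, fromLast = TRUE)],
                    map$gene[map$homolog %in%
                               map$homolog[duplicated(map$homolog)]]))
  if (length(ambig))
    message("dropping ", length(ambig),
            " gene(s) with ambiguous homolog mappings")
  map <- map[!(map$gene %in% ambig), , drop = FALSE]
  keep <- rownames(study$values) %in% map$gene
  study$values <- study$values[keep, , drop = FALSE]
  idx <- match(rownames(study$values), map$gene)
  rownames(study$values) <- map$homolog[idx]
  if (!is.null(study$gene_lengths)) {
    study$gene_lengths <- setNames(study$gene_lengths[keep],
                                   rownames(study$values))
  }
  study
}
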