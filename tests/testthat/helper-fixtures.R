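# Small fixtures built in code, shared across test files.

# tiny single-species study: `values` optionally overridden
toy_study <- function(values = NULL, species = "mouse", tissue = "liver",
                      ages = c("young", "young", "young",
                               "old_1", "old_1", "old_2")) {
  n <- length(ages)
  if (is.null(values)) {
    values <- matrix(seq_len(3 * n) + 0.5, nrow = 3,
                     dimnames = list(paste0("g", 1:3),
                                     paste0("s", seq_len(n))))
  }
  meta <- data.frame(sample = colnames(values), species = species,
                     tissue = tissue, age_group = ages,
                     individual_id = colnames(values))
  expression_study(values, meta)
}

# fully crossed multi-factor study with chosen cell means
crossed_meta <- function(n_rep = 3, ages = c("young", "old_1"),
                         species = c("sp1", "sp2"),
                         tissues = c("t1", "t2")) {
  m <- expand.grid(rep = seq_len(n_rep), age_group = ages,
                   species = species, tissue = tissues,
                   stringsAsFactors = FALSE)
  m$sample <- sprintf("s%03d", seq_len(nrow(m)))
  m$individual_id <- m$sample
  m
}

toy_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal SNP catalog rows
snp_row <- function(rsid, chrom, pos, trait, risk, alt) {
  data.frame(rsid = rsid, chrom = as.character(chrom), pos = pos,
             trait = trait, risk_allele = risk, alt_allele = alt)
}

# disease signature with normalized values set directly (already on the
# [-1, 1] scale); bypasses rank normalization for algebraic tests
normalized_signature <- function(normalized, id = "toy",
                                 category = "other") {
  sig <- disease_signature(normalized, id = id, category = category)
  sig$normalized <- normalized
  sig
}

# independent BH step-up computation (oracle)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# Independent oracle: classical sums-of-squares decomposition for a
# balanced full-factorial a x b x c design with r replicates per cell.
balanced_ss_oracle <- function(y, A, B, C) {
  gm <- mean(y)
  mt <- function(...) tapply(y, list(...), mean)
  r <- length(y) / (nlevels(A) * nlevels(B) * nlevels(C))
  ssA <- r * nlevels(B) * nlevels(C) * sum((mt(A) - gm)^2)
  ssB <- r * nlevels(A) * nlevels(C) * sum((mt(B) - gm)^2)
  ssC <- r * nlevels(A) * nlevels(B) * sum((mt(C) - gm)^2)
  ab <- mt(A, B); ssAB <- r * nlevels(C) *
    sum((ab - outer(mt(A), mt(B), "+") + gm)^2)
  ac <- mt(A, C); ssAC <- r * nlevels(B) *
    sum((ac - outer(mt(A), mt(C), "+") + gm)^2)
  bc <- mt(B, C); ssBC <- r * nlevels(A) *
    sum((bc - outer(mt(B), mt(C), "+") + gm)^2)
  cell <- mt(A, B, C)
  ssE <- sum((y - cell[cbind(A, B, C)])^2)
  ssT <- sum((y - gm)^2)
  ssABC <- ssT - ssA - ssB - ssC - ssAB - ssAC - ssBC - ssE
  list(ss = c(ssA, ssB, ssC, ssAB, ssAC, ssBC, ssABC), ssE = ssE,
       df = c(nlevels(A) - 1, nlevels(B) - 1, nlevels(C) - 1,
              (nlevels(A) - 1) * (nlevels(B) - 1),
              (nlevels(A) - 1) * (nlevels(C) - 1),
              (nlevels(B) - 1) * (nlevels(C) - 1),
              (nlevels(A) - 1) * (nlevels(B) - 1) * (nlevels(C) - 1)),
       dfE = length(y) - nlevels(A) * nlevels(B) * nlevels(C))
}
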