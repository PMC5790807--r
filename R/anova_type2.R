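#' Build a factorial ANOVA design
#'
#' Precomputes the model matrix of a fully crossed factorial design with
#' all interactions up to `max_order`, together with a cache of QR
#' factorizations for sub-models. Because the design is shared by every
#' process analyzed on the same samples, the cache makes repeated
#' backward-selection fits cheap.
#'
#' @param meta data.frame of per-sample metadata.
#' @param factors character vector of factor column names; the first is
#'   conventionally the age factor.
#' @param max_order highest interaction order to include (default 3).
#' @param age_levels age-group labels admitted into the analysis; samples
#'   outside these levels must be excluded upstream.
#' @return An `anova_design` object.
#' @export
anova_design <- function(meta, factors = c("age_group", "species", "tissue"),
                         max_order = 3,
                         age_levels = c("young", "old_1", "old_2")) {
  miss <- setdiff(factors, names(meta))
  if (length(miss))
    stop("metadata lacks factor column(s): ", paste(miss, collapse = ", "))
  data <- meta[factors]
  for (f in factors) {
    if (f == factors[1] && all(data[[f]] %in% AGE_LEVELS)) {
      bad <- setdiff(unique(data[[f]]), age_levels)
      if (length(bad))
        stop("samples with age group(s) ", paste(bad, collapse = ", "),
             " must be excluded before building the design")
      data[[f]] <- factor(data[[f]], levels = age_levels)
      data[[f]] <- droplevels(data[[f]])
    } else {
      data[[f]] <- factor(data[[f]])
    }
  }
  if (any(vapply(data, nlevels, integer(1)) < 2))
    stop("every design factor needs >= 2 levels")
  max_order <- min(max_order, length(factors))
  terms <- unlist(lapply(seq_len(max_order), function(k) {
    combn(factors, k, paste, collapse = ":", simplify = FALSE)
  }))
  X <- model.matrix(reformulate(terms), data = data)
  assign <- attr(X, "assign")  # 0 = intercept, i = terms[i]
  structure(list(data = data, factors = factors, terms = terms,
                 X = X, assign = assign, n = nrow(X),
                 cache = new.env(parent = emptyenv())),
            class = "anova_design")
}

term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# does term u strictly contain term t?
term_contains <- function(u, t) {
  fu <- term_factors(u); ft <- term_factors(t)
  length(fu) > length(ft) && all(ft %in% fu)
}

# cached QR of the sub-model spanned by `terms` (+ intercept)
design_qr <- function(design, terms) {
  key <- paste0("m", paste(sort(match(terms, design$terms)),
                           collapse = ","))
  q <- design$cache[[key]]
  if (is.null(q)) {
    cols <- design$assign %in% c(0L, match(terms, design$terms))
    q <- qr(design$X[, cols, drop = FALSE])
    design$cache[[key]] <- q
  }
  q
}

design_rss <- function(design, y, terms) {
  q <- design_qr(design, terms)
  r <- qr.resid(q, y)
  c(rss = sum(r * r), rank = q$rank)
}

#' Type-II ANOVA table
#'
#' Computes type-II sums of squares for each term of the model given by
#' `terms`: the SS of a term is the reduction in residual SS when it is
#' added to the model containing all terms that do not contain it; F uses
#' the residual mean square of the full `terms` model. Terms that add no
#' estimable columns (rank deficiency from empty cells) get `NA`
#' statistics.
#'
#' @param design an [anova_design()].
#' @param y numeric response vector.
#' @param terms model terms (default: the full design).
#' @return data.frame with columns `term`, `df`, `ss`, `f`, `p`.
#' @export
type2_table <- function(design, y, terms = design$terms) {
  full <- design_rss(design, y, terms)
  df_res <- design$n - full["rank"]
  ms_res <- full["rss"] / df_res
  rows <- lapply(terms, function(t) {
    others <- terms[!vapply(terms, function(u)
      u == t || term_contains(u, t), logical(1))]
    without <- design_rss(design, y, others)
    with_t <- design_rss(design, y, c(others, t))
    df_t <- with_t["rank"] - without["rank"]
    ss_t <- without["rss"] - with_t["rss"]
    if (df_t < 1 || df_res < 1 || ms_res <= 0) {
      data.frame(term = t, df = unname(df_t), ss = unname(ss_t),
                 f = NA_real_, p = NA_real_)
    } else {
      f <- (ss_t / df_t) / ms_res
      data.frame(term = t, df = unname(df_t), ss = unname(ss_t),
                 f = unname(f),
                 p = unname(pf(f, df_t, df_res, lower.tail = FALSE)))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "rss_residual") <- unname(full["rss"])
  attr(out, "df_residual") <- unname(df_res)
  out
}

#' Check ANOVA model assumptions for one process
#'
#' Normality of the full-model residuals (Shapiro-Wilk) and homogeneity
#' of variance across design cells (Levene's test, `car::leveneTest`
#' with its default median centering). The process fails when either
#' p-value is at or below `alpha`, or when the residual variance is
#' (numerically) zero.
#'
#' @param y numeric activity vector.
#' @param design an [anova_design()].
#' @param alpha assumption-filter threshold (default 0.005; deliberately
#'   stringent so that only clear violations are discarded).
#' @return list with `pass`, `shapiro_p`, `levene_p`, `reason`.
#' @export
check_model_assumptions <- function(y, design, alpha = 0.005) {
  stopifnot(inherits(design, "anova_design"))
  q <- design_qr(design, design$terms)
  if (design$n - q$rank < 3)
    stop("need >= 3 residual degrees of freedom")
  res <- qr.resid(q, y)
  if (sd(res) < .Machine$double.eps^0.5 * max(1, sd(y)))
    return(list(pass = FALSE, shapiro_p = NA_real_, levene_p = NA_real_,
                reason = "degenerate"))
  sw <- shapiro.test(res)$p.value
  cells <- interaction(design$data, drop = TRUE)
  lv <- car::leveneTest(y ~ cells)[1, "Pr(>F)"]
  pass <- sw > alpha && lv > alpha
  list(pass = pass, shapiro_p = sw, levene_p = lv,
       reason = if (pass) NA_character_ else "assumption violation")
}

#' Fit the age ANOVA with backward selection
#'
#' Fits the full factorial type-II model and iteratively removes the
#' least significant admissible term: a term may be removed only when no
#' retained higher-order term contains it, removal starts from the
#' highest interaction order, and proceeds while the candidate's p-value
#' exceeds `reduce_alpha`. Selection stops when nothing admissible
#' remains above the threshold or when the age main effect itself is the
#' candidate; in the latter case the age effect is reported as removed.
#' Inestimable terms (no added rank, e.g. from empty cells) are dropped
#' first with a note.
#'
#' @param y numeric activity vector.
#' @param design an [anova_design()]; its first factor is the age term.
#' @param reduce_alpha backward-selection threshold (default 0.05).
#' @return list with `p_age` (NA when removed), `age_removed`, `terms`
#'   (final model), `table` (final type-II table) and `notes`.
#' @export
fit_age_anova <- function(y, design, reduce_alpha = 0.05) {
  stopifnot(inherits(design, "anova_design"))
  age <- design$factors[1]
  terms <- design$terms
  notes <- character()
  repeat {
    tab <- type2_table(design, y, terms)
    removable <- vapply(terms, function(t) {
      !any(vapply(terms, term_contains, logical(1), t = t))
    }, logical(1))
    cand <- tab[removable, , drop = FALSE]
    if (!nrow(cand)) break
    # inestimable terms go first
    bad <- cand$term[is.na(cand$p) & cand$df < 1]
    if (length(bad)) {
      drop_t <- bad[1]
      notes <- c(notes, paste0("dropped inestimable term ", drop_t))
      terms <- setdiff(terms, drop_t)
      if (drop_t == age)
        return(list(p_age = NA_real_, age_removed = TRUE, terms = terms,
                    table = type2_table(design, y, terms), notes = notes))
      next
    }
    # candidate with largest p; ties: higher order first, then name
    ord <- order(-cand$p,
                 -lengths(lapply(cand$term, term_factors)),
                 cand$term)
    top <- cand[ord[1], ]
    if (is.na(top$p) || top$p <= reduce_alpha) break
    if (top$term == age) {
      terms <- setdiff(terms, age)
      return(list(p_age = NA_real_, age_removed = TRUE, terms = terms,
                  table = if (length(terms)) type2_table(design, y, terms)
                          else NULL,
                  notes = notes))
    }
    terms <- setdiff(terms, top$term)
  }
  tab <- type2_table(design, y, terms)
  p_age <- tab$p[tab$term == age]
  list(p_age = if (length(p_age)) p_age else NA_real_,
       age_removed = FALSE, terms = terms, table = tab, notes = notes)
}
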