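#' Per-superfamily and per-lineage element summary
#'
#' Counts elements per superfamily and lineage with percentages of the
#' superfamily total, of the classified total (elements with a known
#' superfamily), and of the grand total. Percentages are rounded half-up to
#' 2 decimals. Accepts either an annotation table (one row per element,
#' columns `superfamily` and `lineage`) or a pre-aggregated table with a
#' `count` column.
#'
#' @param annotations Annotation table or count table.
#' @return A list of class `lineage_summary`: `superfamily` (count,
#'   `pct_grand` of the table total) and `lineage` (count,
#'   `pct_superfamily`, `pct_grand`) data.frames, plus `n_total` and
#'   `n_classified` (elements with a known superfamily).
#' @export
lineage_summary <- function(annotations) {
  if ("count" %in% names(annotations)) {
    df <- annotations[rep(seq_len(nrow(annotations)), annotations$count),
                      c("superfamily", "lineage")]
  } else {
    df <- annotations[, c("superfamily", "lineage")]
  }
  n_total <- nrow(df)
  classified <- df$superfamily != "unknown"
  n_classified <- sum(classified)
  sf_tab <- as.data.frame(table(superfamily = df$superfamily),
                          stringsAsFactors = FALSE)
  names(sf_tab)[2] <- "count"
  sf_tab$pct_grand <- round_half_up(100 * sf_tab$count / n_total, 2)
  lin <- df[classified & df$lineage != "unknown", , drop = FALSE]
  if (nrow(lin) > 0) {
    lin_tab <- as.data.frame(table(superfamily = lin$superfamily,
                                   lineage = lin$lineage),
                             stringsAsFactors = FALSE)
    names(lin_tab)[3] <- "count"
    lin_tab <- lin_tab[lin_tab$count > 0, , drop = FALSE]
    sf_tot <- tapply(lin_tab$count, lin_tab$superfamily, sum)
    lin_tab$pct_superfamily <- round_half_up(
      100 * lin_tab$count / sf_tot[lin_tab$superfamily], 2)
    lin_tab$pct_grand <- round_half_up(100 * lin_tab$count / n_total, 2)
    lin_tab <- lin_tab[order(lin_tab$superfamily, -lin_tab$count), ]
    rownames(lin_tab) <- NULL
  } else {
    lin_tab <- data.frame(superfamily = character(0), lineage = character(0),
                          count = integer(0), pct_superfamily = numeric(0),
                          pct_grand = numeric(0))
  }
  structure(list(superfamily = sf_tab, lineage = lin_tab,
                 n_total = n_total, n_classified = n_classified),
            class = "lineage_summary")
}

# compact letter display by insert-and-absorb over the non-significance
# graph: start with one letter covering all groups, split it on every
# significant pair, absorb redundant letter sets, order letters by
# descending group mean
.compact_letters <- function(groups, sig_pairs, means) {
  sets <- list(groups)
  for (r in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs[r, 1]; b <- sig_pairs[r, 2]
    for (si in seq_along(sets)) {
      s <- sets[[si]]
      if (a %in% s && b %in% s) {
        sets[[si]] <- setdiff(s, a)
        sets[[length(sets) + 1]] <- setdiff(s, b)
      }
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) for (j in seq_along(sets))
      if (i != j && keep[i] && keep[j] &&
          all(sets[[i]] %in% sets[[j]])) keep[i] <- FALSE
    sets <- sets[keep]
  }
  ord <- order(vapply(sets, function(s) -max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (si in seq_along(sets))
    for (g in sets[[si]])
      out[g] <- paste0(out[g], letters[si])
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA across groups, runs Tukey's HSD on the studentised
#' range (Tukey-Kramer for unequal group sizes, via [stats::TukeyHSD()]),
#' and builds a compact letter display from the pairwise non-significance
#' graph: groups sharing a letter are not significantly different at
#' `alpha`. With zero within-group variance everywhere and equal means the
#' F statistic is undefined and the result is reported as non-significant.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups, each
#'   with >= 2 values).
#' @param alpha Significance level for the letter display.
#' @return A list of class `ltr_anova`: `F`, `p`, `means`, `tukey`
#'   (data.frame of pairwise comparisons), `letters` (named character).
#' @export
anova_tukey <- function(values_by_group, alpha = 0.05) {
  stopifnot(length(values_by_group) >= 2,
            all(lengths(values_by_group) >= 2))
  g <- factor(rep(names(values_by_group), lengths(values_by_group)),
              levels = names(values_by_group))
  y <- unlist(values_by_group, use.names = FALSE)
  means <- vapply(values_by_group, mean, numeric(1))
  if (stats::var(y) == 0) {
    letters_out <- stats::setNames(rep("a", length(values_by_group)),
                                   names(values_by_group))
    return(structure(list(F = 0, p = 1, means = means,
                          tukey = data.frame(), letters = letters_out),
                     class = "ltr_anova"))
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  pv <- s[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  pairs <- do.call(rbind, strsplit(tukey$comparison, "-", fixed = TRUE))
  sig <- tukey$p_adj < alpha
  letters_out <- .compact_letters(names(values_by_group),
                                  pairs[sig, , drop = FALSE], means)
  structure(list(F = Fv, p = pv, means = means, tukey = tukey,
                 letters = letters_out),
            class = "ltr_anova")
}

#' @export
print.ltr_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.3g\n", x$F, x$p))
  df <- data.frame(mean = x$means, letters = x$letters[names(x$means)])
  print(df)
  invisible(x)
}

#' Ordinary least-squares regression with Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 2); `x` must vary.
#' @return A list of class `ltr_regression`: `slope`, `intercept`, `r`,
#'   `p` (two-sided, from the t distribution; NA when n < 3), `n`.
#' @export
regress <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete observations")
  if (stats::var(x) == 0) stop("constant x: regression undefined")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  p <- if (n >= 3 && abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  } else if (n >= 3) 0 else NA_real_
  structure(list(slope = slope, intercept = intercept, r = r, p = p, n = n),
            class = "ltr_regression")
}

#' @export
print.ltr_regression <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, r %.3f, p %s, n %d\n",
              x$slope, x$intercept, x$r,
              ifelse(is.na(x$p), "NA", format(x$p, digits = 3)), x$n))
  invisible(x)
}

#' Per-treatment regression slopes of expression against age and abundance
#'
#' For each treatment (C24, S24, C48, S48), regresses the treatment's mean
#' RPKM on estimated insertion age and on genomic abundance. Expression
#' regressions are restricted to Copia elements by default (Gypsy elements
#' are typically too lowly expressed for the correlation to be meaningful).
#'
#' @param elements Joined table with columns `superfamily`, `age_years`,
#'   `coverage`, and one `rpkm_<treatment>` column per treatment.
#' @param treatments Treatment labels (default C24, S24, C48, S48).
#' @param superfamily_filter Superfamily kept for the expression
#'   regressions (default `"Copia"`; NULL keeps all).
#' @return A data.frame: `correlation` (expression_vs_age /
#'   expression_vs_abundance), `treatment`, `slope`, `intercept`, `r`, `p`,
#'   `n`.
#' @export
slope_table <- function(elements,
                        treatments = c("C24", "S24", "C48", "S48"),
                        superfamily_filter = "Copia") {
  cols <- paste0("rpkm_", treatments)
  if (!all(cols %in% names(elements)))
    stop("missing treatment column(s): ",
         paste(setdiff(cols, names(elements)), collapse = ", "))
  df <- elements
  if (!is.null(superfamily_filter))
    df <- df[df$superfamily %in% superfamily_filter, , drop = FALSE]
  rows <- list()
  for (t in treatments) {
    yv <- df[[paste0("rpkm_", t)]]
    for (what in c("age", "abundance")) {
      xv <- if (what == "age") df$age_years else df$coverage
      reg <- regress(xv, yv)
      rows[[length(rows) + 1]] <- data.frame(
        correlation = paste0("expression_vs_", what), treatment = t,
        slope = reg$slope, intercept = reg$intercept, r = reg$r, p = reg$p,
        n = reg$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$correlation, match(out$treatment, treatments)), ]
}
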