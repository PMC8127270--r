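test_that("lineage summary recomputes percentages from counts", {
  counts <- data.frame(
    superfamily = c(rep("Copia", 8), rep("Gypsy", 6), "unknown"),
    lineage = c("Ale", "Angela", "Bianca", "Ikeros", "Ivana", "Sire", "TAR",
                "Tork", "CRM", "Galadriel", "Reina", "Tekay", "Athila",
                "Ogre-Tat", "unknown"),
    count = c(319, 152, 4, 34, 22, 14, 41, 37,
              108, 15, 8, 704, 125, 203, 74))
  s <- lineage_summary(counts)
  lin <- s$lineage
  pct <- function(l) lin$pct_superfamily[lin$lineage == l]
  expect_equal(pct("Ale"), 51.20)
  expect_equal(pct("Tekay"), 60.53)
  expect_equal(pct("Bianca"), 0.64)
  expect_equal(pct("Ivana"), 3.53)
  expect_equal(pct("TAR"), 6.58)
  expect_equal(pct("Ogre-Tat"), 17.45)
  sf <- s$superfamily
  expect_equal(sf$pct_grand[sf$superfamily == "Copia"], 33.49)
  expect_equal(s$n_total, 1860)

  # single element -> 100%
  one <- lineage_summary(data.frame(superfamily = "Copia", lineage = "Ale"))
  expect_equal(one$lineage$pct_superfamily, 100)
  expect_equal(one$superfamily$pct_grand, 100)
})

test_that("one-way ANOVA matches definitional sums of squares", {
  # hand-computed fixture: SSB = 54 (df 2), SSW = 6 (df 6) -> F = 27
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  r <- anova_tukey(g)
  expect_equal(r$F, 27, tolerance = 1e-12)

  # random fixtures against the definitional computation
  set.seed(120)
  for (i in 1:10) {
    vals <- lapply(1:4, function(j) rnorm(sample(3:8, 1), mean = j))
    names(vals) <- paste0("g", 1:4)
    r2 <- anova_tukey(vals)
    y <- unlist(vals); gm <- mean(y)
    k <- length(vals); N <- length(y)
    ssb <- sum(lengths(vals) * (vapply(vals, mean, 0) - gm)^2)
    ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
    f_def <- (ssb / (k - 1)) / (ssw / (N - k))
    expect_equal(r2$F, f_def, tolerance = 1e-9)
  }

  # three identical groups: F = 0, one shared letter
  same <- list(a = c(1, 2), b = c(1, 2), c = c(1, 2))
  rs <- anova_tukey(same)
  expect_equal(rs$F, 0, tolerance = 1e-12)
  expect_equal(length(unique(rs$letters)), 1)
})

test_that("compact letters are consistent with the Tukey pairwise matrix", {
  set.seed(121)
  check_letters <- function(r, alpha = 0.05) {
    pairs <- do.call(rbind, strsplit(r$tukey$comparison, "-", fixed = TRUE))
    for (k in seq_len(nrow(pairs))) {
      shared <- any(strsplit(r$letters[[pairs[k, 1]]], "")[[1]] %in%
                      strsplit(r$letters[[pairs[k, 2]]], "")[[1]])
      if (r$tukey$p_adj[k] < alpha) expect_false(shared)
      else expect_true(shared)
    }
  }
  # two far-apart groups with an intermediate overlapping both: a / ab / b
  g <- list(lo = c(1.43, -0.21, 1.25, -0.23),
            mid = c(2.26, 2.08, 1.98, 2.45),
            hi = c(2.47, 4.94, 2.67, 3.63))
  r <- anova_tukey(g)
  check_letters(r)
  expect_equal(unname(r$letters[c("hi", "mid", "lo")]), c("a", "ab", "b"))

  # random fixtures
  for (i in 1:10) {
    vals <- lapply(1:5, function(j) rnorm(sample(3:6, 1),
                                          mean = sample(1:4, 1)))
    names(vals) <- paste0("g", 1:5)
    check_letters(anova_tukey(vals))
  }
})

test_that("regression returns OLS coefficients, r and valid p-values", {
  x <- 1:10
  r <- regress(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r, 1)

  # slope equals cov/var on a 5-point hand example
  x5 <- c(1, 2, 4, 7, 9); y5 <- c(3, 1, 6, 8, 7)
  r5 <- regress(x5, y5)
  expect_equal(r5$slope, cov(x5, y5) / var(x5), tolerance = 1e-12)
  expect_equal(r5$intercept, mean(y5) - r5$slope * mean(x5), tolerance = 1e-12)

  # under the null, p-values are uniform (KS over 200 replicates)
  set.seed(122)
  ps <- replicate(200, regress(rnorm(15), rnorm(15))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  # n = 2: slope defined, p absent
  r2 <- regress(c(1, 2), c(5, 9))
  expect_equal(r2$slope, 4)
  expect_true(is.na(r2$p))

  expect_error(regress(rep(1, 5), rnorm(5)), "constant")
})

test_that("slope table mirrors the four-treatment layout", {
  set.seed(123)
  n <- 40
  mk <- function(noise = 0.2) {
    df <- data.frame(superfamily = rep(c("Copia", "Gypsy"), each = n / 2),
                     age_years = runif(n, 1e6, 1e7),
                     coverage = runif(n, 1, 50))
    for (t in c("C24", "S24", "C48", "S48"))
      df[[paste0("rpkm_", t)]] <-
        pmax(10 - df$age_years / 1e6 + rnorm(n, 0, noise), 0)
    df
  }
  df <- mk()
  st <- slope_table(df)
  expect_equal(nrow(st), 8)  # 2 correlations x 4 treatments
  age_rows <- st[st$correlation == "expression_vs_age", ]
  expect_true(all(age_rows$slope < 0))  # expression declines with age
  # only Copia elements enter the expression correlations
  expect_true(all(st$n == n / 2))

  # null simulation: slopes centred on zero
  set.seed(124)
  slopes <- replicate(50, {
    df0 <- mk()
    for (t in c("C24", "S24", "C48", "S48"))
      df0[[paste0("rpkm_", t)]] <- rexp(n)
    slope_table(df0)$slope[1]
  })
  expect_lt(abs(mean(slopes) * 1e6), 3 * sd(slopes * 1e6) / sqrt(50))

  expect_error(slope_table(df[, -4]), "missing treatment")

  # two elements: slope defined, p absent
  tiny <- df[df$superfamily == "Copia", ][1:2, ]
  st2 <- slope_table(tiny)
  expect_true(all(is.finite(st2$slope)))
  expect_true(all(is.na(st2$p)))
})
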