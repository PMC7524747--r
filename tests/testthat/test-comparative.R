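# Comparative layers: identification fractions, contrasts, complexes,
# correlations.

test_that("heavy identification fraction: definition, bounds, invariance", {
  expect_equal(heavy_id_fraction(250, 250), 50)
  expect_equal(heavy_id_fraction(0, 500), 0)
  expect_true(is.na(heavy_id_fraction(0, 0)))
  expect_error(heavy_id_fraction(-1, 5), "non-negative")
  # scale invariance and bounds over random counts
  withr::local_seed(61)
  h <- rpois(50, 40); l <- rpois(50, 60)
  f <- heavy_id_fraction(h, l)
  expect_equal(f, heavy_id_fraction(7 * h, 7 * l))
  expect_true(all(f >= 0 & f <= 100, na.rm = TRUE))
})

test_that("slope-set comparison: identity, degeneracy, Welch oracle", {
  x <- c(-0.1, -0.12, -0.09, -0.11)
  same <- compare_slope_sets(x, x)
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)

  deg <- compare_slope_sets(c(0, 0, 0), c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)

  withr::local_seed(62)
  a <- rnorm(15, -0.11, 0.05); b <- rnorm(20, -0.16, 0.08)
  res <- compare_slope_sets(a, b, labels = c("brain", "liver"))
  expect_equal(res$p_value, welch_p_oracle(a, b), tolerance = 1e-9)
  expect_identical(res$contrast, "brain vs liver")
  expect_error(compare_slope_sets(1, c(1, 2)), "at least 2")
})

test_that("ANOVA omnibus matches a sums-of-squares oracle", {
  withr::local_seed(63)
  groups <- list(brain = rnorm(8, 0.6, 0.1), liver = rnorm(8, 0.4, 0.1),
                 kidney = rnorm(8, 0.45, 0.1))
  res <- compare_ratio_groups(groups, posthoc = "bonferroni")

  vals <- unlist(groups); k <- length(groups); n <- length(vals)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - mean(vals))^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1)))
  f_oracle <- (ss_between / (k - 1)) / (ss_within / (n - k))
  expect_equal(res$omnibus$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$omnibus$p_value,
               stats::pf(f_oracle, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)

  # Bonferroni definition and ordering vs raw p
  expect_equal(res$contrasts$adjusted_p,
               pmin(1, res$contrasts$p_value * nrow(res$contrasts)))
  expect_true(all(res$contrasts$adjusted_p >= res$contrasts$p_value))
})

test_that("identical groups give omnibus p = 1", {
  g <- list(a = c(0.5, 0.5, 0.5), b = c(0.5, 0.5, 0.5))
  res <- compare_ratio_groups(g)
  expect_equal(res$omnibus$p_value, 1)
  expect_error(compare_ratio_groups(list(a = 1:3)), "2 groups")
})

test_that("Tukey is no more conservative than Bonferroni when balanced", {
  withr::local_seed(64)
  groups <- list(a = rnorm(10, 0.5, 0.1), b = rnorm(10, 0.55, 0.1),
                 c = rnorm(10, 0.7, 0.1), d = rnorm(10, 0.52, 0.1))
  bon <- compare_ratio_groups(groups, "bonferroni")$contrasts
  tuk <- compare_ratio_groups(groups, "tukey")$contrasts
  m <- merge(bon, tuk, by = "contrast")
  expect_true(all(m$adjusted_p.y <= m$adjusted_p.x + 1e-10))
})

test_that("age volcano: fold changes, Welch p, skipping", {
  reps <- function(g, v) tibble::tibble(group_id = g, ratio = v)
  same <- age_volcano(reps("P1", c(0.5, 0.6, 0.55)),
                      reps("P1", c(0.5, 0.6, 0.55)))
  expect_equal(same$log2_fc, 0)

  doubled <- age_volcano(reps("P1", c(0.4, 0.4, 0.4)),
                         reps("P1", c(0.8, 0.8, 0.8)))
  expect_equal(doubled$log2_fc, 1)
  expect_false(is.na(doubled$p_value))

  withr::local_seed(65)
  y <- c(0.42, 0.39, 0.45); o <- c(0.61, 0.52, 0.75)
  res <- age_volcano(reps("P1", y), reps("P1", o))
  expect_equal(res$p_value, welch_p_oracle(o, y), tolerance = 1e-9)
  expect_identical(res$significant, res$p_value < 0.05)

  both <- dplyr::bind_rows(reps("P1", c(0.4, 0.5, 0.45)),
                           reps("P2", c(-0.1, -0.2, 0)))
  expect_warning(out <- age_volcano(both, both), "non-positive")
  expect_identical(out$group_id, "P1")
})

test_that("complex homogeneity fraction and its invariances", {
  labels <- c(A = "stable", B = "stable", C = "unstable", D = "unstable")
  cx <- list(c1 = c("A", "B"), c2 = c("C", "D"), c3 = c("A", "C"))
  res <- complex_homogeneity(labels, cx)
  expect_equal(res$fraction, 2 / 3)
  expect_identical(res$n_evaluated, 3L)

  # invariant under a global stable/unstable swap
  swapped <- ifelse(labels == "stable", "unstable", "stable")
  names(swapped) <- names(labels)
  expect_equal(complex_homogeneity(swapped, cx)$fraction, 2 / 3)

  # all homogeneous
  expect_equal(complex_homogeneity(labels,
                                   list(c("A", "B"), c("C", "D")))$fraction,
               1)

  # a complex with < 2 labelled members leaves the denominator
  res2 <- complex_homogeneity(labels, list(c1 = c("A", "Zunknown"),
                                           c2 = c("A", "C")))
  expect_identical(res2$n_evaluated, 1L)
  expect_error(complex_homogeneity(labels, list()), "empty")
})

test_that("redundant complexes collapse when read from the toy fixture", {
  path <- system.file("extdata", "toy_complexes.tsv", package = "quadpipe")
  cx <- read_complex_table(path)
  expect_identical(nrow(cx), 5L)
  labels <- c(P00001 = "stable", P00002 = "stable",
              P00003 = "unstable", P00004 = "unstable")
  res <- complex_homogeneity(labels, cx)
  # CPX3 and CPX3b are redundant; CPX4 has one labelled member
  expect_identical(res$n_evaluated, 3L)
  expect_equal(res$fraction, 2 / 3)
})

test_that("replicate correlation matrix matches the covariance oracle", {
  withr::local_seed(66)
  n <- 30
  prot <- sprintf("P%03d", 1:n)
  base <- rnorm(n)
  exps <- list(
    e1 = setNames(base + rnorm(n, 0, 0.2), prot),
    e2 = setNames(base + rnorm(n, 0, 0.2), prot),
    e3 = setNames(rnorm(n), prot)
  )
  r <- replicate_correlation_matrix(exps)
  expect_identical(dim(r), c(3L, 3L))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  manual <- sum((exps$e1 - mean(exps$e1)) * (exps$e2 - mean(exps$e2))) /
    sqrt(sum((exps$e1 - mean(exps$e1))^2) *
           sum((exps$e2 - mean(exps$e2))^2))
  expect_equal(r["e1", "e2"], manual, tolerance = 1e-12)

  # duplicated and negated experiments
  r2 <- replicate_correlation_matrix(list(a = exps$e1, b = exps$e1,
                                          c = setNames(-exps$e1, prot)))
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)

  # pairs sharing < 3 proteins are reported missing
  sparse <- list(
    x = setNames(rnorm(5), prot[1:5]),
    y = setNames(rnorm(5), prot[4:8])
  )
  expect_true(is.na(replicate_correlation_matrix(sparse)["x", "y"]))
  expect_error(replicate_correlation_matrix(exps["e1"]), "2 experiments")
})

test_that("property correlation: identity, sign, null behaviour", {
  withr::local_seed(67)
  prot <- sprintf("P%03d", 1:1000)
  slopes <- setNames(rnorm(1000, -0.12, 0.05), prot)

  perfect <- property_correlation(slopes, slopes)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_identical(perfect$n, 1000L)

  neg <- property_correlation(slopes,
                              setNames(-slopes + rnorm(1000, 0, 0.02), prot))
  expect_lt(neg$r, 0)

  null <- property_correlation(slopes, setNames(rnorm(1000), prot))
  expect_lt(abs(null$r), 0.1)

  flat <- property_correlation(slopes[1:5], setNames(rep(1, 5), prot[1:5]))
  expect_identical(flat$flag, "zero_variance")
  expect_error(property_correlation(slopes[1:2],
                                    setNames(1:2, prot[1:2])),
               "at least 3")
})
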