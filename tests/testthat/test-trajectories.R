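# Protein ratios, PST construction, kinetic fits.

ratio_row <- function(group, rep, day, ratio, tissue = "brain", n = 3L) {
  tibble::tibble(group_id = group, tissue = tissue, replicate = rep,
                 chase_day = day, median_ratio = ratio, n_peptides = n)
}

test_that("protein ratios are peptide medians with midpoint convention", {
  rec <- tibble::tibble(
    peptide = sprintf("x%dM*K", 1:5),
    proteins = c("P1", "P1", "P1", "P2", "P2"),
    group_id = c("P1", "P1", "P1", "P2", "P2"),
    tissue = "brain", replicate = "mouse1", chase_day = 3L,
    heavy_intensity = 1, light_intensity = 2,
    ratio_hl = c(0.5, 0.7, 0.9, 0.4, 0.8),
    quality = 0.01
  )
  out <- compute_protein_ratios(rec)
  expect_equal(out$median_ratio[out$group_id == "P1"], 0.7)
  expect_equal(out$n_peptides[out$group_id == "P1"], 3L)
  expect_equal(out$median_ratio[out$group_id == "P2"], 0.6)
})

test_that("median equals the sort-and-pick oracle on random ratios", {
  withr::local_seed(31)
  for (n in c(1, 2, 5, 100)) {
    r <- stats::rlnorm(n, -0.5, 0.4)
    rec <- tibble::tibble(
      peptide = sprintf("x%dM*K", seq_len(n)), proteins = "P1",
      group_id = "P1", tissue = "brain", replicate = "mouse1",
      chase_day = 7L, heavy_intensity = 1, light_intensity = 2,
      ratio_hl = r, quality = 0.01
    )
    s <- sort(r)
    oracle <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(compute_protein_ratios(rec)$median_ratio, oracle)
  }
})

test_that("non-positive ratios are excluded with a warning", {
  rec <- tibble::tibble(
    peptide = c("aM*K", "bM*K"), proteins = "P1", group_id = "P1",
    tissue = "brain", replicate = "mouse1", chase_day = 3L,
    heavy_intensity = 1, light_intensity = 2, ratio_hl = c(0.5, -1),
    quality = 0.01
  )
  expect_warning(out <- compute_protein_ratios(rec), "1 record")
  expect_equal(out$n_peptides, 1L)
  # median always lies within the contributing peptide ratios
  expect_equal(out$median_ratio, 0.5)
})

test_that("completeness rule excludes proteins missing a required day", {
  ratios <- dplyr::bind_rows(
    ratio_row("G1", "mouse1", 3L, 0.7), ratio_row("G1", "mouse1", 7L, 0.5),
    ratio_row("G1", "mouse1", 14L, 0.3),
    ratio_row("G2", "mouse1", 3L, 0.7), ratio_row("G2", "mouse1", 7L, 0.5)
  )
  pst <- build_psts(ratios, required_days = c(0, 3, 7, 14),
                    mode = "per_replicate")
  expect_setequal(unique(pst$group_id), "G1")
  expect_error(build_psts(ratios, required_days = numeric(0)),
               "required_days", class = "quadpipe_config_error")
})

test_that("averaged mode means ratios across mice before the log", {
  ratios <- dplyr::bind_rows(
    ratio_row("G1", "mouse1", 3L, 0.6), ratio_row("G1", "mouse2", 3L, 0.8),
    ratio_row("G1", "mouse1", 7L, 0.5), ratio_row("G1", "mouse2", 7L, 0.5),
    ratio_row("G1", "mouse1", 14L, 0.3), ratio_row("G1", "mouse2", 14L, 0.3)
  )
  pst <- build_psts(ratios, required_days = c(3, 7, 14), mode = "averaged")
  d3 <- pst$ln_ratio[pst$chase_day == 3]
  expect_equal(d3, log(0.7), tolerance = 1e-12)
  expect_equal(round(d3, 4), -0.3567)

  # mean-then-ln dominates ln-then-mean (Jensen) and must differ on
  # unequal replicates
  ln_then_mean <- mean(log(c(0.6, 0.8)))
  expect_gt(d3, ln_then_mean)
  # day 0 anchor present at exactly zero
  expect_equal(pst$ln_ratio[pst$chase_day == 0], 0)
})

test_that("unit ratios give an identically-zero trajectory", {
  ratios <- dplyr::bind_rows(lapply(c(0L, 3L, 7L, 14L), function(d) {
    ratio_row("G1", "mouse1", d, 1.0)
  }))
  pst <- build_psts(ratios, required_days = c(0, 3, 7, 14),
                    mode = "per_replicate")
  expect_true(all(pst$ln_ratio == 0))
})

test_that("day-0 anchor is a switch: unanchored fits use measured day 0", {
  ratios <- dplyr::bind_rows(
    ratio_row("G1", "mouse1", 0L, 0.9),
    ratio_row("G1", "mouse1", 3L, 0.7),
    ratio_row("G1", "mouse1", 7L, 0.5),
    ratio_row("G1", "mouse1", 14L, 0.3)
  )
  anchored <- build_psts(ratios, c(0, 3, 7, 14), mode = "per_replicate",
                         anchor_day0 = TRUE)
  free <- build_psts(ratios, c(0, 3, 7, 14), mode = "per_replicate",
                     anchor_day0 = FALSE)
  expect_equal(anchored$ln_ratio[anchored$chase_day == 0], 0)
  expect_equal(free$ln_ratio[free$chase_day == 0], log(0.9))
})

test_that("least squares on collinear points recovers the exact slope", {
  pst <- tibble::tibble(
    group_id = "G1", tissue = "brain", scope = "averaged",
    chase_day = c(0, 3, 7, 14), ln_ratio = c(0, -0.33, -0.77, -1.54)
  )
  fit <- fit_kinetics(pst)
  expect_equal(fit$slope, -0.11, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$lambda, 0.11, tolerance = 1e-12)
  expect_equal(fit$half_life_days, log(2) / 0.11, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("constant trajectories are stable with the infinite sentinel", {
  pst <- tibble::tibble(
    group_id = "G1", tissue = "brain", scope = "averaged",
    chase_day = c(0, 3, 7, 14), ln_ratio = rep(-0.2, 4)
  )
  fit <- fit_kinetics(pst)
  expect_equal(fit$slope, 0)
  expect_identical(fit$half_life_days, Inf)
  expect_true(fit$stable)
})

test_that("slope and intercept agree with the lm oracle", {
  withr::local_seed(32)
  pst <- make_psts(stats::rnorm(20, -0.12, 0.05), jitter_sd = 0.1)
  fit <- fit_kinetics(pst)
  for (g in fit$group_id) {
    sub <- pst[pst$group_id == g, ]
    ref <- stats::lm(ln_ratio ~ chase_day, data = sub)
    expect_equal(fit$slope[fit$group_id == g],
                 unname(stats::coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept[fit$group_id == g],
                 unname(stats::coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$r_squared[fit$group_id == g],
                 summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("half-life transform and sentinel conventions", {
  expect_equal(half_life_from_slope(-0.11), 6.3013, tolerance = 1e-4)
  expect_equal(half_life_from_slope(-0.6931), 1, tolerance = 1e-4)
  expect_identical(half_life_from_slope(0), Inf)
  expect_identical(half_life_from_slope(0.05), Inf)
  expect_error(half_life_from_slope(NaN), "NA/NaN")
  # lambda * half-life = ln 2 whenever the half-life is finite
  s <- -c(0.01, 0.11, 0.5, 2)
  expect_equal(half_life_from_slope(s) * (-s), rep(log(2), 4))
})

test_that("degenerate designs (a single repeated day) are rejected", {
  pst <- tibble::tibble(group_id = "G1", tissue = "brain",
                        scope = "averaged", chase_day = c(3, 3, 3),
                        ln_ratio = c(-0.1, -0.2, -0.3))
  expect_error(fit_kinetics(pst), "degenerate",
               class = "quadpipe_degenerate_error")
})

test_that("zero-noise synthetic proteins are recovered to machine precision", {
  cfg <- sim_config(n_proteins = 20, lambda_meanlog = log(0.11),
                    lambda_sdlog = 0.4, ratio_noise_sd = 0,
                    intensity_noise_sdlog = 0, detection_midpoint = -100,
                    biphasic_fraction = 0, seed = 33)
  sim <- generate_dataset(cfg)
  inf <- infer_protein_groups(sim$peptides)
  ratios <- compute_protein_ratios(inf$records)
  psts <- build_psts(ratios, c(0, 3, 7, 14), mode = "averaged")
  fits <- fit_kinetics(psts)
  merged <- merge(fits, sim$ground_truth,
                  by.x = "group_id", by.y = "protein_id")
  expect_equal(merged$slope, -merged$lambda_true, tolerance = 1e-10)
})
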