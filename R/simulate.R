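# Synthetic pulse-chase data generator.
#
# Emulates the post-acquisition shape of an AHA pulse-chase experiment:
# per-protein exponential (or biphasic) decay of the heavy-labelled pool
# against a fixed Day0 light internal standard, peptide-level lognormal
# ratio noise, lognormal protein abundances and peptide ionisation
# efficiencies, and an abundance-dependent logistic detection model.

#' Tissue presets for the simulator
#'
#' Mean per-day degradation slopes observed in mouse tissues: brain
#' trajectories decay on average at \eqn{-0.11} per day and liver at
#' \eqn{-0.16} per day. Used as `slope_mean` defaults by [sim_config()].
#'
#' @return Named list of lists with elements `slope_mean` and `slope_sd`.
#' @export
tissue_presets <- function() {
  list(
    brain = list(slope_mean = -0.11, slope_sd = 0.05),
    liver = list(slope_mean = -0.16, slope_sd = 0.05)
  )
}

#' Simulation configuration
#'
#' Build and validate the configuration for the synthetic pulse-chase
#' generator. Defaults describe a single-tissue experiment with three
#' biological replicates (mice), chase days 0/3/7/14, a mean of 8.3
#' quantified AHA peptides per protein, and brain-like decay rates.
#'
#' Per-protein true slopes are drawn as Normal(`slope_mean`, `slope_sd`)
#' and converted to degradation constants `lambda = max(0, -slope)`
#' (label cannot be gained during the chase). Alternatively set
#' `lambda_meanlog`/`lambda_sdlog` to draw `lambda` from a lognormal
#' distribution directly.
#'
#' @param n_proteins Number of simulated proteins.
#' @param tissue Tissue label; `"brain"` and `"liver"` carry slope presets.
#' @param slope_mean,slope_sd Mean and SD (per day) of true trajectory
#'   slopes; default from the tissue preset.
#' @param lambda_meanlog,lambda_sdlog Optional lognormal parameters for the
#'   degradation constant; when given they override the normal-slope draw.
#' @param peptides_per_protein_mean Mean quantified peptides per protein
#'   (shifted Poisson, minimum 1).
#' @param ratio_noise_sd SD of the multiplicative lognormal noise applied
#'   to each peptide heavy/light ratio (natural-log scale).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of protein
#'   abundance (arbitrary intensity units).
#' @param ionization_sdlog Lognormal SD of the per-peptide ionisation
#'   efficiency factor.
#' @param intensity_noise_sdlog Lognormal SD of per-measurement intensity
#'   noise (applied per channel).
#' @param detection_midpoint,detection_steepness Logistic detection model:
#'   a channel is identified with probability
#'   `plogis(detection_steepness * (log10(intensity) - detection_midpoint))`.
#'   Midpoint is in log10 intensity units; steepness is per decade and must
#'   be positive. A very low midpoint (e.g. `-100`) gives certain detection.
#' @param chase_days Ordered integer chase days; must start at 0 and be
#'   strictly increasing.
#' @param n_replicates Number of biological replicates (mice).
#' @param biphasic_fraction Proportion of proteins with two-phase decay.
#' @param biphasic_breakpoint Chase day at which biphasic proteins switch
#'   to their late rate.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output tables.
#'
#' @return An object of class `quad_sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 200,
                       tissue = "brain",
                       slope_mean = NULL,
                       slope_sd = NULL,
                       lambda_meanlog = NULL,
                       lambda_sdlog = NULL,
                       peptides_per_protein_mean = 8.3,
                       ratio_noise_sd = 0.2,
                       abundance_meanlog = log(1e6),
                       abundance_sdlog = 1.2,
                       ionization_sdlog = 0.8,
                       intensity_noise_sdlog = 0.1,
                       detection_midpoint = 4,
                       detection_steepness = 1.5,
                       chase_days = c(0L, 3L, 7L, 14L),
                       n_replicates = 3,
                       biphasic_fraction = 0.1,
                       biphasic_breakpoint = 7,
                       seed = 1L) {
  preset <- tissue_presets()[[tissue]]
  if (is.null(slope_mean)) {
    slope_mean <- if (is.null(preset)) -0.11 else preset$slope_mean
  }
  if (is.null(slope_sd)) {
    slope_sd <- if (is.null(preset)) 0.05 else preset$slope_sd
  }

  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins"),
    tissue = tissue,
    slope_mean = check_scalar_number(slope_mean, "slope_mean"),
    slope_sd = check_scalar_number(slope_sd, "slope_sd", lower = 0),
    lambda_meanlog = lambda_meanlog,
    lambda_sdlog = lambda_sdlog,
    peptides_per_protein_mean =
      check_scalar_number(peptides_per_protein_mean,
                          "peptides_per_protein_mean", lower = 1),
    ratio_noise_sd = check_scalar_number(ratio_noise_sd, "ratio_noise_sd",
                                         lower = 0),
    abundance_meanlog = check_scalar_number(abundance_meanlog,
                                            "abundance_meanlog"),
    abundance_sdlog = check_scalar_number(abundance_sdlog,
                                          "abundance_sdlog", lower = 0),
    ionization_sdlog = check_scalar_number(ionization_sdlog,
                                           "ionization_sdlog", lower = 0),
    intensity_noise_sdlog = check_scalar_number(intensity_noise_sdlog,
                                                "intensity_noise_sdlog",
                                                lower = 0),
    detection_midpoint = check_scalar_number(detection_midpoint,
                                             "detection_midpoint"),
    detection_steepness = check_scalar_number(detection_steepness,
                                              "detection_steepness",
                                              lower = 1e-12),
    chase_days = chase_days,
    n_replicates = check_count(n_replicates, "n_replicates"),
    biphasic_fraction = check_scalar_number(biphasic_fraction,
                                            "biphasic_fraction",
                                            lower = 0, upper = 1),
    biphasic_breakpoint = check_scalar_number(biphasic_breakpoint,
                                              "biphasic_breakpoint",
                                              lower = 0),
    seed = check_count(seed, "seed", min = 0L)
  )

  if (!is.character(tissue) || length(tissue) != 1L || is.na(tissue)) {
    qp_config_error("tissue", "must be a single label")
  }
  if (!is.numeric(chase_days) || length(chase_days) < 1L ||
      anyNA(chase_days)) {
    qp_config_error("chase_days", "must be a numeric vector")
  }
  if (chase_days[1L] != 0) {
    qp_config_error("chase_days", "must start at day 0")
  }
  if (length(chase_days) > 1L && any(diff(chase_days) <= 0)) {
    qp_config_error("chase_days", "must be strictly increasing")
  }
  cfg$chase_days <- as.integer(chase_days)
  if (!is.null(lambda_meanlog) || !is.null(lambda_sdlog)) {
    check_scalar_number(lambda_meanlog, "lambda_meanlog")
    check_scalar_number(lambda_sdlog, "lambda_sdlog", lower = 0)
  }

  structure(cfg, class = "quad_sim_config")
}

# Deterministic AHA peptide sequences for proteins i, peptides j (equal
# length vectors). Encodes the pair in amino-acid letters so sequences
# are unique, and carries one "M*" AHA site marker plus a tryptic-like
# C-terminal K.
make_peptide_seqs <- function(i, j) {
  alphabet <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1L]]
  n <- length(alphabet)
  code <- (as.numeric(i) - 1) * 100000 + (as.numeric(j) - 1)
  out <- matrix("", nrow = length(code), ncol = 6L)
  for (d in 6:1) {
    out[, d] <- alphabet[(code %% n) + 1L]
    code <- code %/% n
  }
  paste0(apply(out, 1L, paste0, collapse = ""), "M*K")
}

detection_prob <- function(intensity, cfg) {
  plogis(cfg$detection_steepness *
           (log10(pmax(intensity, .Machine$double.xmin)) -
              cfg$detection_midpoint))
}

# Cumulative log-decay at day t for rate lambda (early), optional late
# rate after the breakpoint.
log_decay <- function(t, lambda, lambda_late = NA_real_, breakpoint = Inf) {
  early <- pmin(t, breakpoint)
  late <- pmax(t - breakpoint, 0)
  ll <- ifelse(is.na(lambda_late), lambda, lambda_late)
  -(lambda * early + ll * late)
}

#' Generate a synthetic pulse-chase peptide quantification table
#'
#' Simulates an AHA pulse-chase experiment under a known ground truth:
#' each protein decays exponentially at its own rate `lambda` (a subset
#' biphasically), every quantified peptide of the protein carries the
#' protein's heavy/light ratio `exp(-lambda * t)` times multiplicative
#' lognormal noise, intensities derive from lognormal protein abundances
#' and peptide ionisation factors, and a peptide row is emitted only when
#' it passes the abundance-dependent logistic detection model (heavy
#' channel for chase days, both channels at the Day0 baseline).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `quad_sim` with elements `peptides` (tibble in
#'   the peptide TSV dialect, see [read_peptide_table()]) and
#'   `ground_truth` (tibble with `protein_id`, `lambda_true`,
#'   `decay_class`, `lambda_late`, `breakpoint_day`, `n_peptides`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "quad_sim_config"))
  cfg <- config

  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    protein_id <- sprintf("P%05d", seq_len(n))

    if (!is.null(cfg$lambda_meanlog)) {
      lambda <- rlnorm(n, cfg$lambda_meanlog, cfg$lambda_sdlog)
      slope_true <- -lambda
    } else {
      slope_true <- rnorm(n, cfg$slope_mean, cfg$slope_sd)
      lambda <- pmax(-slope_true, 0)
    }

    biphasic <- runif(n) < cfg$biphasic_fraction
    lambda_late <- ifelse(biphasic, lambda * runif(n, 0.1, 0.5), NA_real_)
    breakpoint_day <- ifelse(biphasic, cfg$biphasic_breakpoint, NA_real_)

    n_pep <- 1L + rpois(n, max(cfg$peptides_per_protein_mean - 1, 0))
    abundance <- rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)

    ground_truth <- tibble::tibble(
      protein_id = protein_id,
      lambda_true = lambda,
      decay_class = ifelse(biphasic, "biphasic", "exponential"),
      lambda_late = lambda_late,
      breakpoint_day = breakpoint_day,
      n_peptides = n_pep
    )

    # one row per peptide, then cross with replicates x chase days
    p_idx <- rep.int(seq_len(n), n_pep)
    pep_j <- sequence(n_pep)
    pep_seq <- make_peptide_seqs(p_idx, pep_j)
    ionization <- rlnorm(length(p_idx), 0, cfg$ionization_sdlog)

    n_pep_total <- length(p_idx)
    reps <- seq_len(cfg$n_replicates)
    days <- cfg$chase_days
    n_obs <- n_pep_total * length(reps) * length(days)

    obs <- tibble::tibble(
      pep = rep(seq_len(n_pep_total), times = length(reps) * length(days)),
      replicate_i = rep(rep(reps, each = n_pep_total), times = length(days)),
      chase_day = rep(days, each = n_pep_total * length(reps))
    )

    prot <- p_idx[obs$pep]
    true_lnr <- log_decay(obs$chase_day, lambda[prot],
                          lambda_late[prot],
                          ifelse(biphasic[prot], cfg$biphasic_breakpoint,
                                 Inf))
    eps <- rlnorm(n_obs, 0, cfg$ratio_noise_sd)
    ratio_hl <- exp(true_lnr) * eps

    light <- abundance[prot] * ionization[obs$pep] *
      rlnorm(n_obs, 0, cfg$intensity_noise_sdlog)
    heavy <- light * ratio_hl
    quality <- rbeta(n_obs, 1, 15)

    p_heavy <- detection_prob(heavy, cfg)
    p_light <- detection_prob(light, cfg)
    det_heavy <- rbinom(n_obs, 1L, p_heavy) == 1L
    det_light <- rbinom(n_obs, 1L, p_light) == 1L
    keep <- ifelse(obs$chase_day > 0, det_heavy, det_heavy & det_light)

    peptides <- tibble::tibble(
      peptide = pep_seq[obs$pep],
      proteins = protein_id[prot],
      tissue = cfg$tissue,
      replicate = sprintf("mouse%d", obs$replicate_i),
      chase_day = as.integer(obs$chase_day),
      heavy_intensity = heavy,
      light_intensity = light,
      ratio_hl = ratio_hl,
      quality = quality
    )[keep, ]
    peptides <- dplyr::arrange(peptides, .data$proteins, .data$replicate,
                               .data$chase_day, .data$peptide)

    structure(list(peptides = peptides, ground_truth = ground_truth),
              class = "quad_sim")
  })
}

#' Simulate a Day0 heavy/light self-mix baseline
#'
#' Emulates the baseline measurement of a pulse-chase design: two aliquots
#' of the same Day0 sample, one tagged with the heavy and one with the
#' light biotin-alkyne, mixed 1:1. Each peptide has equal expected
#' abundance in both channels and each channel is identified
#' independently under the logistic detection model; with symmetric
#' channels about half of all identifications are expected to be heavy.
#'
#' @param config A [sim_config()] object (abundance, ionisation, noise and
#'   detection parameters are used; decay parameters are irrelevant at
#'   day 0).
#' @param n_peptides Optional exact total number of simulated peptides;
#'   overrides the protein-count-based total.
#' @param heavy_scale Multiplier on heavy-channel abundance (default 1,
#'   i.e. a true 1:1 mix); values below 1 bias identifications light.
#' @return Tibble of identifications with columns `peptide`, `proteins`,
#'   `tissue`, `replicate`, `chase_day` (0), `channel`
#'   (`"heavy"`/`"light"`) and `intensity`: one row per identified
#'   channel event.
#' @export
simulate_baseline_mix <- function(config, n_peptides = NULL,
                                  heavy_scale = 1) {
  stopifnot(inherits(config, "quad_sim_config"))
  cfg <- config
  check_scalar_number(heavy_scale, "heavy_scale", lower = 0)

  with_seed(cfg$seed, {
    if (is.null(n_peptides)) {
      n_pep <- 1L + rpois(cfg$n_proteins,
                          max(cfg$peptides_per_protein_mean - 1, 0))
    } else {
      n_peptides <- check_count(n_peptides, "n_peptides")
      # spread peptides over proteins at the configured mean
      n_prot <- max(1L, round(n_peptides / cfg$peptides_per_protein_mean))
      base <- n_peptides %/% n_prot
      n_pep <- rep.int(base, n_prot)
      extra <- n_peptides - base * n_prot
      if (extra > 0) n_pep[seq_len(extra)] <- n_pep[seq_len(extra)] + 1L
    }
    n_prot <- length(n_pep)
    protein_id <- sprintf("P%05d", seq_len(n_prot))
    abundance <- rlnorm(n_prot, cfg$abundance_meanlog, cfg$abundance_sdlog)

    p_idx <- rep.int(seq_len(n_prot), n_pep)
    pep_j <- sequence(n_pep)
    pep_seq <- make_peptide_seqs(p_idx, pep_j)
    ionization <- rlnorm(length(p_idx), 0, cfg$ionization_sdlog)
    base_int <- abundance[p_idx] * ionization

    m <- length(p_idx)
    heavy <- base_int * heavy_scale * rlnorm(m, 0, cfg$intensity_noise_sdlog)
    light <- base_int * rlnorm(m, 0, cfg$intensity_noise_sdlog)
    det_heavy <- rbinom(m, 1L, detection_prob(heavy, cfg)) == 1L
    det_light <- rbinom(m, 1L, detection_prob(light, cfg)) == 1L

    ids <- tibble::tibble(
      peptide = c(pep_seq[det_heavy], pep_seq[det_light]),
      proteins = c(protein_id[p_idx][det_heavy],
                   protein_id[p_idx][det_light]),
      tissue = cfg$tissue,
      replicate = "baseline",
      chase_day = 0L,
      channel = c(rep("heavy", sum(det_heavy)),
                  rep("light", sum(det_light))),
      intensity = c(heavy[det_heavy], light[det_light])
    )
    dplyr::arrange(ids, .data$proteins, .data$peptide, .data$channel)
  })
}

#' Write the simulator's ground-truth table
#'
#' @param ground_truth Tibble from [generate_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  readr::write_tsv(ground_truth, path)
  invisible(path)
}

#' @export
print.quad_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic pulse-chase dataset: %d proteins, %d peptide rows, days {%s}\n",
    nrow(x$ground_truth), nrow(x$peptides),
    paste(sort(unique(x$peptides$chase_day)), collapse = ", ")))
  invisible(x)
}
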