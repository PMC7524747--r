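# Run configuration and end-to-end orchestration: filter -> infer ->
# ratios -> PST -> fit -> cluster -> classify -> compare, with every
# intermediate written as TSV and a log carrying versions, seed and a
# config fingerprint.

#' Pipeline run configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. All
#' randomness (only the optional simulation stage is stochastic) flows
#' from `seed`; re-running an identical config on identical inputs
#' reproduces identical outputs.
#'
#' @param chase_days Chase days of the experiment.
#' @param required_days Days a protein must be quantified at to get a
#'   trajectory; must be a subset of `chase_days`.
#' @param quality_threshold Peptide quality cutoff (lower is better).
#' @param pst_mode Trajectory mode for the kinetics fit:
#'   `"averaged"` (replicate means, then ln) or `"per_replicate"`.
#' @param anchor_day0 Pin day 0 at ln ratio 0 (see [build_psts()]).
#' @param k_clusters Number of trajectory clusters per tissue.
#' @param stability_threshold Per-day slope threshold for the
#'   stable/unstable call.
#' @param posthoc Post-hoc adjustment for multi-group ratio contrasts.
#' @param seed Integer seed.
#' @param input_peptides Path to a peptide TSV, or `NULL` to simulate.
#' @param sim A [sim_config()] used when `input_peptides` is `NULL`.
#' @param out_dir Output directory for the run.
#' @return Object of class `quad_run_config`.
#' @export
quad_config <- function(chase_days = c(0, 3, 7, 14),
                        required_days = c(0, 3, 7, 14),
                        quality_threshold = 0.1,
                        pst_mode = c("averaged", "per_replicate"),
                        anchor_day0 = TRUE,
                        k_clusters = 6,
                        stability_threshold = -0.10,
                        posthoc = c("bonferroni", "tukey"),
                        seed = 1L,
                        input_peptides = NULL,
                        sim = NULL,
                        out_dir = tempfile("quad_run_")) {
  pst_mode <- match.arg(pst_mode)
  posthoc <- match.arg(posthoc)
  if (!all(required_days %in% chase_days)) {
    qp_config_error("required_days", "must be a subset of chase_days")
  }
  check_scalar_number(quality_threshold, "quality_threshold",
                      lower = 0, upper = 1)
  check_count(k_clusters, "k_clusters")
  check_scalar_number(stability_threshold, "stability_threshold")
  if (!is.logical(anchor_day0) || length(anchor_day0) != 1L ||
      is.na(anchor_day0)) {
    qp_config_error("anchor_day0", "must be TRUE or FALSE")
  }
  if (is.null(input_peptides) && is.null(sim)) {
    sim <- sim_config(chase_days = chase_days, seed = seed)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "quad_sim_config"))
  structure(list(
    chase_days = as.numeric(chase_days),
    required_days = as.numeric(required_days),
    quality_threshold = quality_threshold,
    pst_mode = pst_mode,
    anchor_day0 = anchor_day0,
    k_clusters = as.integer(k_clusters),
    stability_threshold = stability_threshold,
    posthoc = posthoc,
    seed = check_count(seed, "seed", min = 0L),
    input_peptides = input_peptides,
    sim = sim,
    out_dir = out_dir
  ), class = "quad_run_config")
}

#' Serialise / restore a run configuration
#'
#' YAML round trip: every field of [quad_config()] serialises losslessly.
#'
#' @param config A `quad_run_config`.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `quad_run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "quad_run_config"))
  lst <- unclass(config)
  lst$sim <- if (is.null(lst$sim)) NULL else unclass(lst$sim)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- if (is.null(lst$sim)) NULL else do.call(sim_config, lst$sim)
  do.call(quad_config, c(
    lst[setdiff(names(lst), "sim")],
    list(sim = sim)
  ))
}

stage <- function(log_path, name, expr) {
  cat(sprintf("stage: %s\n", name), file = log_path, append = TRUE)
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                         conditionMessage(e)),
                 class = "quadpipe_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a peptide table (read from
#' `config$input_peptides`, or simulated from `config$sim`): quality
#' filter, protein-group inference, median protein ratios, trajectory
#' construction, kinetic fits, per-tissue Ward clustering of
#' per-replicate trajectories, replicate-concordance filter,
#' stable/unstable classification, and (with two or more tissues) the
#' tissue slope contrast. Every intermediate table is written as TSV
#' under `config$out_dir` together with a log and a summary.
#'
#' @param config A [quad_config()] object.
#' @return List (invisible class `quad_run`) with the run directory and
#'   all in-memory results: `peptides`, `groups`, `ratios`, `psts`,
#'   `kinetics`, `clusters` (per tissue), `concordance` (per tissue),
#'   `tissue_contrast` (or `NULL`), `ground_truth` (simulated runs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "quad_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  cat(sprintf("quadpipe %s | R %s | seed %d | config hash %s\n",
              as.character(utils::packageVersion("quadpipe")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed,
              rlang::hash(unclass(config)[setdiff(names(config),
                                                  "out_dir")])),
      file = log_path)

  ground_truth <- NULL
  if (is.null(config$input_peptides)) {
    sim <- stage(log_path, "simulate", generate_dataset(config$sim))
    peptides <- sim$peptides
    ground_truth <- sim$ground_truth
    write_peptide_table(peptides,
                        file.path(config$out_dir, "peptides_raw.tsv"))
    write_ground_truth(ground_truth,
                       file.path(config$out_dir, "ground_truth.tsv"))
  } else {
    peptides <- stage(log_path, "read",
                      read_peptide_table(config$input_peptides))
  }
  if (!all(peptides$chase_day %in% config$chase_days)) {
    qp_input_error("peptide table contains chase days outside the configured set")
  }

  filtered <- stage(log_path, "filter",
                    apply_quality_filter(peptides, config$quality_threshold))
  write_peptide_table(filtered,
                      file.path(config$out_dir, "peptides_filtered.tsv"))

  inference <- stage(log_path, "infer", infer_protein_groups(filtered))
  write_protein_groups(inference$groups,
                       file.path(config$out_dir, "protein_groups.tsv"))

  ratios <- stage(log_path, "ratios",
                  compute_protein_ratios(inference$records))
  readr::write_tsv(ratios, file.path(config$out_dir, "protein_ratios.tsv"))

  psts <- stage(log_path, "pst",
                build_psts(ratios, config$required_days,
                           mode = config$pst_mode,
                           anchor_day0 = config$anchor_day0))
  write_pst_table(psts, file.path(config$out_dir, "psts.tsv"))

  kinetics <- stage(log_path, "fit", fit_kinetics(psts))
  readr::write_tsv(kinetics, file.path(config$out_dir, "kinetics.tsv"))

  # clustering runs on per-replicate trajectories, per tissue
  rep_psts <- stage(log_path, "pst_replicate",
                    build_psts(ratios, config$required_days,
                               mode = "per_replicate",
                               anchor_day0 = config$anchor_day0))
  tissues <- sort(unique(rep_psts$tissue))
  clusters <- list(); concordance <- list()
  for (ts in tissues) {
    sub <- rep_psts[rep_psts$tissue == ts, ]
    cl <- stage(log_path, paste0("cluster_", ts), {
      cl <- cluster_psts(sub, k = min(config$k_clusters, nrow(
        dplyr::distinct(sub, .data$group_id, .data$scope))))
      classify_stability(cl, config$stability_threshold)
    })
    cc <- stage(log_path, paste0("concordance_", ts),
                concordance_filter(cl))
    clusters[[ts]] <- cl
    concordance[[ts]] <- cc
    write_cluster_table(cl,
                        file.path(config$out_dir,
                                  sprintf("clusters_%s.tsv", ts)),
                        concordance = cc)
    readr::write_tsv(cl$summaries,
                     file.path(config$out_dir,
                               sprintf("cluster_summary_%s.tsv", ts)))
    if (!is.null(cl$tree)) {
      write_merge_tree(cl, file.path(config$out_dir,
                                     sprintf("merge_tree_%s.nwk", ts)))
    }
  }

  tissue_contrast <- NULL
  if (length(tissues) >= 2L) {
    two <- utils::combn(tissues, 2L)
    tissue_contrast <- dplyr::bind_rows(lapply(seq_len(ncol(two)), function(i) {
      a <- two[1L, i]; b <- two[2L, i]
      compare_slope_sets(kinetics$slope[kinetics$tissue == a],
                         kinetics$slope[kinetics$tissue == b],
                         labels = c(a, b))
    }))
    readr::write_tsv(tissue_contrast,
                     file.path(config$out_dir, "tissue_contrasts.tsv"))
  }

  summary_lines <- c(
    sprintf("peptide rows (raw/filtered): %d / %d",
            nrow(peptides), nrow(filtered)),
    sprintf("protein groups reported: %d", nrow(inference$groups)),
    sprintf("trajectories fitted (%s): %d", config$pst_mode,
            nrow(kinetics)),
    sprintf("mean slope per tissue: %s", paste(
      vapply(tissues, function(ts) {
        sprintf("%s %.4f", ts,
                mean(kinetics$slope[kinetics$tissue == ts]))
      }, character(1L)), collapse = ", ")),
    sprintf("median half-life (finite, days): %.2f",
            median(kinetics$half_life_days[
              is.finite(kinetics$half_life_days)]))
  )
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  cat("done\n", file = log_path, append = TRUE)

  invisible(structure(list(
    out_dir = config$out_dir,
    config = config,
    peptides = filtered,
    groups = inference$groups,
    ratios = ratios,
    psts = psts,
    kinetics = kinetics,
    clusters = clusters,
    concordance = concordance,
    tissue_contrast = tissue_contrast,
    ground_truth = ground_truth
  ), class = "quad_run"))
}

#' @export
print.quad_run <- function(x, ...) {
  cat("QUAD pipeline run:", x$out_dir, "\n")
  cat(readLines(file.path(x$out_dir, "summary.txt")), sep = "\n")
  invisible(x)
}
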