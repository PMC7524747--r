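# Protein stability trajectories (PSTs) and degradation kinetics.
#
# Peptide heavy/light ratios are aggregated to protein medians per
# (replicate, chase day); trajectories are the natural log of those
# medians over chase days; the degradation slope comes from ordinary
# least squares (y = mx + b), the rate constant is lambda = -slope and
# the half-life is ln(2)/lambda.

#' Median protein ratios per replicate and chase day
#'
#' Collapses peptide-level heavy/light ratios to one median ratio per
#' protein group, tissue, replicate and chase day. Even peptide counts
#' use the midpoint of the two central values. Records with missing or
#' non-positive ratios are excluded (a warning reports how many).
#'
#' @param records Tibble of peptide records annotated with `group_id`
#'   (see [infer_protein_groups()]); a `proteins` column is used as the
#'   group when `group_id` is absent.
#' @return Tibble with `group_id`, `tissue`, `replicate`, `chase_day`,
#'   `median_ratio`, `n_peptides`.
#' @export
compute_protein_ratios <- function(records) {
  if (!"group_id" %in% names(records)) {
    records <- dplyr::mutate(records, group_id = .data$proteins)
  }
  bad <- is.na(records$ratio_hl) | records$ratio_hl <= 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "excluded %d record(s) with missing or non-positive ratio", sum(bad)))
    records <- records[!bad, ]
  }
  records |>
    dplyr::group_by(.data$group_id, .data$tissue, .data$replicate,
                    .data$chase_day) |>
    dplyr::summarise(
      median_ratio = median(.data$ratio_hl),
      n_peptides = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group_id, .data$tissue, .data$replicate,
                   .data$chase_day)
}

#' Build protein stability trajectories
#'
#' Converts per-timepoint median protein ratios into natural-log
#' trajectories (PSTs). In `per_replicate` mode each biological replicate
#' yields its own trajectory; in `averaged` mode replicate median ratios
#' are first averaged arithmetically per chase day and the mean is then
#' log-transformed (mean-then-ln — the order matters under Jensen's
#' inequality and matches how averaged trajectories are defined for the
#' half-life regression). Proteins missing any required chase day in the
#' relevant scope are excluded (completeness rule).
#'
#' By default the day-0 point is anchored at `ln_ratio = 0`: the Day0
#' self-mix measures a ratio of 1 by construction, so the trajectory is
#' pinned there and `required_days` is effectively checked on chase days
#' only. With `anchor_day0 = FALSE`, day 0 enters only if measured (and is
#' then required when listed in `required_days`).
#'
#' @param ratios Tibble from [compute_protein_ratios()].
#' @param required_days Chase days a protein must be quantified at.
#' @param mode `"per_replicate"` or `"averaged"`.
#' @param anchor_day0 Pin the day-0 point at 0 (default `TRUE`).
#' @return Long tibble with `group_id`, `tissue`, `scope` (replicate
#'   label or `"averaged"`), `chase_day`, `ln_ratio`.
#' @export
build_psts <- function(ratios, required_days = c(0, 3, 7, 14),
                       mode = c("per_replicate", "averaged"),
                       anchor_day0 = TRUE) {
  mode <- match.arg(mode)
  if (length(required_days) == 0L || anyNA(required_days)) {
    qp_config_error("required_days", "must be a non-empty day set")
  }
  required_days <- sort(unique(as.numeric(required_days)))

  if (mode == "averaged") {
    ratios <- ratios |>
      dplyr::group_by(.data$group_id, .data$tissue, .data$chase_day) |>
      dplyr::summarise(median_ratio = mean(.data$median_ratio),
                       .groups = "drop") |>
      dplyr::mutate(scope = "averaged")
  } else {
    ratios <- dplyr::mutate(ratios, scope = .data$replicate)
  }

  if (anchor_day0) {
    needed <- setdiff(required_days, 0)
    ratios <- ratios[ratios$chase_day != 0, ]
  } else {
    needed <- required_days
  }
  ratios <- ratios[ratios$chase_day %in% required_days, ]

  pst <- ratios |>
    dplyr::group_by(.data$group_id, .data$tissue, .data$scope) |>
    dplyr::filter(all(needed %in% .data$chase_day)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      group_id = .data$group_id, tissue = .data$tissue,
      scope = .data$scope,
      chase_day = as.numeric(.data$chase_day),
      ln_ratio = log(.data$median_ratio)
    )

  if (anchor_day0 && nrow(pst) > 0L) {
    anchors <- pst |>
      dplyr::distinct(.data$group_id, .data$tissue, .data$scope) |>
      dplyr::mutate(chase_day = 0, ln_ratio = 0)
    pst <- dplyr::bind_rows(anchors, pst)
  }
  if (any(!is.finite(pst$ln_ratio))) {
    qp_input_error("non-finite ln ratio encountered while building PSTs")
  }
  dplyr::arrange(pst, .data$group_id, .data$tissue, .data$scope,
                 .data$chase_day)
}

#' Half-life from a degradation slope
#'
#' A trajectory slope `m` (per day, from the ln-ratio regression) implies
#' a degradation constant `lambda = -m` and a half-life of
#' `ln(2)/lambda` days. Non-negative slopes (no measurable decay, or
#' apparent accretion) map to an infinite half-life sentinel.
#'
#' @param slope_m Numeric vector of slopes (per day).
#' @return Numeric vector of half-lives in days (`Inf` where
#'   `slope_m >= 0`).
#' @export
half_life_from_slope <- function(slope_m) {
  if (any(is.nan(slope_m)) || anyNA(slope_m)) {
    qp_input_error("slope must not be NA/NaN")
  }
  ifelse(slope_m < 0, log(2) / (-slope_m), Inf)
}

#' Fit degradation kinetics to trajectories
#'
#' Ordinary least squares of `ln_ratio` on `chase_day` (y = mx + b) for
#' each trajectory. Reports the slope `m` (per day), intercept,
#' degradation constant `lambda = -m`, half-life `ln(2)/lambda` (infinite
#' sentinel with a `"stable"` flag when `lambda <= 0`), coefficient of
#' determination and point count. Trajectories need at least two distinct
#' chase days; a single repeated day is a degenerate design.
#'
#' @param psts Long PST tibble from [build_psts()].
#' @return Tibble with one row per (`group_id`, `tissue`, `scope`):
#'   `slope`, `intercept`, `lambda`, `half_life_days`, `stable`,
#'   `r_squared`, `n_points`.
#' @export
fit_kinetics <- function(psts) {
  if (nrow(psts) == 0L) {
    qp_input_error("no trajectories to fit")
  }
  fits <- psts |>
    dplyr::group_by(.data$group_id, .data$tissue, .data$scope) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      n_days = dplyr::n_distinct(.data$chase_day),
      xbar = mean(.data$chase_day),
      ybar = mean(.data$ln_ratio),
      sxx = sum((.data$chase_day - mean(.data$chase_day))^2),
      sxy = sum((.data$chase_day - mean(.data$chase_day)) *
                  (.data$ln_ratio - mean(.data$ln_ratio))),
      syy = sum((.data$ln_ratio - mean(.data$ln_ratio))^2),
      .groups = "drop"
    )
  if (any(fits$n_days < 2L)) {
    qp_input_error(sprintf(
      "degenerate design: trajectory with < 2 distinct chase days (%s)",
      paste(utils::head(fits$group_id[fits$n_days < 2L], 5L),
            collapse = ", ")),
      class = "quadpipe_degenerate_error")
  }
  slope <- fits$sxy / fits$sxx
  intercept <- fits$ybar - slope * fits$xbar
  ss_res <- fits$syy - slope * fits$sxy
  r_squared <- ifelse(fits$syy > 0, 1 - ss_res / fits$syy, NA_real_)
  lambda <- -slope
  tibble::tibble(
    group_id = fits$group_id,
    tissue = fits$tissue,
    scope = fits$scope,
    slope = slope,
    intercept = intercept,
    lambda = lambda,
    half_life_days = half_life_from_slope(slope),
    stable = slope >= 0,
    r_squared = pmin(pmax(r_squared, 0), 1),
    n_points = fits$n_points
  )
}

#' Write trajectories in wide (one column per chase day) form
#'
#' @param psts Long PST tibble from [build_psts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pst_table <- function(psts, path) {
  wide <- psts |>
    dplyr::mutate(chase_day = sprintf("day%g", .data$chase_day)) |>
    tidyr::pivot_wider(names_from = "chase_day", values_from = "ln_ratio")
  readr::write_tsv(wide, path)
  invisible(path)
}
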