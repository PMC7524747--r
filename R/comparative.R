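# Comparison layers: heavy-identification fractions, tissue and age
# contrasts, protein-complex co-stability, and correlation analyses.

#' Percentage of heavy identifications
#'
#' `100 * n_heavy / (n_heavy + n_light)`; the fraction of all AHA peptide
#' identifications (light plus heavy) that are heavy. `NA` where the
#' total is zero.
#'
#' @param n_heavy,n_light Non-negative counts (vectorised).
#' @return Numeric percentage(s) in `[0, 100]`.
#' @export
heavy_id_fraction <- function(n_heavy, n_light) {
  if (any(n_heavy < 0, na.rm = TRUE) || any(n_light < 0, na.rm = TRUE)) {
    qp_input_error("identification counts must be non-negative")
  }
  total <- n_heavy + n_light
  ifelse(total > 0, 100 * n_heavy / total, NA_real_)
}

#' Count heavy/light identifications in a baseline mix table
#'
#' @param baseline Tibble from [simulate_baseline_mix()] (or any table
#'   with `tissue`, `replicate`, `chase_day`, `channel`).
#' @return Tibble with `tissue`, `replicate`, `chase_day`, `n_heavy`,
#'   `n_light`, `heavy_pct`.
#' @export
count_identifications <- function(baseline) {
  baseline |>
    dplyr::group_by(.data$tissue, .data$replicate, .data$chase_day) |>
    dplyr::summarise(
      n_heavy = sum(.data$channel == "heavy"),
      n_light = sum(.data$channel == "light"),
      .groups = "drop"
    ) |>
    dplyr::mutate(heavy_pct = heavy_id_fraction(.data$n_heavy,
                                                .data$n_light))
}

#' Compare two sets of trajectory slopes
#'
#' Two-tailed t-test between slope sets (e.g. brain vs liver), Welch by
#' default. Zero-variance degenerate inputs are flagged: equal constant
#' sets give p = 1, distinct constant sets p = 0.
#'
#' @param slopes_a,slopes_b Numeric vectors, each with at least 2 values.
#' @param labels Length-2 character vector naming the sets.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return One-row tibble: `contrast`, `mean_a`, `mean_b`, `estimate`
#'   (mean difference a - b), `p_value`, `method`, `degenerate`.
#' @export
compare_slope_sets <- function(slopes_a, slopes_b,
                               labels = c("a", "b"), var_equal = FALSE) {
  slopes_a <- slopes_a[!is.na(slopes_a)]
  slopes_b <- slopes_b[!is.na(slopes_b)]
  if (length(slopes_a) < 2L || length(slopes_b) < 2L) {
    qp_input_error("each slope set needs at least 2 values")
  }
  degenerate <- stats::var(slopes_a) < 1e-24 && stats::var(slopes_b) < 1e-24
  if (degenerate) {
    p <- if (isTRUE(all.equal(mean(slopes_a), mean(slopes_b)))) 1 else 0
  } else {
    p <- t.test(slopes_a, slopes_b, var.equal = var_equal)$p.value
  }
  tibble::tibble(
    contrast = paste(labels, collapse = " vs "),
    mean_a = mean(slopes_a),
    mean_b = mean(slopes_b),
    estimate = mean(slopes_a) - mean(slopes_b),
    p_value = p,
    method = if (var_equal) "student_t" else "welch_t",
    degenerate = degenerate
  )
}

#' One-way ANOVA across ratio groups with post-hoc contrasts
#'
#' Omnibus one-way ANOVA over named groups of per-protein mean ratios,
#' followed by all pairwise contrasts with either Bonferroni-adjusted
#' pooled-SD t-tests or Tukey's honest significant difference.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param posthoc `"bonferroni"` or `"tukey"`.
#' @return List with `omnibus` (tibble: `f_statistic`, `p_value`,
#'   `df_between`, `df_within`) and `contrasts` (tibble: `contrast`,
#'   `estimate`, `p_value`, `adjusted_p`, `method`).
#' @export
compare_ratio_groups <- function(groups, posthoc = c("bonferroni", "tukey")) {
  posthoc <- match.arg(posthoc)
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups))) {
    qp_input_error("`groups` must be a named list with at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1L)) < 2L)) {
    qp_input_error("every group needs at least 2 values")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  )
  if (stats::var(df$value) < 1e-24) {
    omnibus <- tibble::tibble(
      f_statistic = 0, p_value = 1,
      df_between = length(groups) - 1L,
      df_within = nrow(df) - length(groups))
    combs <- utils::combn(names(groups), 2L)
    contrasts <- tibble::tibble(
      contrast = paste(combs[2L, ], combs[1L, ], sep = "-"),
      estimate = 0, p_value = 1, adjusted_p = 1, method = posthoc)
    return(list(omnibus = omnibus, contrasts = contrasts))
  }

  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1L]]
  omnibus <- tibble::tibble(
    f_statistic = s[["F value"]][1L],
    p_value = s[["Pr(>F)"]][1L],
    df_between = s[["Df"]][1L],
    df_within = s[["Df"]][2L]
  )

  if (posthoc == "tukey") {
    tk <- TukeyHSD(fit)$group
    contrasts <- tibble::tibble(
      contrast = rownames(tk),
      estimate = tk[, "diff"],
      p_value = NA_real_,
      adjusted_p = tk[, "p adj"],
      method = "tukey"
    )
  } else {
    raw <- pairwise.t.test(df$value, df$group, p.adjust.method = "none",
                           pool.sd = TRUE)$p.value
    combs <- utils::combn(names(groups), 2L)
    pv <- vapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1L, i]; b <- combs[2L, i]
      if (!is.na(match(b, rownames(raw))) && !is.na(match(a, colnames(raw))) &&
          !is.na(raw[b, a])) raw[b, a] else raw[a, b]
    }, numeric(1L))
    est <- vapply(seq_len(ncol(combs)), function(i) {
      mean(groups[[combs[2L, i]]]) - mean(groups[[combs[1L, i]]])
    }, numeric(1L))
    contrasts <- tibble::tibble(
      contrast = paste(combs[2L, ], combs[1L, ], sep = "-"),
      estimate = est,
      p_value = pv,
      adjusted_p = pmin(1, pv * ncol(combs)),
      method = "bonferroni"
    )
  }
  list(omnibus = omnibus, contrasts = contrasts)
}

#' Per-protein age comparison (volcano table)
#'
#' For each protein quantified in both age groups, computes the log2
#' fold change of mean ratios (old over young) and a two-tailed Welch
#' t-test p-value across replicate means. Proteins with a non-positive
#' mean in either group are skipped with a warning. Significance is
#' flagged at raw p < 0.05; Benjamini-Hochberg adjusted p-values are
#' included as a column but not used for the flag unless requested.
#'
#' @param ratios_young,ratios_old Tibbles with `group_id` and `ratio`
#'   (one row per replicate; >= 2 replicates per protein per group).
#' @param alpha Significance level for the flag.
#' @param use_bh Flag significance on BH-adjusted p-values instead.
#' @return Tibble: `group_id`, `mean_young`, `mean_old`, `log2_fc`,
#'   `p_value`, `p_bh`, `significant`.
#' @export
age_volcano <- function(ratios_young, ratios_old, alpha = 0.05,
                        use_bh = FALSE) {
  shared <- intersect(unique(ratios_young$group_id),
                      unique(ratios_old$group_id))
  if (length(shared) == 0L) {
    qp_input_error("no proteins shared between age groups")
  }
  rows <- lapply(shared, function(g) {
    y <- ratios_young$ratio[ratios_young$group_id == g]
    o <- ratios_old$ratio[ratios_old$group_id == g]
    if (length(y) < 2L || length(o) < 2L) return(NULL)
    my <- mean(y); mo <- mean(o)
    if (!(my > 0) || !(mo > 0)) return("skipped")
    degenerate <- stats::var(y) < 1e-24 && stats::var(o) < 1e-24
    p <- if (degenerate) {
      if (isTRUE(all.equal(my, mo))) 1 else 0
    } else {
      t.test(o, y)$p.value
    }
    tibble::tibble(group_id = g, mean_young = my, mean_old = mo,
                   log2_fc = log2(mo / my), p_value = p)
  })
  skipped <- sum(vapply(rows, identical, logical(1L), "skipped"))
  if (skipped > 0) {
    rlang::warn(sprintf(
      "skipped %d protein(s) with non-positive mean ratio", skipped))
  }
  rows <- rows[vapply(rows, is.list, logical(1L))]
  if (length(rows) == 0L) {
    qp_input_error("no proteins with enough replicates in both age groups")
  }
  out <- dplyr::bind_rows(rows)
  out$p_bh <- p.adjust(out$p_value, method = "BH")
  out$significant <- if (use_bh) out$p_bh < alpha else out$p_value < alpha
  dplyr::arrange(out, .data$group_id)
}

#' Read a protein-complex membership table
#'
#' @param path TSV with columns `complex_id` and `members`
#'   (';'-delimited protein ids).
#' @return Tibble with `complex_id`, `members`.
#' @export
read_complex_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    complex_id = readr::col_character(),
    members = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(c("complex_id", "members"), names(tab))
  if (length(missing) > 0) {
    qp_input_error(sprintf("complex table is missing column(s): %s",
                           paste(missing, collapse = ", ")),
                   class = "quadpipe_format_error")
  }
  tab
}

#' Co-stability of protein complexes
#'
#' Restricts each complex to its members with a stability label, drops
#' complexes with fewer than two labelled members, collapses complexes
#' with identical labelled member sets (redundant), and calls a complex
#' homogeneous when all its labelled members share one class. Returns the
#' homogeneous fraction and a per-complex table. The fraction is
#' invariant under a global stable/unstable label swap.
#'
#' @param labels Named character vector: protein id -> `"stable"` or
#'   `"unstable"` (e.g. from [classify_stability()] assignments).
#' @param complexes Tibble with `complex_id` and `members`
#'   (';'-delimited), or a list of character vectors.
#' @return List with `fraction` (homogeneous complexes / evaluated
#'   complexes), `n_evaluated`, and `table` (per complex: `complex_id`,
#'   `n_labeled`, `classes`, `homogeneous`).
#' @export
complex_homogeneity <- function(labels, complexes) {
  if (is.data.frame(complexes)) {
    member_sets <- strsplit(complexes$members, ";", fixed = TRUE)
    ids <- complexes$complex_id
  } else {
    member_sets <- complexes
    ids <- names(complexes)
    if (is.null(ids)) ids <- sprintf("complex%d", seq_along(complexes))
  }
  if (length(member_sets) == 0L) {
    qp_input_error("complex list is empty")
  }
  labeled_sets <- lapply(member_sets, function(m) {
    sort(unique(intersect(m, names(labels))))
  })
  eval_idx <- which(lengths(labeled_sets) >= 2L)
  # drop redundant complexes (identical labelled member sets)
  keys <- vapply(labeled_sets[eval_idx], paste, character(1L),
                 collapse = ";")
  eval_idx <- eval_idx[!duplicated(keys)]

  verdict <- vapply(eval_idx, function(i) {
    length(unique(labels[labeled_sets[[i]]])) == 1L
  }, logical(1L))

  tab <- tibble::tibble(
    complex_id = ids[eval_idx],
    n_labeled = lengths(labeled_sets[eval_idx]),
    classes = vapply(eval_idx, function(i) {
      paste(sort(unique(labels[labeled_sets[[i]]])), collapse = "+")
    }, character(1L)),
    homogeneous = verdict
  )
  list(
    fraction = if (length(eval_idx) > 0) mean(verdict) else NA_real_,
    n_evaluated = length(eval_idx),
    table = tab
  )
}

#' Pairwise replicate correlation matrix
#'
#' Pearson correlation between every pair of experiments over the
#' proteins common to the pair (pairwise-complete log2 ratios). Cells
#' with fewer than 3 common proteins are reported missing; the diagonal
#' is 1.
#'
#' @param experiments Named list of named numeric vectors (protein ->
#'   log2 ratio), or a proteins-by-experiments matrix/data frame with
#'   row names.
#' @return Symmetric correlation matrix with experiment names.
#' @export
replicate_correlation_matrix <- function(experiments) {
  if (is.list(experiments) && !is.data.frame(experiments)) {
    proteins <- sort(unique(unlist(lapply(experiments, names))))
    mat <- sapply(experiments, function(e) e[proteins])
    rownames(mat) <- proteins
  } else {
    mat <- as.matrix(experiments)
  }
  if (ncol(mat) < 2L) {
    qp_input_error("need at least 2 experiments")
  }
  r <- cor(mat, use = "pairwise.complete.obs", method = "pearson")
  ok <- !is.na(mat)
  n_common <- t(ok * 1) %*% (ok * 1)
  r[n_common < 3L] <- NA_real_
  diag(r) <- 1
  r
}

#' Correlate trajectory slopes with a protein property
#'
#' Pearson correlation between per-protein slopes and an external
#' property (e.g. intrinsic disorder, molecular weight, abundance) over
#' the protein intersection.
#'
#' @param slopes Named numeric vector: protein -> slope.
#' @param property Named numeric vector: protein -> property value.
#' @return Tibble: `r`, `r_squared`, `p_value`, `n`, `flag` (`"ok"` or
#'   `"zero_variance"`).
#' @export
property_correlation <- function(slopes, property) {
  shared <- intersect(names(slopes), names(property))
  shared <- shared[!is.na(slopes[shared]) & !is.na(property[shared])]
  if (length(shared) < 3L) {
    qp_input_error("need at least 3 proteins common to both tables")
  }
  x <- slopes[shared]; y <- property[shared]
  if (stats::var(y) < 1e-24 || stats::var(x) < 1e-24) {
    return(tibble::tibble(r = NA_real_, r_squared = NA_real_,
                          p_value = NA_real_, n = length(shared),
                          flag = "zero_variance"))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    n = length(shared),
    flag = "ok"
  )
}
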