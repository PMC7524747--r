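# Independent oracles and small generators used across the suite.

# --- Ward clustering oracle -------------------------------------------------
# Greedy agglomeration minimising the increase in total within-cluster
# error sum of squares (ESS) at every merge, implemented directly from
# centroids. Ties broken by the lexicographically smallest pair of
# current cluster indices. Returns the label-invariant partition (integer
# membership vector) at each cluster count 1..n.
ward_oracle_partitions <- function(mat) {
  n <- nrow(mat)
  clusters <- lapply(seq_len(n), identity)
  partitions <- vector("list", n)
  partitions[[n]] <- seq_len(n)
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    centroid <- colMeans(mat[idx, , drop = FALSE])
    sum(sweep(mat[idx, , drop = FALSE], 2L, centroid)^2)
  }
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    best_cost <- Inf
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        cost <- ess(c(clusters[[a]], clusters[[b]])) -
          ess(clusters[[a]]) - ess(clusters[[b]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(a, b)
        }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
    labels <- integer(n)
    for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
    partitions[[length(clusters)]] <- labels
  }
  partitions
}

# Are two membership vectors the same partition (up to label renaming)?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b))) ||
    all(outer(a, a, "==") == outer(b, b, "=="))
}

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

# --- Parsimony oracle -------------------------------------------------------
# Applies the three reporting rules one at a time until none applies.
# Redundancy merging and subset removal are applied in a randomised
# order (they commute); the no-unique drop is evaluated only once the
# evidence redundancy is resolved, since a peptide shared solely with a
# redundant or subset protein still identifies its reported group.
# Returns a canonical representation: sorted list of sorted member
# vectors.
parsimony_oracle <- function(protein_peptides) {
  groups <- lapply(names(protein_peptides), function(p) {
    list(members = p, peptides = sort(unique(protein_peptides[[p]])))
  })
  repeat {
    applied <- FALSE
    merge_subset_active <- local({
      keys <- vapply(groups, function(g) paste(g$peptides, collapse = "\r"),
                     character(1L))
      has_dup <- anyDuplicated(keys) > 0L
      has_sub <- any(vapply(seq_along(groups), function(a) {
        any(vapply(seq_along(groups), function(b) {
          a != b &&
            length(groups[[a]]$peptides) < length(groups[[b]]$peptides) &&
            all(groups[[a]]$peptides %in% groups[[b]]$peptides)
        }, logical(1L)))
      }, logical(1L)))
      c(if (has_dup) "merge", if (has_sub) "subset")
    })
    rules <- if (length(merge_subset_active) > 0L) {
      sample(merge_subset_active)
    } else {
      "unique"
    }
    for (rule in rules) {
      if (rule == "merge" && length(groups) > 1L) {
        keys <- vapply(groups, function(g) paste(g$peptides, collapse = "\r"),
                       character(1L))
        if (anyDuplicated(keys)) {
          groups <- lapply(split(groups, keys), function(gs) {
            list(members = sort(unlist(lapply(gs, `[[`, "members"))),
                 peptides = gs[[1L]]$peptides)
          })
          groups <- unname(groups)
          applied <- TRUE
        }
      } else if (rule == "subset" && length(groups) > 1L) {
        drop <- rep(FALSE, length(groups))
        for (a in seq_along(groups)) {
          for (b in seq_along(groups)) {
            if (a != b &&
                length(groups[[a]]$peptides) < length(groups[[b]]$peptides) &&
                all(groups[[a]]$peptides %in% groups[[b]]$peptides)) {
              drop[a] <- TRUE
            }
          }
        }
        if (any(drop)) {
          groups <- groups[!drop]
          applied <- TRUE
        }
      } else if (rule == "unique" && length(groups) > 0L) {
        counts <- table(unlist(lapply(groups, `[[`, "peptides")))
        has_unique <- vapply(groups, function(g) {
          any(counts[g$peptides] == 1L)
        }, logical(1L))
        if (!all(has_unique)) {
          groups <- groups[has_unique]
          applied <- TRUE
        }
      }
      if (applied) break
    }
    if (!applied) break
  }
  members <- lapply(groups, `[[`, "members")
  members[order(vapply(members, `[`, character(1L), 1L))]
}

random_protein_peptide_map <- function(max_proteins = 10L,
                                       max_peptides = 15L) {
  n_prot <- sample(2:max_proteins, 1L)
  n_pep <- sample(3:max_peptides, 1L)
  peptides <- sprintf("pep%02dM*K", seq_len(n_pep))
  map <- lapply(seq_len(n_prot), function(i) {
    sort(sample(peptides, sample.int(n_pep, 1L)))
  })
  names(map) <- sprintf("PR%02d", seq_len(n_prot))
  map
}

# Peptide records for a protein->peptides map (one row per peptide,
# shared peptides carry all owners ';'-joined).
records_from_map <- function(map) {
  pep_owner <- list()
  for (p in names(map)) {
    for (pep in map[[p]]) pep_owner[[pep]] <- c(pep_owner[[pep]], p)
  }
  peps <- names(pep_owner)
  tibble::tibble(
    peptide = peps,
    proteins = vapply(pep_owner, paste, character(1L), collapse = ";"),
    tissue = "brain",
    replicate = "mouse1",
    chase_day = 3L,
    heavy_intensity = 1e5,
    light_intensity = 2e5,
    ratio_hl = 0.5,
    quality = 0.01
  )
}

# --- Trajectory helpers -----------------------------------------------------
# Exact (noise-free) long PST tibble for given slopes.
make_psts <- function(slopes, days = c(0, 3, 7, 14), scope = "averaged",
                      tissue = "brain", jitter_sd = 0,
                      ids = sprintf("G%03d", seq_along(slopes))) {
  dplyr::bind_rows(lapply(seq_along(slopes), function(i) {
    tibble::tibble(
      group_id = ids[i], tissue = tissue, scope = scope,
      chase_day = days,
      ln_ratio = slopes[i] * days +
        if (jitter_sd > 0) stats::rnorm(length(days), 0, jitter_sd) else 0
    )
  }))
}

# Welch t-test oracle from first principles.
welch_p_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}
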