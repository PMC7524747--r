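# Peptide quantification table IO, quality filtering, and parsimony
# protein-group inference.
#
# TSV dialect: UTF-8, tab-separated, '.' decimal, columns
#   peptide, proteins, tissue, replicate, chase_day,
#   heavy_intensity, light_intensity, ratio_hl, quality
# `proteins` is ';'-delimited for shared peptides.

#' Read a peptide quantification table
#'
#' Reads the tab-separated peptide dialect emitted by the upstream
#' heavy/light ratio quantification (and by [generate_dataset()]). Rows
#' with non-numeric intensities, non-positive ratios that cannot be
#' recomputed, or missing required fields are rejected with a warning
#' naming their row numbers. A missing `ratio_hl` is recomputed as
#' `heavy_intensity / light_intensity` when both intensities are present
#' and positive.
#'
#' @param path Path to a TSV file.
#' @return Tibble of peptide records, in file order. Rejected row numbers
#'   (if any) are attached as attribute `rejected_rows`.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) {
    qp_input_error(sprintf("peptide table not found: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  required <- peptide_table_columns()
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    qp_input_error(
      sprintf("peptide table is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      class = "quadpipe_format_error"
    )
  }
  raw <- raw[required]
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(
      peptide = character(), proteins = character(), tissue = character(),
      replicate = character(), chase_day = integer(),
      heavy_intensity = double(), light_intensity = double(),
      ratio_hl = double(), quality = double()
    )
    attr(out, "rejected_rows") <- integer()
    return(out)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    peptide = raw$peptide,
    proteins = raw$proteins,
    tissue = raw$tissue,
    replicate = raw$replicate,
    chase_day = suppressWarnings(as.integer(raw$chase_day)),
    heavy_intensity = num(raw$heavy_intensity),
    light_intensity = num(raw$light_intensity),
    ratio_hl = num(raw$ratio_hl),
    quality = num(raw$quality)
  )

  # derive missing ratios from intensities
  derivable <- is.na(out$ratio_hl) &
    !is.na(out$heavy_intensity) & !is.na(out$light_intensity) &
    out$heavy_intensity > 0 & out$light_intensity > 0
  out$ratio_hl[derivable] <-
    out$heavy_intensity[derivable] / out$light_intensity[derivable]

  bad <- is.na(out$peptide) | is.na(out$proteins) | out$proteins == "" |
    is.na(out$chase_day) |
    is.na(out$heavy_intensity) | out$heavy_intensity < 0 |
    is.na(out$light_intensity) | out$light_intensity < 0 |
    is.na(out$ratio_hl) | out$ratio_hl <= 0 |
    is.na(out$quality) | out$quality < 0 | out$quality > 1
  if (any(bad)) {
    rlang::warn(sprintf(
      "rejected %d malformed peptide row(s): %s", sum(bad),
      paste(utils::head(which(bad), 20L), collapse = ", ")))
  }
  res <- out[!bad, ]
  attr(res, "rejected_rows") <- which(bad)
  res
}

#' Write a peptide quantification table
#'
#' @param records Tibble of peptide records (see [read_peptide_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  cols <- peptide_table_columns()
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    qp_input_error(sprintf("records are missing column(s): %s",
                           paste(missing, collapse = ", ")))
  }
  readr::write_tsv(records[cols], path)
  invisible(path)
}

#' Filter peptide records on quantification quality
#'
#' Keeps records whose quality score (lower is better) is at or below the
#' threshold; the conventional cutoff for pQuant-style scores is 0.1,
#' boundary inclusive. Record order is preserved.
#'
#' @param records Tibble of peptide records.
#' @param threshold Quality threshold in `[0, 1]`.
#' @return Filtered tibble.
#' @export
apply_quality_filter <- function(records, threshold = 0.1) {
  check_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  records[!is.na(records$quality) & records$quality <= threshold, ]
}

# Core parsimony engine on a protein -> peptide-set map. Applies, to a
# fixed point, the three reporting rules: merge proteins with identical
# peptide evidence; drop groups whose peptide set is a proper subset of
# another retained group's; drop groups with no peptide unique to them
# among retained groups. Returns a list of groups, each
# list(members, peptides).
parsimony_groups <- function(protein_peptides) {
  if (length(protein_peptides) == 0L) return(list())
  protein_peptides <- lapply(protein_peptides,
                             function(p) sort(unique(p)))

  # rule 1: merge identical evidence
  keys <- vapply(protein_peptides, paste, character(1L), collapse = "\r")
  groups <- lapply(split(names(protein_peptides), keys), function(members) {
    list(members = sort(members),
         peptides = protein_peptides[[members[1L]]])
  })
  groups <- unname(groups)

  # rule 2: drop proper subsets (subset relation is static post-merge)
  n <- length(groups)
  is_subset <- rep(FALSE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b && !is_subset[b] &&
          length(groups[[a]]$peptides) < length(groups[[b]]$peptides) &&
          all(groups[[a]]$peptides %in% groups[[b]]$peptides)) {
        is_subset[a] <- TRUE
        break
      }
    }
  }
  groups <- groups[!is_subset]

  # rule 3: drop groups with no unique peptide; iterate, since removing a
  # group can make another group's shared peptides unique
  repeat {
    all_pep <- unlist(lapply(groups, `[[`, "peptides"))
    counts <- table(all_pep)
    has_unique <- vapply(groups, function(g) {
      any(counts[g$peptides] == 1L)
    }, logical(1L))
    if (all(has_unique) || length(groups) == 0L) break
    groups <- groups[has_unique]
  }

  # deterministic order and ids
  ids <- vapply(groups, function(g) g$members[1L], character(1L))
  groups[order(ids)]
}

#' Infer parsimonious protein groups from peptide evidence
#'
#' Applies the standard protein-reporting rules of shotgun proteomics:
#' proteins with identical peptide evidence are merged into one group
#' (redundant), groups whose peptide set is a proper subset of another
#' group's are dropped (their peptides are retained by the superset
#' group), and groups with no unique quantified peptide are dropped.
#' The rules are applied to a fixed point and the result is independent
#' of input order. Each reported group is identified by the
#' lexicographically smallest member protein id.
#'
#' @param records Tibble of peptide records; `proteins` may be
#'   ';'-delimited for shared peptides.
#' @return List with elements `groups` (tibble: `group_id`, `members`
#'   ';'-joined, `n_peptides`, `n_unique`) and `records` (input records
#'   annotated with `group_id`; a peptide matching several reported
#'   groups yields one annotated row per group).
#' @export
infer_protein_groups <- function(records) {
  if (nrow(records) == 0L) {
    return(list(
      groups = tibble::tibble(group_id = character(), members = character(),
                              n_peptides = integer(), n_unique = integer()),
      records = dplyr::mutate(records, group_id = character(0))
    ))
  }
  if (any(is.na(records$proteins) | records$proteins == "")) {
    qp_input_error("every peptide record must carry at least one protein id")
  }

  prot_list <- strsplit(records$proteins, ";", fixed = TRUE)
  long <- tibble::tibble(
    peptide = rep(records$peptide, lengths(prot_list)),
    protein = unlist(prot_list)
  )
  protein_peptides <- split(long$peptide, long$protein)

  groups <- parsimony_groups(protein_peptides)

  all_pep <- unlist(lapply(groups, `[[`, "peptides"))
  counts <- table(all_pep)
  group_tbl <- tibble::tibble(
    group_id = vapply(groups, function(g) g$members[1L], character(1L)),
    members = vapply(groups, function(g) paste(g$members, collapse = ";"),
                     character(1L)),
    n_peptides = vapply(groups, function(g) length(g$peptides), integer(1L)),
    n_unique = vapply(groups, function(g) sum(counts[g$peptides] == 1L),
                      integer(1L))
  )

  # peptide -> reported group ids
  pep2group <- lapply(groups, `[[`, "peptides")
  map <- tibble::tibble(
    peptide = as.character(unlist(pep2group)),
    group_id = rep(group_tbl$group_id, lengths(pep2group))
  )
  annotated <- dplyr::inner_join(records, map, by = "peptide",
                                 relationship = "many-to-many")

  list(groups = group_tbl, records = annotated)
}

#' Write a protein-group table
#'
#' @param groups Tibble from [infer_protein_groups()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(groups, path) {
  readr::write_tsv(groups, path)
  invisible(path)
}
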