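# Internal helpers shared across modules.

# Stop with a classed condition; `field` names the offending config field
# so callers (and the CLI) can report it.
qp_config_error <- function(field, msg) {
  rlang::abort(
    sprintf("invalid configuration field `%s`: %s", field, msg),
    class = "quadpipe_config_error",
    field = field
  )
}

qp_input_error <- function(msg, class = "quadpipe_input_error") {
  rlang::abort(msg, class = class)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    qp_config_error(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    qp_config_error(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  check_scalar_number(x, field, lower = min)
  if (x != as.integer(x)) qp_config_error(field, "must be an integer")
  invisible(as.integer(x))
}

# Ordered column set for the peptide quantification TSV dialect.
peptide_table_columns <- function() {
  c("peptide", "proteins", "tissue", "replicate", "chase_day",
    "heavy_intensity", "light_intensity", "ratio_hl", "quality")
}

# Deterministic draw helper: run `expr` under a temporary RNG state seeded
# with `seed`, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}
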