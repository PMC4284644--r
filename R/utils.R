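# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so package functions never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed derived from a root seed and a stage tag, so each
# simulation / permutation stage gets its own reproducible stream.  Kept
# strictly below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h * 2654435) %% 2147483562) + 1L
}

# Stop with a classed configuration/input error naming the offending field.
config_error <- function(msg, field = NULL) {
  abort(msg, class = "twindmr_config_error", field = field)
}

input_error <- function(msg, ...) {
  abort(msg, class = "twindmr_input_error", ...)
}

check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    config_error(
      sprintf("`%s` must be a single integer >= %d (got %s).", name, min,
              paste(format(x), collapse = ", ")),
      field = name
    )
  }
  invisible(as.integer(x))
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x > max) {
    config_error(
      sprintf("`%s` must be a single number in [%s, %s].", name,
              format(min), format(max)),
      field = name
    )
  }
  invisible(as.numeric(x))
}

# Two-sided normal p-value from a z statistic.
z_pvalue <- function(z) 2 * pnorm(-abs(z))

# Direction label from an effect sign: hypermethylated in cases when beta > 0.
direction_label <- function(beta) {
  dplyr::case_when(
    is.na(beta) ~ NA_character_,
    beta > 0 ~ "hyper",
    beta < 0 ~ "hypo",
    TRUE ~ NA_character_
  )
}
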