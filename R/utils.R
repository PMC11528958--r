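# Internal utilities: seed management, validation helpers.

# data.table is used via Imports (not Depends); this flag tells it that
# [.data.table syntax inside this package is intentional.
.datatable.aware <- TRUE

#' Derive a stage seed from a master seed and a tag
#'
#' Deterministically maps `(seed, tag)` to an integer in `[0, 2^31 - 2]` so
#' that independent pipeline stages (registry generation, resampling draws,
#' tie-breaks, ERGM simulation) consume unrelated random streams.  Changing
#' one stage's iteration count therefore never perturbs another stage.
#'
#' @param seed integer master seed.
#' @param tag character scalar naming the stage (and, optionally, the
#'   iteration, e.g. `"null:17"`).
#' @return integer scalar suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 2047 + h) %% 2147483646L
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Named-proportion validation: must be numeric, non-negative, sum to 1
# within 1e-9.  `field` names the offending configuration entry in errors.
check_proportions <- function(x, field) {
  if (!is.numeric(x) || any(x < 0)) {
    stop(sprintf("configuration error: '%s' must be a non-negative numeric vector", field),
         call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("configuration error: '%s' must sum to 1 (got %.12f)", field, sum(x)),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("configuration error: '%s' must be an integer >= %d", field, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a semicolon-packed code field into a character vector ("" -> none).
split_codes <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
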