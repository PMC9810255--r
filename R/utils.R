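# Internal helpers shared across the pipeline.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# scalar checks used by config validators; `what` names the offending field
check_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      x != trunc(x)) {
    stop(sprintf("'%s' must be a positive integer", what), call. = FALSE)
  }
  as.integer(x)
}

check_range <- function(x, what) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] >= x[2]) {
    stop(sprintf("'%s' must be an increasing numeric range of length 2", what),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Bonferroni-adjusted significance level
#'
#' Divides a family-wise alpha by the number of comparisons in the family.
#' With the defaults used throughout the package (family alpha 0.05, five
#' comparisons per family) the per-test threshold is 0.01.
#'
#' @param family_alpha Family-wise type-I error rate, in (0, 1).
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted per-comparison alpha.
#' @examples
#' bonferroni_alpha(0.05, 5)  # 0.01
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (!is.numeric(family_alpha) || length(family_alpha) != 1L ||
      is.na(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop("'family_alpha' must be in (0, 1)", call. = FALSE)
  }
  m <- check_count(m, "m")
  family_alpha / m
}
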