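# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)`, restoring the caller's RNG state on
#' exit so library calls never clobber a user's random stream. A `NULL` seed
#' evaluates `code` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Canonical unordered pair key: genes sorted within the pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Fisher exact p for a 2x2 count table. Degenerate margins (any zero row or
# column sum) carry no association information: p = 1 by convention.
fisher_p <- function(tab, alternative = "two.sided") {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

# Sample (ad/bc) odds ratio with the conventions: numerator 0 -> 0,
# zero denominator with nonzero numerator -> +Inf.
sample_odds_ratio <- function(tab) {
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  if (num == 0) return(0)
  if (den == 0) return(Inf)
  num / den
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
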