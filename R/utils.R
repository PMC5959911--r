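# Shared internal helpers.

#' Round half away from zero
#'
#' Integer rounding where exact halves move away from zero, the convention
#' used for all reported percentages (so 4.5% prints as 5%, not 4%).
#' Base `round()` rounds half to even, which is unsuitable for reporting.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_away <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# Percentage of `num` in `den`, integer-rounded half away from zero.
# Empty denominator yields NA rather than NaN.
pct_of <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_away(100 * num / den)
}

# lognormal multiplicative noise factors with mean 1 and coefficient of
# variation `cv`; cv = 0 returns exact ones.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Draw one uniform value per row from per-class ranges c(lo, hi).
runif_range <- function(n, range) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  stats::runif(n, range[1], range[2])
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Check that a data.frame has the named columns; error names the missing ones.
check_columns <- function(df, cols, what = "table") {
  stopifnot(is.data.frame(df))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
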