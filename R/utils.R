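# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

clip01 <- function(x) clip(x, 0, 1)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so package functions never leave a footprint on the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  })
  set.seed(as.integer(seed))
  code
}

# Sample skewness m3 / m2^(3/2) and excess kurtosis m4 / m2^2 - 3.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}

# z-score that tolerates zero variance (returns centred zeros).
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

# Truncated-normal draws by rejection; ranges here are wide so this is cheap.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# Stable md5 fingerprint of an R object (used to stamp pipeline outputs).
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("exact", "niceNames")), tf)
  unname(tools::md5sum(tf))
}

# write.csv wrapper that preserves doubles to full precision so tables
# round-trip losslessly through read_cohort().
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
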