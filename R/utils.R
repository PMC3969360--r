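# Internal helpers shared across modules.

# Row means / sds of a matrix ignoring NAs, without looping in R.
.row_means_na <- function(x) {
  n <- rowSums(!is.na(x))
  s <- rowSums(x, na.rm = TRUE)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# Sample (n-1) standard deviation per row, NA where fewer than 2 values.
.row_sds_na <- function(x) {
  n <- rowSums(!is.na(x))
  m <- .row_means_na(x)
  dev2 <- (x - m)^2
  ss <- rowSums(dev2, na.rm = TRUE)
  out <- sqrt(ss / (n - 1))
  out[n < 2] <- NA_real_
  out
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.missing_tokens <- c("", "NA", "na", "null", "NULL")
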