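# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## round() uses round-half-even; reported fractions use conventional
## half-up rounding so printed percentages match manual arithmetic.
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. Keeps the simulator's sub-streams
## (sequence / mutation / pedigree) independent of each other.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

## Upper-case character vector of single bases from a string / XString.
## A character vector of length > 1 is assumed to already be split.
seqChars <- function(x) {
  x <- as.character(x)
  if (length(x) > 1L) return(toupper(x))
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

DNA_BASES4 <- c("A", "C", "G", "T")

## Write a file atomically (write to sibling temp path, then rename).
writeAtomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

stopStage <- function(stage, fmt, ...) {
  stop(sprintf("[stage %s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}
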