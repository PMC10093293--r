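#' @importFrom stats rbinom rnorm setNames aggregate pt
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero (printed tables use commercial rounding, while
# round() rounds half to even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Pairwise Hamming distance between equal-length strings.
hammingDist <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

# Hamming distance from each string in `subs` (all of length nchar(target))
# to `target`, vectorised through raw byte matrices.
hammingToTarget <- function(subs, target) {
  L <- nchar(target)
  if (length(subs) == 0L) return(integer(0))
  m <- matrix(charToRaw(paste(subs, collapse = "")), nrow = L)
  as.integer(colSums(m != charToRaw(target)))
}

# Uniform random DNA strings (vectorised).
randomDNA <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = len)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
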