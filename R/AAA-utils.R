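## typed conditions: config errors (bad parameters/files) vs data errors
## (inputs that cannot be quantified); the CLI maps these to exit codes

.stopConfig <- function(fmt, ...) {
  stop(structure(
    class = c("ampliMeth_config_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.stopData <- function(fmt, ...) {
  stop(structure(
    class = c("ampliMeth_data_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.revComp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

## evaluate code under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.msg <- function(level, current, fmt, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[current]] >= levels[[level]])
    message(sprintf(fmt, ...))
}

## base codes used throughout the vectorized simulator/aligner
.BASE_A <- utf8ToInt("A")
.BASE_C <- utf8ToInt("C")
.BASE_G <- utf8ToInt("G")
.BASE_T <- utf8ToInt("T")
.BASE_N <- utf8ToInt("N")

## split a character vector of equal-length sequences into an
## nchar x n integer matrix of utf8 codes
.seqMatrix <- function(seqs, len = nchar(seqs[1])) {
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = len)
}

## collapse an nchar x n utf8 code matrix back to a character vector
.matrixSeq <- function(m) {
  if (length(m) == 0L) return(character(0))
  s <- intToUtf8(as.vector(m))
  n <- ncol(m); w <- nrow(m)
  substring(s, (seq_len(n) - 1L) * w + 1L, seq_len(n) * w)
}
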