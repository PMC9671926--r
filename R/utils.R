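# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# fast char -> integer code (A=1, C=2, G=3, T=4, N=5)
.CODE_TABLE <- local({
  tab <- rep(NA_integer_, 127L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab[utf8ToInt("N")] <- 5L
  tab
})

seq_to_int <- function(s) {
  .CODE_TABLE[utf8ToInt(toupper(s))]
}

int_to_seq <- function(x) {
  paste(c(.BASES, "N")[x], collapse = "")
}

revcomp <- function(s) {
  x <- chartr("ACGTN", "TGCAN", toupper(s))
  vapply(x, function(z) {
    paste(rev(strsplit(z, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# validate a finite numeric scalar/vector, stop with the argument name otherwise
assert_finite <- function(x, what) {
  if (length(x) == 0L || !is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite and non-empty", what), call. = FALSE)
  }
  invisible(x)
}

# derive a 32-bit-safe child seed from a base seed and a stream index
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131L + k * 7919) %% 2147483647)
}
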