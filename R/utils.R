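# Small internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Broadcast a length-ncol vector across the rows of a matrix.
row_bcast <- function(v, nrow) matrix(v, nrow = nrow, ncol = length(v), byrow = TRUE)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
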