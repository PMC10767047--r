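## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## coerce to column-sparse without dropping dimnames
as_csparse <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

## population (ddof = 0) standard deviation of each row of a dense matrix
row_sd_pop <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans(x * x) - m * m)
}

## rank-sum AUC of `score` for separating positive from negative spots
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
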