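# Small fixtures built in code, shared across test files.

tiny_panel <- function() {
  genotype_matrix(
    matrix(c(0L, 1L, 2L,
             1L, NA, 0L), nrow = 3),
    map = data.frame(id = c("rs1", "rs2"), chr = c("1", "2"),
                     pos = c(100L, 250L), a1 = c("A", "G"), a2 = c("C", "T")),
    samples = c("i1", "i2", "i3")
  )
}

# a complete panel with hand-chosen calls for arithmetic checks
hand_panel <- function() {
  genotype_matrix(
    cbind(c(0L, 0L, 0L, 0L),    # p = 0
          c(0L, 1L, 2L, 1L),    # p = 0.5
          c(0L, 1L, 2L, 2L)),   # p = 5/8
    map = data.frame(id = paste0("m", 1:3), chr = "1",
                     pos = c(10L, 20L, 30L), a1 = "A", a2 = "B"),
    samples = paste0("s", 1:4)
  )
}

# dense-GLS association oracle: explicit V inverse, weighted regression with
# per-marker residual variance and a t test -- independent of the scan code path
gls_oracle_p <- function(y, X, S, V) {
  Vi <- solve(V)
  n <- length(y)
  p <- ncol(X)
  vapply(seq_len(ncol(S)), function(j) {
    Xj <- cbind(X, S[, j])
    A <- solve(t(Xj) %*% Vi %*% Xj)
    bj <- A %*% t(Xj) %*% Vi %*% y
    r <- y - Xj %*% bj
    s2 <- drop(t(r) %*% Vi %*% r) / (n - p - 1)
    zj <- bj[p + 1] / sqrt(s2 * A[p + 1, p + 1])
    2 * stats::pnorm(-abs(zj))
  }, numeric(1))
}
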