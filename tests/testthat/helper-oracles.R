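# brute-force permutation oracle: two-sided p over all splits
perm_oracle <- function(x, y) {
  v <- c(x, y)
  nx <- length(x)
  N <- length(v)
  r <- rank(v)
  mu <- nx * (N + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - mu)
  splits <- utils::combn(N, nx)
  stat <- apply(splits, 2, function(idx) abs(sum(r[idx]) - mu))
  mean(stat >= obs - 1e-9)
}

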