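# Small labeled source/target/test split for transfer-learning tests.
toy_split <- function(n_s = 20, m = 8, n_S = 10, p = 3, shift = 0, seed = 1) {
  set.seed(seed)
  mk <- function(n, mu_shift) {
    y <- rep(c("a", "b"), length.out = n)
    X <- matrix(stats::rnorm(n * p), n, p)
    X[y == "b", 1] <- X[y == "b", 1] + 3
    list(features = sweep(X, 2, rep(mu_shift, p), `+`), labels = y)
  }
  src <- mk(n_s, 0)
  td <- mk(m, shift)
  S <- mk(n_S, shift)
  domain_split(Tsd = src, Ttd = td, S = S$features)
}
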