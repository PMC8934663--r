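# small in-code fixtures shared across test files

# deterministic valid protospacers: cycle A/C/G/T with an offset per guide
toy_protospacers <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(rep(c("A", "C", "G", "T"), length.out = 20 + i)[(i + 1):(i + 20)],
          collapse = "")
  }, "")
}

# guide set with chosen target sequences (23 nt) and one weight each
toy_guide_set <- function(targets, weights, strand = NULL, ...) {
  guide_set(
    name = paste0("g", seq_along(targets)),
    protospacer = substr(targets, 1, 20),
    pam = substr(targets, 21, 23),
    replicates = as.list(weights),
    strand = strand,
    ...
  )
}

# n-guide set with random sequences and given weights
random_guide_set <- function(n, weights, seed = 1, ...) {
  set.seed(seed)
  proto <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), "")
  pam <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), "GG")
  guide_set(name = paste0("g", seq_len(n)), protospacer = proto, pam = pam,
            replicates = as.list(weights), ...)
}

# brute-force pooled two-sample t (independent of the package implementation)
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
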