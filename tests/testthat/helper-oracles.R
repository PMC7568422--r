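# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# All set partitions of 1..n by recursive insertion: element n joins each
# existing block of each partition of 1..(n-1), or starts a new block.
oracle_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in oracle_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# canonical key of a partition-as-blocks: assignment string in order of
# first appearance
partition_key <- function(blocks) {
  n <- sum(lengths(blocks))
  assign <- integer(n)
  for (b in seq_along(blocks)) assign[blocks[[b]]] <- b
  paste(match(assign, unique(assign)), collapse = ".")
}

# NB-beta marginal by numerical quadrature of the NB likelihood against
# the Beta(alpha, beta) prior
oracle_marginal <- function(x, r, alpha, beta) {
  if (length(r) == 1L) r <- rep(r, length(x))
  f <- function(q) {
    sapply(q, function(qi)
      prod(dnbinom(x, size = r, prob = qi)) *
        dbeta(qi, alpha, beta))
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0)$value
}

# brute-force median-of-ratios size factors
oracle_size_factors <- function(x) {
  pos <- apply(x, 1, function(r) all(r > 0))
  geo <- apply(x[pos, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  apply(x[pos, , drop = FALSE], 2, function(col) median(col / geo))
}

# the nine-candidate normalized condition means shipped with the package
candidate_means_fixture <- function() {
  path <- system.file("extdata", "candidate_means.tsv", package = "ebpat")
  df <- read.delim(path)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene
  m
}

toy_conditions <- function(K, R, labels = LETTERS[seq_len(K)]) {
  factor(rep(labels, each = R), levels = labels)
}
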