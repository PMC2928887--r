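# Brute-force finite-genome oracle: explicit genomes of L sites with
# per-site inheritance (each site from either parent with probability 1/2)
# and infinite-alleles mutation (each site mutates with probability
# 1 - exp(-2 mu) to a globally novel allele). Independent of the
# similarity-matrix recursion it is used to check.

genome_similarity <- function(a, b) mean(a == b)

# Evolve a small explicit-genome population from a common ancestor by
# `births` random replacement events; returns a list of genomes.
oracle_population <- function(n, L, mu, births = 40) {
  m <- 1 - exp(-2 * mu)
  genomes <- replicate(n, integer(L), simplify = FALSE)
  allele <- 0L
  for (b in seq_len(births)) {
    die <- sample.int(n, 1)
    ps <- sample(setdiff(seq_len(n), die), 2)
    child <- ifelse(stats::runif(L) < 0.5,
                    genomes[[ps[1]]], genomes[[ps[2]]])
    mut <- which(stats::runif(L) < m)
    if (length(mut)) {
      child[mut] <- allele + seq_along(mut)
      allele <- allele + length(mut)
    }
    genomes[[die]] <- child
  }
  genomes
}

# One explicit birth from parents p1, p2; returns the offspring genome.
oracle_offspring <- function(genomes, p1, p2, mu) {
  L <- length(genomes[[1]])
  m <- 1 - exp(-2 * mu)
  child <- ifelse(stats::runif(L) < 0.5, genomes[[p1]], genomes[[p2]])
  mut <- which(stats::runif(L) < m)
  child[mut] <- -seq_along(mut)  # globally novel alleles
  child
}

# Random symmetric unit-diagonal similarity matrix for graph tests.
random_similarity <- function(n) {
  q <- matrix(stats::runif(n * n), n, n)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 1
  q
}
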