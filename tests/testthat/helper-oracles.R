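## Independent oracles and small generators used across the suite.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

## Random point mutations (substitutions and indels).
mutate_seq <- function(s, nsub = 0, nind = 0) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in sample(length(ch), min(nsub, length(ch))))
    ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  for (k in seq_len(nind)) {
    p <- sample(length(ch), 1)
    if (runif(1) < 0.5) ch <- ch[-p]
    else ch <- append(ch, sample(BASES, 1), p)
  }
  paste(ch, collapse = "")
}

## Exact d<=1 test by direct characterization: equal length with Hamming
## distance <= 1, or length difference 1 with the shorter equal to the
## longer minus one character.  Independent of the deletion-signature /
## banded-DP implementation.
oracle_is_d1 <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  dl <- abs(la - lb)
  if (dl > 1) return(FALSE)
  ra <- utf8ToInt(a); rb <- utf8ToInt(b)
  if (dl == 0) return(sum(ra != rb) <= 1)
  if (la < lb) { tmp <- ra; ra <- rb; rb <- tmp }
  La <- length(ra)
  k <- 1
  while (k < La && ra[k] == rb[k]) k <- k + 1
  if (k == La) return(TRUE)               # deletion of the last character
  all(ra[(k + 1):La] == rb[k:(La - 1)])
}

## Brute-force connected components of the Levenshtein-<=1 graph, returned
## as a canonical partition (list of sorted member vectors, ordered by
## first member).
oracle_d1_components <- function(seqs) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (oracle_is_d1(seqs[i], seqs[j])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  parts <- lapply(split(seqs, comp), sort)
  parts <- unname(parts)
  parts[order(vapply(parts, `[`, character(1), 1))]
}

## Canonicalize swarm output to the same partition representation.
swarm_partition <- function(swarms) {
  parts <- lapply(swarms, function(sw) sort(sw$members$sequence))
  parts[order(vapply(parts, `[`, character(1), 1))]
}

## Full affine-gap (Gotoh) global alignment score in plain R.
oracle_affine_score <- function(a, b, match = 1, mismatch = -3,
                                go = 5, ge = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + i * ge)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + j * ge)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge,
                             X[i + 1, j] - go - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## Conditional Poisson tail P(X >= n | X >= 1) by explicit series summation
## (independent of stats::ppois).
oracle_cond_poisson <- function(n, lambda) {
  if (n == 1) return(1)
  if (lambda == 0) return(0)
  logterm <- function(k) k * log(lambda) - lambda - lgamma(k + 1)
  if (n > lambda) {
    s <- 0; k <- n
    repeat {
      t <- exp(logterm(k))
      s <- s + t
      k <- k + 1
      if ((k > lambda && t < s * 1e-18) || k > n + 100000) break
    }
    tail <- s
  } else {
    tail <- 1 - sum(exp(logterm(0:(n - 1))))
  }
  tail / (-expm1(-lambda))
}

## Random clustered instance for the swarm oracle tests: a few templates
## plus 0-2-edit satellites, deduplicated, with random counts.
random_swarm_instance <- function(max_seqs = 200, max_len = 140) {
  n_templates <- sample(1:5, 1)
  L <- sample(60:max_len, 1)
  templates <- vapply(seq_len(n_templates), function(i) rand_seq(L),
                      character(1))
  seqs <- templates
  target <- sample(10:max_seqs, 1)
  while (length(seqs) < target) {
    t <- sample(templates, 1)
    s <- mutate_seq(t, nsub = sample(0:2, 1), nind = sample(0:1, 1))
    seqs <- c(seqs, s)
  }
  seqs <- unique(seqs)
  data.frame(sequence = seqs,
             count = sample(1:50, length(seqs), replace = TRUE),
             stringsAsFactors = FALSE)
}
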