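## Two OTU definitions built from first principles: single-linkage d=1
## clustering with fastidious grafting ("swarms") and abundance-ordered
## greedy centroid clustering at 97% identity, plus the environmental
## occupancy/abundance prefilter.

#' Swarm clustering configuration
#'
#' @param d linkage distance (only d = 1 is implemented, as in the default
#'   swarm protocol).
#' @param fastidious graft low-mass swarms onto heavy swarms reachable
#'   through one virtual intermediate (total distance <= 2)?
#' @param fastidious_boundary swarms with mass below this are graft
#'   candidates (default 3, the published default).
#' @return a `swarm_config` list.
#' @export
swarm_config <- function(d = 1L, fastidious = TRUE, fastidious_boundary = 3L) {
  stopifnot(d == 1L, fastidious_boundary >= 2)
  structure(list(d = as.integer(d), fastidious = fastidious,
                 fastidious_boundary = as.integer(fastidious_boundary)),
            class = "swarm_config")
}

#' Single-linkage d=1 OTU clustering with fastidious grafting
#'
#' Without the fastidious step, swarms are exactly the connected components
#' of the graph joining unique sequences at Levenshtein distance <= 1
#' (neighbors found by deletion-signature hashing). With it, each swarm of
#' mass below `fastidious_boundary` is grafted onto the highest-mass heavy
#' swarm reachable by a distance-<= 2 link between any of its members and
#' any heavy-swarm member; unreachable light swarms remain standalone.
#' Input order does not matter: ordering is canonicalized internally
#' (count descending, then sequence), and output swarms are sorted by mass
#' descending with ties broken by seed sequence.
#'
#' @param barcodes data frame with `sequence` (unique) and `count`.
#' @param cfg a [swarm_config()].
#' @return list of swarms; each is a list with `seed` (sequence of the
#'   highest-count member), `members` (data frame `sequence`, `count`) and
#'   `mass` (total count).
#' @export
swarm_d1 <- function(barcodes, cfg = swarm_config()) {
  if (nrow(barcodes) == 0) return(list())
  stopifnot(!anyDuplicated(barcodes$sequence))
  b <- barcodes[order(-barcodes$count, barcodes$sequence), , drop = FALSE]
  n <- nrow(b)
  pairs <- cpp_d1_pairs(b$sequence)

  ## union-find over the d<=1 graph
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)

  make_swarm <- function(idx) {
    m <- b[idx, c("sequence", "count"), drop = FALSE]
    m <- m[order(-m$count, m$sequence), , drop = FALSE]
    rownames(m) <- NULL
    list(seed = m$sequence[1], members = m, mass = sum(m$count))
  }
  swarms <- lapply(groups, make_swarm)

  if (isTRUE(cfg$fastidious) && length(swarms) > 1) {
    mass <- vapply(swarms, `[[`, numeric(1), "mass")
    light <- which(mass < cfg$fastidious_boundary)
    heavy <- which(mass >= cfg$fastidious_boundary)
    if (length(light) > 0 && length(heavy) > 0) {
      graft_target <- rep(NA_integer_, length(swarms))
      for (li in light) {
        lseq <- swarms[[li]]$members$sequence
        best <- NA_integer_; best_mass <- -Inf
        for (hi in heavy) {
          hseq <- swarms[[hi]]$members$sequence
          d2 <- cpp_edit_cross(lseq, hseq, 2L)
          if (any(d2 <= 2)) {
            if (mass[hi] > best_mass ||
                (mass[hi] == best_mass &&
                 swarms[[hi]]$seed < swarms[[best]]$seed)) {
              best <- hi; best_mass <- mass[hi]
            }
          }
        }
        graft_target[li] <- best
      }
      for (li in light) {
        if (!is.na(graft_target[li])) {
          hi <- graft_target[li]
          m <- rbind(swarms[[hi]]$members, swarms[[li]]$members)
          m <- m[order(-m$count, m$sequence), , drop = FALSE]
          rownames(m) <- NULL
          swarms[[hi]]$members <- m
          swarms[[hi]]$mass <- sum(m$count)
          swarms[[hi]]$seed <- m$sequence[1]
        }
      }
      drop <- light[!is.na(graft_target[light])]
      if (length(drop) > 0) swarms <- swarms[-drop]
    }
  }

  mass <- vapply(swarms, `[[`, numeric(1), "mass")
  seeds <- vapply(swarms, `[[`, character(1), "seed")
  swarms <- swarms[order(-mass, seeds)]
  unname(swarms)
}

#' Abundance-ordered greedy centroid clustering at 97% identity
#'
#' A single greedy pass in decreasing count order (ties broken
#' lexicographically): each sequence joins the first already-created
#' centroid with global-alignment identity at least `min_identity`,
#' otherwise it becomes a new centroid.
#'
#' @param barcodes data frame with `sequence` (unique) and `count`.
#' @param min_identity identity threshold (default 0.97).
#' @param scoring a [scoring_scheme()].
#' @param band alignment band half-width (widened automatically on
#'   boundary contact; default 16).
#' @return list of clusters; each is a list with `centroid` and `members`
#'   (data frame `sequence`, `count`).
#' @export
centroid_cluster <- function(barcodes, min_identity = 0.97,
                             scoring = scoring_scheme(), band = 16) {
  if (nrow(barcodes) == 0) return(list())
  stopifnot(!anyDuplicated(barcodes$sequence))
  b <- barcodes[order(-barcodes$count, barcodes$sequence), , drop = FALSE]
  centroids <- character(0)
  assignment <- integer(nrow(b))
  for (i in seq_len(nrow(b))) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (global_identity(b$sequence[i], centroids[ci], scoring,
                          band = band) >= min_identity) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, b$sequence[i])
      assignment[i] <- length(centroids)
    }
  }
  lapply(seq_along(centroids), function(ci) {
    m <- b[assignment == ci, c("sequence", "count"), drop = FALSE]
    rownames(m) <- NULL
    list(centroid = centroids[ci], members = m)
  })
}

#' Environmental occupancy/abundance prefilter
#'
#' Retains barcodes that occur in at least `min_samples` samples and have
#' a total abundance of at least `min_reads` (the defaults keep barcodes
#' occurring in more than one sample with more than two reads).
#'
#' @param table samples x barcodes count matrix.
#' @param min_samples minimum occupancy (default 2).
#' @param min_reads minimum total reads (default 3).
#' @return the filtered count matrix.
#' @export
env_prefilter <- function(table, min_samples = 2, min_reads = 3) {
  stopifnot(is.matrix(table), nrow(table) >= 1)
  keep <- colSums(table > 0) >= min_samples & colSums(table) >= min_reads
  table[, keep, drop = FALSE]
}
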