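## Divisive amplicon denoiser with a quality-dependent error model.
##
## Unique sequences are partitioned around centers; a unique splits off as
## a new center when its abundance is implausibly high under the error
## model given its current center (conditional Poisson tail below omega_a).
## Error rates are learned self-consistently by alternating denoising and
## re-estimation of the quality-binned substitution matrix, regularized to
## be monotone non-increasing in quality.

Q_MAX <- 45L

#' Denoiser configuration
#'
#' @param omega_a partition-split threshold on the abundance p-value
#'   (default 1e-40, the published default; it reproduces the behavior
#'   that singletons can never seed a new partition).
#' @param max_selfconsist_rounds maximum rounds of alternating denoising
#'   and error-rate re-estimation (default 10).
#' @param pool_mode `"pooled"` (genome data: all reads learned together)
#'   or `"per_sample"` (environmental data).
#' @param bimera `"consensus"` or `"off"`.
#' @param min_fold_parent_overabundance parents must be at least this many
#'   times more abundant than a bimera candidate (default 2).
#' @param consensus_sample_fraction remove an ASV when it is flagged in
#'   more than this fraction of the samples where it was testable
#'   (default 0.9).
#' @param band alignment band half-width for unique-vs-center comparisons
#'   (default 16; widened automatically on boundary contact).
#' @param indel_prob per-event indel probability used for gap columns in
#'   the error product (default 1e-5).
#' @return a `denoise_config` list.
#' @export
denoise_config <- function(omega_a = 1e-40, max_selfconsist_rounds = 10L,
                           pool_mode = c("pooled", "per_sample"),
                           bimera = c("consensus", "off"),
                           min_fold_parent_overabundance = 2,
                           consensus_sample_fraction = 0.9,
                           band = 16L, indel_prob = 1e-5) {
  stopifnot(omega_a > 0, omega_a < 1, max_selfconsist_rounds >= 1)
  structure(list(omega_a = omega_a,
                 max_selfconsist_rounds = as.integer(max_selfconsist_rounds),
                 pool_mode = match.arg(pool_mode),
                 bimera = match.arg(bimera),
                 min_fold_parent_overabundance = min_fold_parent_overabundance,
                 consensus_sample_fraction = consensus_sample_fraction,
                 band = as.integer(band), indel_prob = indel_prob),
            class = "denoise_config")
}

#' Build an error model from per-quality substitution rates
#'
#' @param rate_by_q numeric vector of total substitution probabilities
#'   indexed by quality 0..`Q_MAX` (recycled from a scalar); each
#'   off-diagonal transition gets a third of the total.
#' @param floor minimum probability for any transition (default 1e-7).
#' @param indel_prob per-event indel probability.
#' @return an `error_model` list with the 4 x 4 x (Q_MAX + 1) transition
#'   array `sub`, `indel_prob`, `floor` and `learned`.
#' @export
error_model_flat <- function(rate_by_q = 10^(-(0:Q_MAX) / 10), floor = 1e-7,
                             indel_prob = 1e-5) {
  rate_by_q <- rep_len(rate_by_q, Q_MAX + 1L)
  sub <- array(0, dim = c(4, 4, Q_MAX + 1L),
               dimnames = list(DNA_BASES, DNA_BASES, 0:Q_MAX))
  for (qi in seq_len(Q_MAX + 1L)) {
    off <- pmax(rate_by_q[qi] / 3, floor)
    m <- matrix(off, 4, 4)
    diag(m) <- 1 - 3 * off
    sub[, , qi] <- m
  }
  structure(list(sub = sub, indel_prob = indel_prob, floor = floor,
                 learned = FALSE),
            class = "error_model")
}

## log10 probability that `center` was read as `seq` given per-base
## qualities of `seq` (positionwise means for a dereplicated unique).
log10_error_probability <- function(seq, quals, center, model,
                                    scoring = scoring_scheme(), band = 16) {
  if (seq == center) {
    q <- pmin(pmax(round(quals), 0L), Q_MAX)
    cb <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
    p <- model$sub[cbind(cb, cb, q + 1L)]
    return(sum(log10(p)))
  }
  aln <- global_align(center, seq, scoring, band = band)
  ca <- strsplit(aln$a_aln, "", fixed = TRUE)[[1]]
  ua <- strsplit(aln$b_aln, "", fixed = TRUE)[[1]]
  qs <- pmin(pmax(round(quals), 0L), Q_MAX)
  lp <- 0
  upos <- 0L
  in_gap <- FALSE
  for (k in seq_along(ca)) {
    if (ua[k] != "-") upos <- upos + 1L
    if (ca[k] == "-" || ua[k] == "-") {
      if (!in_gap) lp <- lp + log10(model$indel_prob)  # one event per run
      in_gap <- TRUE
      next
    }
    in_gap <- FALSE
    ci <- match(ca[k], DNA_BASES)
    ui <- match(ua[k], DNA_BASES)
    q <- qs[min(upos, length(qs))]
    if (is.na(ci) || is.na(ui)) next
    lp <- lp + log10(model$sub[ci, ui, q + 1L])
  }
  lp
}

#' Per-sequence error-production probability
#'
#' The probability that sequencing errors turn the partition center into
#' the observed unique sequence: the product over global-alignment columns
#' of the quality-dependent transition probabilities, with a per-event
#' indel probability for gap runs.
#'
#' @param seq unique sequence.
#' @param quals per-position quality aggregate (numeric vector).
#' @param center partition center sequence.
#' @param model an [error_model_flat()] or learned model.
#' @param cfg a [denoise_config()] (band, indel probability).
#' @return numeric probability (may underflow to 0 for very divergent
#'   pairs; the divisive test works on the conditional Poisson mean, where
#'   0 simply forces a split for non-singletons).
#' @export
error_probability <- function(seq, quals, center, model,
                              cfg = denoise_config()) {
  model$indel_prob <- cfg$indel_prob
  10^log10_error_probability(seq, quals, center, model, band = cfg$band)
}

#' Conditional Poisson abundance p-value
#'
#' p = P(X >= n | X >= 1) for X ~ Poisson(lambda); the p-value of observing
#' `n` or more error reads when `lambda` are expected. Defined as 1 for
#' n = 1 (a singleton is always consistent with being an error) and 0 for
#' lambda = 0 with n > 1.
#'
#' @param n observed abundance (>= 1).
#' @param lambda expected number of error-derived reads.
#' @return numeric p-value in [0, 1].
#' @export
abundance_p_value <- function(n, lambda) {
  stopifnot(n >= 1, lambda >= 0)
  if (n == 1) return(1)
  if (lambda == 0) return(0)
  denom <- -expm1(-lambda)               # P(X >= 1)
  ppois(n - 1, lambda, lower.tail = FALSE) / denom
}

## Dereplicate reads keeping positionwise mean qualities per unique.
derep_with_quality <- function(reads) {
  if (nrow(reads) == 0)
    return(data.frame(sequence = character(0), count = integer(0)))
  groups <- split(seq_len(nrow(reads)), reads$seq)
  seqs <- names(groups)
  counts <- lengths(groups)
  quals <- lapply(groups, function(idx) {
    qm <- vapply(reads$qual[idx], phred_to_int,
                 integer(nchar(reads$seq[idx[1]])))
    if (is.matrix(qm)) rowMeans(qm) else as.numeric(qm)
  })
  out <- data.frame(sequence = seqs, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$quals <- unname(quals)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Divisive denoising of one sample
#'
#' Starts from one partition centered on the most abundant unique. For
#' every unique the expected number of error reads lambda = rho x
#' (partition reads) and the conditional Poisson abundance p-value are
#' computed against its current center; while the smallest p-value is
#' below `omega_a` the corresponding unique is promoted to a new partition
#' center and all uniques are reassigned to the center maximizing rho. At
#' convergence each partition yields one ASV (its center sequence with the
#' partition's total reads).
#'
#' @param uniques data frame from `derep_with_quality()`: `sequence`,
#'   `count`, `quals` (list column of positionwise mean qualities).
#' @param model an error model.
#' @param cfg a [denoise_config()].
#' @return list with `asvs` (data frame `sequence`, `count`, sorted by
#'   count descending) and `assignment` (partition index per unique, in
#'   the canonical count-descending order of `uniques`).
#' @export
denoise_sample <- function(uniques, model, cfg = denoise_config()) {
  if (nrow(uniques) == 0)
    return(list(asvs = data.frame(sequence = character(0),
                                  count = integer(0)),
                assignment = integer(0),
                uniques = uniques))
  u <- uniques[order(-uniques$count, uniques$sequence), , drop = FALSE]
  rownames(u) <- NULL
  n <- nrow(u)
  model$indel_prob <- cfg$indel_prob

  centers <- 1L                           # indices into u
  log_rho <- matrix(NA_real_, n, 1)
  log_rho[, 1] <- vapply(seq_len(n), function(i)
    log10_error_probability(u$sequence[i], u$quals[[i]],
                            u$sequence[centers[1]], model,
                            band = cfg$band), numeric(1))
  assignment <- rep(1L, n)

  repeat {
    part_reads <- vapply(seq_along(centers), function(ci)
      sum(u$count[assignment == ci]), numeric(1))
    pvals <- rep(1, n)
    for (i in seq_len(n)) {
      if (i %in% centers) next
      ci <- assignment[i]
      lambda <- 10^log_rho[i, ci] * part_reads[ci]
      pvals[i] <- abundance_p_value(u$count[i], lambda)
    }
    imin <- which.min(pvals)
    if (pvals[imin] >= cfg$omega_a) break
    centers <- c(centers, imin)
    newcol <- vapply(seq_len(n), function(i)
      log10_error_probability(u$sequence[i], u$quals[[i]],
                              u$sequence[imin], model,
                              band = cfg$band), numeric(1))
    log_rho <- cbind(log_rho, newcol)
    ## reassign every unique to the partition maximizing rho
    assignment <- apply(log_rho, 1, which.max)
    assignment <- as.integer(assignment)
    for (ci in seq_along(centers)) assignment[centers[ci]] <- ci
  }

  counts <- vapply(seq_along(centers), function(ci)
    sum(u$count[assignment == ci]), integer(1))
  asvs <- data.frame(sequence = u$sequence[centers], count = counts,
                     stringsAsFactors = FALSE)
  ord <- order(-asvs$count, asvs$sequence)
  rank <- match(seq_along(centers), ord)
  asvs <- asvs[ord, , drop = FALSE]
  rownames(asvs) <- NULL
  list(asvs = asvs, assignment = rank[assignment], uniques = u)
}

## Weighted pool-adjacent-violators: non-increasing fit of y against index
## order, with weights w.
pava_nonincreasing <- function(y, w) {
  n <- length(y)
  if (n <= 1) return(y)
  ## fit non-decreasing to reversed series, then reverse back
  yr <- rev(y); wr <- rev(w)
  val <- yr; wt <- wr
  idx <- rep(1, n)                        # block membership sizes
  i <- 1
  vals <- c(); wts <- c(); sizes <- c()
  for (k in seq_len(n)) {
    cv <- yr[k]; cw <- wr[k]; cs <- 1
    while (length(vals) > 0 && tail(vals, 1) > cv) {
      pv <- tail(vals, 1); pw <- tail(wts, 1); ps <- tail(sizes, 1)
      cv <- (pv * pw + cv * cw) / (pw + cw)
      cw <- pw + cw; cs <- ps + cs
      vals <- vals[-length(vals)]; wts <- wts[-length(wts)]
      sizes <- sizes[-length(sizes)]
    }
    vals <- c(vals, cv); wts <- c(wts, cw); sizes <- c(sizes, cs)
  }
  rev(rep(vals, sizes))
}

#' Learn a quality-dependent error model self-consistently
#'
#' Alternates denoising with the current model and re-estimation of the
#' substitution rates from mismatches between each unique and its
#' partition center, binned by quality. Bins with no observations inherit
#' the nearest quality bin's value; rates are regularized to be monotone
#' non-increasing in quality (weighted isotonic regression) with a
#' probability floor. Stops when the transition array changes by less
#' than 1e-6 in max-norm or after `max_selfconsist_rounds` rounds.
#'
#' @param samples list of unique data frames (see `derep_with_quality()`),
#'   or a single data frame.
#' @param cfg a [denoise_config()].
#' @param init initial error model (default Phred-implied rates).
#' @return a learned `error_model` (field `learned` reports convergence).
#' @export
learn_error_model <- function(samples, cfg = denoise_config(),
                              init = error_model_flat(indel_prob = cfg$indel_prob)) {
  if (is.data.frame(samples)) samples <- list(samples)
  stopifnot(length(samples) >= 1)
  model <- init
  converged <- FALSE
  for (round in seq_len(cfg$max_selfconsist_rounds)) {
    counts <- array(0, dim = c(4, 4, Q_MAX + 1L),
                    dimnames = dimnames(model$sub))
    for (s in samples) {
      dn <- denoise_sample(s, model, cfg)
      u <- dn$uniques
      for (i in seq_len(nrow(u))) {
        center <- dn$asvs$sequence[dn$assignment[i]]
        counts <- counts + transition_counts(u$sequence[i], u$quals[[i]],
                                             center, u$count[i], cfg)
      }
    }
    new_sub <- estimate_rates(counts, model$floor)
    delta <- max(abs(new_sub - model$sub))
    model$sub <- new_sub
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  model$learned <- converged
  model
}

## Quality-binned (from, to) transition counts of one unique against its
## center, weighted by the unique's read count.
transition_counts <- function(seq, quals, center, weight, cfg) {
  counts <- array(0, dim = c(4, 4, Q_MAX + 1L))
  qs <- pmin(pmax(round(quals), 0L), Q_MAX)
  if (seq == center) {
    cb <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
    for (k in seq_along(cb))
      counts[cb[k], cb[k], qs[k] + 1L] <-
        counts[cb[k], cb[k], qs[k] + 1L] + weight
    return(counts)
  }
  aln <- global_align(center, seq, band = cfg$band)
  ca <- strsplit(aln$a_aln, "", fixed = TRUE)[[1]]
  ua <- strsplit(aln$b_aln, "", fixed = TRUE)[[1]]
  upos <- 0L
  for (k in seq_along(ca)) {
    if (ua[k] != "-") upos <- upos + 1L
    if (ca[k] == "-" || ua[k] == "-") next
    ci <- match(ca[k], DNA_BASES); ui <- match(ua[k], DNA_BASES)
    if (is.na(ci) || is.na(ui)) next
    q <- qs[min(upos, length(qs))]
    counts[ci, ui, q + 1L] <- counts[ci, ui, q + 1L] + weight
  }
  counts
}

## Estimate the transition array from counts: per (from, quality) row
## normalization, nearest-bin inheritance for empty bins, isotonic
## (non-increasing in quality) off-diagonal rates, floor, renormalized
## diagonal.
estimate_rates <- function(counts, floor) {
  sub <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  totals <- apply(counts, c(1, 3), sum)   # from x quality
  for (f in 1:4) {
    obs_q <- which(totals[f, ] > 0)
    for (t in 1:4) {
      if (f == t) next
      rate <- rep(NA_real_, Q_MAX + 1L)
      rate[obs_q] <- counts[f, t, obs_q] / totals[f, obs_q]
      if (length(obs_q) == 0) {
        rate[] <- floor
      } else {
        ## empty bins inherit the nearest observed quality bin
        for (qi in seq_len(Q_MAX + 1L)) {
          if (is.na(rate[qi]))
            rate[qi] <- rate[obs_q[which.min(abs(obs_q - qi))]]
        }
        w <- pmax(totals[f, ], 1)
        rate <- pava_nonincreasing(rate, w)
      }
      sub[f, t, ] <- pmax(rate, floor)
    }
  }
  for (qi in seq_len(Q_MAX + 1L)) {
    for (f in 1:4) {
      off <- sum(sub[f, setdiff(1:4, f), qi])
      sub[f, f, qi] <- max(1 - off, floor)
    }
  }
  sub
}

#' Consensus bimera removal across samples
#'
#' Within each sample, an ASV is flagged as a bimera when it is exactly
#' reconstructable as a left prefix of one parent plus a right suffix of a
#' different parent (one breakpoint, zero mismatches per segment), with
#' both parents at least `min_fold_parent_overabundance` times more
#' abundant. An ASV is testable in a sample when it has at least two such
#' candidate parents. An ASV is removed from all samples when it was
#' flagged in more than `consensus_sample_fraction` of the samples where
#' it was testable.
#'
#' @param per_sample_asvs list of ASV data frames (`sequence`, `count`),
#'   one per sample; a single data frame is treated as one sample.
#' @param cfg a [denoise_config()].
#' @return list with `tables` (filtered ASV tables) and `removed`
#'   (character vector of removed sequences).
#' @export
remove_bimeras_consensus <- function(per_sample_asvs,
                                     cfg = denoise_config()) {
  single <- is.data.frame(per_sample_asvs)
  if (single) per_sample_asvs <- list(per_sample_asvs)
  flags <- list()                        # sequence -> c(flagged, testable)
  note <- function(seqs, key, inc) {
    for (s in seqs) {
      if (is.null(flags[[s]])) flags[[s]] <<- c(flagged = 0, testable = 0)
      cur <- flags[[s]]
      cur[key] <- cur[key] + inc
      flags[[s]] <<- cur
    }
  }
  for (tab in per_sample_asvs) {
    if (nrow(tab) < 3) next
    tab <- tab[order(-tab$count, tab$sequence), , drop = FALSE]
    for (i in seq_len(nrow(tab))) {
      child <- tab$sequence[i]
      L <- nchar(child)
      par_idx <- which(tab$count >= cfg$min_fold_parent_overabundance *
                         tab$count[i] & tab$sequence != child)
      if (length(par_idx) < 2) next
      note(child, "testable", 1)
      ps <- cpp_prefix_suffix(child, tab$sequence[par_idx])
      lcp <- ps[, 1]; lcs <- ps[, 2]
      ## need distinct parents A (prefix) and B (suffix) covering the child
      o <- order(-lcp)
      top1 <- o[1]; top2 <- if (length(o) > 1) o[2] else NA
      flagged <- FALSE
      for (bi in seq_along(par_idx)) {
        ai <- if (bi == top1 && !is.na(top2)) top2 else top1
        if (bi == ai) next
        if (lcp[ai] >= 1 && lcs[bi] >= 1 && lcp[ai] + lcs[bi] >= L) {
          flagged <- TRUE
          break
        }
      }
      if (flagged) note(child, "flagged", 1)
    }
  }
  removed <- character(0)
  for (s in names(flags)) {
    fl <- flags[[s]]
    if (fl["testable"] > 0 &&
        fl["flagged"] / fl["testable"] > cfg$consensus_sample_fraction)
      removed <- c(removed, s)
  }
  tables <- lapply(per_sample_asvs, function(tab)
    tab[!tab$sequence %in% removed, , drop = FALSE])
  list(tables = if (single) tables[[1]] else tables, removed = removed)
}

#' Denoise merged reads end to end
#'
#' Convenience wrapper: dereplicates reads with quality aggregates, learns
#' the error model self-consistently, denoises, and (optionally) removes
#' bimeras by the consensus rule.
#'
#' @param reads merged reads data frame.
#' @param cfg a [denoise_config()].
#' @param model optional pre-learned error model (skips learning).
#' @return list with `asvs`, `model` and the dereplicated `uniques`.
#' @export
denoise_merged <- function(reads, cfg = denoise_config(), model = NULL) {
  uniques <- derep_with_quality(reads)
  if (is.null(model)) model <- learn_error_model(uniques, cfg)
  dn <- denoise_sample(uniques, model, cfg)
  asvs <- dn$asvs
  if (cfg$bimera == "consensus" && nrow(asvs) > 0) {
    asvs <- remove_bimeras_consensus(asvs, cfg)$tables
  }
  list(asvs = asvs, model = model, uniques = uniques, assignment = dn$assignment)
}

#' Denoise paired reads (80/80 truncation protocol)
#'
#' Truncates both mates to `trunc_len` (80 nt), denoises the forward and
#' reverse streams independently, merges denoised mate pairs by exact
#' ungapped overlap consensus (pairs whose denoised sequences fail to
#' overlap with at least `min_merge_overlap` identical bases are dropped),
#' then removes bimeras.
#'
#' @param pairs list with `forward`/`reverse` reads data frames (primer
#'   trimmed).
#' @param cfg a [denoise_config()].
#' @param trunc_len truncation length per mate (default 80).
#' @param max_expected_errors per-mate expected-error cap (default 2).
#' @param min_merge_overlap minimum exact overlap when merging denoised
#'   mates (default 12).
#' @return list with `asvs`, the per-stream models, and `n_dropped_pairs`
#'   (read pairs whose denoised mates failed to merge).
#' @export
denoise_paired <- function(pairs, cfg = denoise_config(), trunc_len = 80,
                           max_expected_errors = 2, min_merge_overlap = 12) {
  fwd <- discard_n_and_truncate(pairs$forward, max_n = 0, trunc_q = 2,
                                trunc_len = trunc_len,
                                max_expected_errors = max_expected_errors)
  rev_ <- discard_n_and_truncate(pairs$reverse, max_n = 0, trunc_q = 2,
                                 trunc_len = trunc_len,
                                 max_expected_errors = max_expected_errors)
  ids <- intersect(fwd$id, rev_$id)
  fwd <- fwd[match(ids, fwd$id), , drop = FALSE]
  rev_ <- rev_[match(ids, rev_$id), , drop = FALSE]
  if (length(ids) == 0)
    return(list(asvs = data.frame(sequence = character(0),
                                  count = integer(0)),
                n_dropped_pairs = 0L))

  uf <- derep_with_quality(fwd)
  ur <- derep_with_quality(rev_)
  mf <- learn_error_model(uf, cfg)
  mr <- learn_error_model(ur, cfg)
  df <- denoise_sample(uf, mf, cfg)
  dr <- denoise_sample(ur, mr, cfg)

  ## map each read pair to its (forward ASV, reverse ASV) combination
  fmap <- df$assignment[match(fwd$seq, df$uniques$sequence)]
  rmap <- dr$assignment[match(rev_$seq, dr$uniques$sequence)]
  combo <- paste(fmap, rmap)
  dropped <- 0L
  merged <- list()
  for (cb in unique(combo)) {
    idx <- which(combo == cb)
    fseq <- df$asvs$sequence[fmap[idx[1]]]
    rseq <- revcomp(dr$asvs$sequence[rmap[idx[1]]])
    m <- exact_overlap_merge(fseq, rseq, min_merge_overlap)
    if (is.null(m)) {
      dropped <- dropped + length(idx)
    } else {
      merged[[length(merged) + 1]] <- data.frame(sequence = m,
                                                 count = length(idx))
    }
  }
  if (length(merged) == 0)
    return(list(asvs = data.frame(sequence = character(0),
                                  count = integer(0)),
                n_dropped_pairs = dropped))
  asvs <- do.call(rbind, merged)
  asvs <- aggregate(count ~ sequence, asvs, sum)
  asvs <- asvs[order(-asvs$count, asvs$sequence), c("sequence", "count")]
  rownames(asvs) <- NULL
  if (cfg$bimera == "consensus" && nrow(asvs) > 0)
    asvs <- remove_bimeras_consensus(asvs, cfg)$tables
  list(asvs = asvs, model_forward = mf, model_reverse = mr,
       n_dropped_pairs = dropped)
}

## Merge two sequences by their best exact ungapped overlap (>= min_ov
## identical bases); NULL when none exists.
exact_overlap_merge <- function(a, b, min_ov) {
  la <- nchar(a); lb <- nchar(b)
  for (L in seq(min(la, lb), min_ov)) {
    if (L < min_ov) break
    if (substr(a, la - L + 1, la) == substr(b, 1, L))
      return(paste0(a, substr(b, L + 1, lb)))
  }
  NULL
}
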