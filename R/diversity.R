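# Depth normalization and alpha diversity: random subsampling without
# replacement, analytic (hypergeometric) rarefaction, Chao1 richness and
# the Shannon index, plus the pooled "mixed" sample.

#' Subsample a count vector to a fixed depth without replacement
#'
#' @param counts Named numeric/integer vector of reads per cluster.
#' @param depth Target depth; samples with fewer reads cannot be subsampled
#'   and yield `NULL` (callers flag them as excluded, they are not an
#'   error).
#' @param seed Optional integer seed applied locally (the caller's RNG
#'   state is restored on exit).
#' @return Named integer vector of resampled counts (clusters with zero
#'   draws dropped), or `NULL` when `sum(counts) < depth`.
#' @export
subsample_counts <- function(counts, depth = 2883L, seed = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  if (N < depth) return(NULL)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  if (N == depth) return(counts[counts > 0])
  ids <- rep(names(counts), counts)
  drawn <- sample(ids, depth, replace = FALSE)
  tab <- table(drawn)
  stats::setNames(as.integer(tab), names(tab))
}

#' Pooled "mixed" sample from depth-normalized count vectors
#'
#' Pools several subsampled count vectors (each at exactly `depth` reads)
#' and draws `depth` reads without replacement from the pool, emulating a
#' global composite community at the same sequencing depth.
#'
#' @param subsampled List of >= 2 named count vectors, each summing to
#'   `depth`.
#' @param depth Common depth.
#' @param seed Optional local seed.
#' @return Named integer count vector summing to `depth`.
#' @export
mixed_sample <- function(subsampled, depth = 2883L, seed = NULL) {
  if (length(subsampled) < 2) stop("need at least 2 subsampled inputs")
  sums <- vapply(subsampled, sum, numeric(1))
  if (any(sums != depth)) {
    stop("every input must sum to exactly the common depth")
  }
  pool <- tapply(
    unlist(lapply(subsampled, as.numeric), use.names = FALSE),
    unlist(lapply(subsampled, names), use.names = FALSE),
    sum
  )
  pooled <- stats::setNames(as.integer(pool), names(pool))
  subsample_counts(pooled, depth = depth, seed = seed)
}

#' Chao1 richness estimator
#'
#' Bias-corrected form (default): `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`,
#' defined for all inputs. Classic form: `S_obs + F1^2 / (2 F2)`, which
#' falls back to the bias-corrected form when no doubletons exist.
#'
#' @param counts Named count vector.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- counts[counts > 0]
  S <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (bias_corrected || F2 == 0) {
    S + F1 * (F1 - 1) / (2 * (F2 + 1))
  } else {
    S + F1^2 / (2 * F2)
  }
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum p_i ln p_i` with `p_i = counts_i / N`.
#'
#' @param counts Named count vector.
#' @return Shannon index in `[0, ln S_obs]`.
#' @export
shannon_index <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Expected richness under hypergeometric rarefaction
#'
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated with
#' log-gamma for numerical stability; exact at the endpoints
#' (`E[S_0] = 0`, `E[S_N] = S_obs`).
#'
#' @param counts Named count vector.
#' @param n Subsample size(s), `0 <= n <= N` (vectorised).
#' @return Expected richness for each `n`.
#' @export
rarefy_expectation <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(n < 0 | n > N)) stop("n must be between 0 and N = ", N)
  vapply(n, function(nn) {
    sum(1 - exp(lchoose(N - counts, nn) - lchoose(N, nn)))
  }, numeric(1))
}

#' Rarefaction curve on an evenly spaced grid
#'
#' @param counts Named count vector.
#' @param n_points Number of grid points between 0 and N.
#' @return Data frame with columns `n` and `E_Sn`.
#' @export
rarefaction_curve <- function(counts, n_points = 20L) {
  N <- sum(counts)
  grid <- unique(round(seq(0, N, length.out = n_points + 1)))
  data.frame(n = grid, E_Sn = rarefy_expectation(counts, grid))
}

#' Per-sample diversity report across clustering thresholds
#'
#' Subsamples each sample's cluster counts to a common depth (samples below
#' the depth are excluded, not an error), then reports N, observed
#' richness, singletons/doubletons, Chao1 (both forms) and Shannon at every
#' threshold, plus the pooled "mixed" sample per threshold when at least
#' two samples are included.
#'
#' @param cluster_sets Named list of `cluster_set`s (one per threshold).
#' @param depth Subsampling depth.
#' @param seed Integer seed; each (threshold, sample) combination gets a
#'   deterministic derived seed.
#' @return List with `table` (long data frame), `subsampled` (list:
#'   threshold -> sample -> counts) and `excluded` (list: threshold ->
#'   character vector of sample names below depth at that level).
#' @export
diversity_report <- function(cluster_sets, depth = 2883L, seed = 1L) {
  tab <- list()
  sub_all <- list()
  excluded <- list()
  for (k in seq_along(cluster_sets)) {
    cs <- cluster_sets[[k]]
    thr <- as.character(cs$threshold)
    samples <- colnames(cs$abundance)
    subs <- list()
    excluded[[thr]] <- character(0)
    for (i in seq_along(samples)) {
      s <- samples[i]
      cnt <- cs$abundance[, s]
      cnt <- cnt[cnt > 0]
      sub <- subsample_counts(cnt, depth = depth,
                              seed = seed + 1009L * k + i)
      if (is.null(sub)) {
        excluded[[thr]] <- c(excluded[[thr]], s)
        next
      }
      subs[[s]] <- sub
      tab[[length(tab) + 1]] <- diversity_row(cs$threshold, s, sub)
    }
    if (length(subs) >= 2) {
      mx <- mixed_sample(subs, depth = depth, seed = seed + 1009L * k)
      tab[[length(tab) + 1]] <- diversity_row(cs$threshold, "mixed", mx)
      subs[["mixed"]] <- mx
    }
    sub_all[[thr]] <- subs
  }
  list(table = do.call(rbind, tab), subsampled = sub_all,
       excluded = excluded)
}

diversity_row <- function(thr, s, cnt) {
  data.frame(
    threshold = thr, sample = s,
    N = sum(cnt), S_obs = length(cnt),
    F1 = sum(cnt == 1), F2 = sum(cnt == 2),
    chao1 = chao1(cnt),
    chao1_classic = chao1(cnt, bias_corrected = FALSE),
    shannon = shannon_index(cnt),
    stringsAsFactors = FALSE
  )
}
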