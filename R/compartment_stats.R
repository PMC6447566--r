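# Differential-compartment statistics: across-timepoint eigenvector
# variance, rank-sum comparison and the permutation-based FDR.

#' Across-timepoint eigenvector variance per compartment
#'
#' For each footprint, the per-timepoint mean eigenvector value over its
#' (unmasked) bins is computed, then the variance of those means across the
#' timepoints. The population variance (divide by the number of timepoints)
#' is used by default: the quantity is descriptive over exactly the observed
#' timepoints.
#'
#' @param tracks list of `eigen_track`s (typically the five timepoints), all
#'   on one layout.
#' @param footprints data.frame of footprints (chrom, start, end), e.g.
#'   `pattern_assignments`.
#' @param population use population variance (default TRUE); FALSE gives the
#'   sample variance.
#' @return data.frame: footprint columns, one `mean_<tag>` column per track,
#'   and `sigma2`. Fully masked footprints are dropped with a warning.
#' @export
eigen_variance <- function(tracks, footprints, population = TRUE) {
  stopifnot(length(tracks) >= 2)
  layout <- attr(tracks[[1]], "layout")
  for (tr in tracks)
    if (!.layouts_equal(attr(tr, "layout"), layout))
      stop("tracks are on different layouts")
  tags <- vapply(seq_along(tracks), function(i) {
    tp <- attr(tracks[[i]], "timepoint")
    if (is.null(tp) || is.na(tp)) paste0("t", i) else tp
  }, character(1))
  vals <- sapply(tracks, function(tr) tr$value)
  n <- nrow(footprints)
  means <- matrix(NA_real_, n, length(tracks))
  keep <- rep(TRUE, n)
  for (k in seq_len(n)) {
    bins <- .seg_bins(layout, footprints$chrom[k], footprints$start[k],
                      footprints$end[k])
    v <- vals[bins, , drop = FALSE]
    if (all(is.na(v))) { keep[k] <- FALSE; next }
    means[k, ] <- colMeans(v, na.rm = TRUE)
  }
  if (any(!keep))
    warning(sum(!keep), " footprint(s) fully masked; dropped")
  m <- means[keep, , drop = FALSE]
  denom <- if (population) ncol(m) else ncol(m) - 1
  sigma2 <- apply(m, 1, function(r) sum((r - mean(r))^2) / denom)
  out <- cbind(footprints[keep, , drop = FALSE],
               stats::setNames(as.data.frame(m), paste0("mean_", tags)),
               sigma2 = sigma2)
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration over all group labelings of the pooled midranks when
#' the combined sample size is at most `exact_max` (handles ties exactly);
#' tie-corrected normal approximation with continuity correction otherwise
#' (delegated to [stats::wilcox.test()]).
#'
#' @param group1,group2 numeric vectors (both nonempty).
#' @param exact_max combined-size threshold for exact enumeration
#'   (default 12).
#' @return two-sided p-value in (0, 1].
#' @export
ranksum_test <- function(group1, group2, exact_max = 12) {
  stopifnot(length(group1) > 0, length(group2) > 0)
  n1 <- length(group1); n2 <- length(group2); n <- n1 + n2
  pooled <- c(group1, group2)
  if (n <= exact_max) {
    r <- rank(pooled)  # midranks under ties
    w_obs <- sum(r[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    combs <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    eps <- sqrt(.Machine$double.eps)
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
    return(min(1, p))
  }
  stats::wilcox.test(group1, group2, exact = FALSE, correct = TRUE)$p.value
}

#' Permutation-based FDR for the difference between two compartment groups
#'
#' The observed statistic is the absolute difference in means of the two
#' value sets (the absolute-value convention makes the statistic symmetric
#' in the two groups). Each round pools all values and splits them uniformly
#' at random into two groups of the original sizes; the FDR estimate is the
#' fraction of permuted absolute differences at least as large as the
#' observed one (ties count as exceedances, conservatively). With
#' `exhaustive = TRUE` all distinct splits are enumerated instead of random
#' rounds.
#'
#' @param comp1,comp2 numeric value sets (e.g. per-compartment eigenvector
#'   means of two types), both nonempty.
#' @param rounds number of random permutation rounds (default 1000).
#' @param seed integer seed; the caller's RNG state is restored on exit.
#' @param exhaustive enumerate all splits instead of sampling.
#' @return list of class `permutation_result`: `observed`, `permuted`,
#'   `rounds`, `fdr`.
#' @export
permutation_fdr <- function(comp1, comp2, rounds = 1000, seed = NULL,
                            exhaustive = FALSE) {
  stopifnot(length(comp1) > 0, length(comp2) > 0)
  if (!exhaustive && rounds <= 0) stop("rounds must be > 0")
  obs <- abs(mean(comp1) - mean(comp2))
  pool <- c(comp1, comp2)
  n <- length(pool); n1 <- length(comp1)
  if (exhaustive) {
    if (choose(n, n1) > 2e5)
      stop("too many splits for exhaustive enumeration; use random rounds")
    combs <- utils::combn(n, n1)
    perm <- apply(combs, 2, function(idx)
      abs(mean(pool[idx]) - mean(pool[-idx])))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    perm <- replicate(rounds, {
      idx <- sample.int(n, n1)
      abs(mean(pool[idx]) - mean(pool[-idx]))
    })
  }
  eps <- sqrt(.Machine$double.eps)
  res <- list(observed = obs, permuted = perm, rounds = length(perm),
              fdr = mean(perm >= obs - eps))
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed |diff in means| = %.4g, %d rounds, FDR = %.4g\n",
              x$observed, x$rounds, x$fdr))
  invisible(x)
}
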