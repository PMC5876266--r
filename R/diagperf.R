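#' Integer-percent rounding, half away from zero
#'
#' The rounding convention of clinical accuracy tables: `100 * num / den`
#' rounded half away from zero (so 94.5 becomes 95), to `digits` decimals.
#'
#' @param num,den numerator and denominator.
#' @param digits decimal places (default 0).
#' @return numeric; `NA` where `den == 0`.
#' @export
percent_round <- function(num, den, digits = 0) {
  p <- ifelse(den == 0, NA_real_, 100 * num / den)
  m <- 10^digits
  sign(p) * floor(abs(p) * m + 0.5) / m
}

NA_VERDICTS <- c("na_not_depicted", "na_low_contrast", "na_calcified",
                 "na_prosthesis", "na_stent")

is_na_verdict <- function(v) v %in% NA_VERDICTS

#' Confusion counts per vascular region
#'
#' Crosses per-segment verdicts against the reference standard. Segments
#' absent from the reference (not depicted by it) or rated in any of the
#' five non-assessable categories are counted in `excluded_na` and never
#' enter the 2x2 table. Strata are the three anatomical groups plus
#' `"overall"`, so `tp + fp + tn + fn + excluded_na` equals the number of
#' segments offered to each stratum.
#'
#' @param ratings data frame with key columns (`patient`, `leg`, `segment`),
#'   a `group` column, and `verdict` (`"significant"`, `"non_significant"`
#'   or an `na_*` category).
#' @param reference data frame with the same key columns and a logical
#'   `significant` column; segments the reference does not depict are
#'   simply absent (or have `significant = NA`).
#' @return data frame: `stratum`, `tp`, `fp`, `tn`, `fn`, `excluded_na`.
#' @export
tabulate_ratings <- function(ratings, reference) {
  key <- function(d) paste(d$patient, d$leg, d$segment, sep = "\r")
  kr <- key(ratings)
  if (anyDuplicated(kr))
    stop("data error: duplicate segment key in ratings: ",
         gsub("\r", "/", kr[duplicated(kr)][1]))
  kf <- key(reference)
  if (anyDuplicated(kf))
    stop("data error: duplicate segment key in reference")
  truth <- reference$significant[match(kr, kf)]
  strata <- c(stats::na.omit(unique(ratings$group)), "overall")
  res <- lapply(strata, function(st) {
    sel <- if (st == "overall") rep(TRUE, nrow(ratings)) else ratings$group == st
    v <- ratings$verdict[sel]; tr <- truth[sel]
    excl <- is.na(tr) | is_na_verdict(v)
    pos <- v == "significant" & !excl
    neg <- v == "non_significant" & !excl
    data.frame(stratum = st,
               tp = sum(pos & tr), fp = sum(pos & !tr),
               tn = sum(neg & !tr), fn = sum(neg & tr),
               excluded_na = sum(excl), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Diagnostic-performance statistics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`, each reported as
#' (integer percent rounded half away from zero, numerator, denominator).
#' A zero denominator yields an `NA` percent (not calculable), never a
#' division error.
#'
#' @param counts data frame from [tabulate_ratings] (columns `tp`, `fp`,
#'   `tn`, `fn`, optionally `stratum`).
#' @return long data frame: `stratum`, `statistic`, `percent`, `numerator`,
#'   `denominator`.
#' @export
perf_stats <- function(counts) {
  res <- lapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    st <- if ("stratum" %in% names(x)) x$stratum else as.character(i)
    num <- c(sensitivity = x$tp, specificity = x$tn,
             accuracy = x$tp + x$tn, ppv = x$tp, npv = x$tn)
    den <- c(sensitivity = x$tp + x$fn, specificity = x$tn + x$fp,
             accuracy = x$tp + x$fp + x$tn + x$fn,
             ppv = x$tp + x$fp, npv = x$tn + x$fn)
    data.frame(stratum = st, statistic = names(num),
               percent = percent_round(num, den),
               numerator = as.numeric(num), denominator = as.numeric(den),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Paired clustered comparison of two proportions
#'
#' Compares per-segment correctness between two modalities read on the same
#' patients: the statistic is the difference in proportions, and inference
#' accounts for the within-patient clustering of segments by resampling
#' whole patients with replacement (cluster bootstrap). The two-sided
#' p-value is the tail probability of the bootstrap distribution of the
#' difference on the other side of zero, `2 * min(P(D* <= 0), P(D* >= 0))`
#' capped at 1. `method = "robust"` instead fits a binomial GLM with a
#' cluster-robust (sandwich) variance as a cross-check; the bootstrap is
#' the primary contract.
#'
#' @param outcomes_a,outcomes_b logical/0-1 vectors of equal length (e.g.
#'   segment rated correctly yes/no), paired by position.
#' @param clusters patient identifiers, same length; at least 2 distinct.
#' @param reps bootstrap resamples (default 10000).
#' @param seed optional integer seed for the resampling.
#' @param method `"bootstrap"` (contract) or `"robust"`.
#' @return list: `p_value`, `diff` (a minus b), `prop_a`, `prop_b`,
#'   `method`.
#' @export
compare_clustered <- function(outcomes_a, outcomes_b, clusters, reps = 10000,
                              seed = NULL,
                              method = c("bootstrap", "robust")) {
  method <- match.arg(method)
  a <- as.numeric(outcomes_a); b <- as.numeric(outcomes_b)
  if (length(a) != length(b) || length(a) != length(clusters))
    stop("outcomes and clusters must have equal length")
  cl <- as.character(clusters)
  ucl <- unique(cl)
  if (length(ucl) < 2)
    stop("need at least 2 clusters (no between-cluster variance otherwise)")
  prop_a <- mean(a); prop_b <- mean(b)
  obs <- prop_a - prop_b
  if (method == "robust") {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stop("method = 'robust' needs the sandwich package")
    dat <- data.frame(y = c(a, b),
                      mod = rep(c(0, 1), each = length(a)),
                      cl = rep(cl, 2))
    fit <- stats::glm(y ~ mod, family = stats::binomial(), data = dat)
    V <- sandwich::vcovCL(fit, cluster = dat$cl)
    z <- stats::coef(fit)["mod"] / sqrt(V["mod", "mod"])
    p <- 2 * stats::pnorm(-abs(z))
    return(list(p_value = unname(p), diff = obs, prop_a = prop_a,
                prop_b = prop_b, method = "robust"))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- split(seq_along(a), cl)
  # per-cluster sufficient statistics: paired difference sum and size
  dsum <- vapply(idx, function(i) sum(a[i] - b[i]), numeric(1))
  nsz <- vapply(idx, function(i) length(i), numeric(1))
  # canonical order: the draw depends only on the multiset of cluster
  # statistics, making the p-value invariant to cluster relabeling
  ord <- order(dsum, nsz)
  dsum <- dsum[ord]; nsz <- nsz[ord]
  k <- length(idx)
  pick <- matrix(sample.int(k, k * reps, replace = TRUE), nrow = reps)
  bd <- matrix(dsum[pick], nrow = reps)
  bn <- matrix(nsz[pick], nrow = reps)
  boot <- rowSums(bd) / rowSums(bn)
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  list(p_value = p, diff = obs, prop_a = prop_a, prop_b = prop_b,
       method = "bootstrap")
}

#' Absolute inter-reader agreement
#'
#' Fraction of segments on which two readers give the same verdict, after
#' excluding every segment that either reader rated in a non-assessable
#' category (which is why agreement denominators differ from the
#' performance-table denominators).
#'
#' @param r1,r2 verdict vectors aligned by position (same segments).
#' @param digits rounding decimals for the percent (default 0).
#' @return list: `percent` (rounded half away from zero), `numerator`,
#'   `denominator` (`percent = NA` when no segment is comparable).
#' @export
agreement <- function(r1, r2, digits = 0) {
  if (length(r1) != length(r2)) stop("verdict vectors must align")
  keep <- !is_na_verdict(r1) & !is_na_verdict(r2)
  den <- sum(keep)
  num <- sum(r1[keep] == r2[keep])
  list(percent = percent_round(num, den, digits), numerator = num,
       denominator = den)
}
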