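mk_ratings <- function(verdicts, groups = "iliac", patients = 1,
                       legs = "left") {
  n <- length(verdicts)
  data.frame(patient = rep_len(patients, n), leg = rep_len(legs, n),
             segment = paste0("S", seq_len(n)), group = rep_len(groups, n),
             verdict = verdicts, stringsAsFactors = FALSE)
}

mk_reference <- function(ratings, truth) {
  data.frame(patient = ratings$patient, leg = ratings$leg,
             segment = ratings$segment, significant = truth,
             stringsAsFactors = FALSE)
}

test_that("tabulation matches verdicts against the reference standard", {
  r <- mk_ratings(rep("significant", 10))
  ref <- mk_reference(r, rep(TRUE, 10))
  tab <- tabulate_ratings(r, ref)
  ov <- tab[tab$stratum == "overall", ]
  expect_equal(unlist(ov[c("tp", "fp", "tn", "fn", "excluded_na")]),
               c(tp = 10, fp = 0, tn = 0, fn = 0, excluded_na = 0))
  # one non-assessable segment is excluded, not counted in the 2x2
  r$verdict[4] <- "na_calcified"
  tab2 <- tabulate_ratings(r, ref)
  ov2 <- tab2[tab2$stratum == "overall", ]
  expect_equal(ov2$tp, 9)
  expect_equal(ov2$excluded_na, 1)
  # a segment the reference does not depict is excluded as well
  ref3 <- ref[-2, ]
  ov3 <- tabulate_ratings(r, ref3)
  ov3 <- ov3[ov3$stratum == "overall", ]
  expect_equal(ov3$tp, 8)
  expect_equal(ov3$excluded_na, 2)
  # duplicate keys are a data error
  rd <- rbind(r, r[1, ])
  expect_error(tabulate_ratings(rd, ref), "duplicate segment key")
})

test_that("tabulation conserves segments across strata", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 200
    r <- mk_ratings(sample(c("significant", "non_significant",
                             mpcpr:::NA_VERDICTS), n, replace = TRUE),
                    groups = sample(c("iliac", "femoro-popliteal",
                                      "infra-popliteal"), n, replace = TRUE),
                    patients = sample(1:10, n, replace = TRUE))
    r$segment <- paste0("S", seq_len(n))
    ref <- mk_reference(r, sample(c(TRUE, FALSE, NA), n, replace = TRUE))
    tab <- tabulate_ratings(r, ref)
    ov <- tab[tab$stratum == "overall", ]
    expect_equal(ov$tp + ov$fp + ov$tn + ov$fn + ov$excluded_na, n)
    grp <- tab[tab$stratum != "overall", ]
    expect_equal(sum(grp$tp + grp$fp + grp$tn + grp$fn + grp$excluded_na), n)
  }
})

test_that("performance statistics reproduce the benchmark overall row", {
  counts <- data.frame(stratum = "overall", tp = 220, fp = 36, tn = 566,
                       fn = 22)
  ps <- perf_stats(counts)
  get <- function(s) ps$percent[ps$statistic == s]
  expect_equal(get("sensitivity"), 91) # 220/242
  expect_equal(get("specificity"), 94) # 566/602
  expect_equal(get("accuracy"), 93)    # 786/844
  expect_equal(get("ppv"), 86)         # 220/256
  expect_equal(get("npv"), 96)
  expect_equal(ps$numerator[ps$statistic == "sensitivity"], 220)
  expect_equal(ps$denominator[ps$statistic == "sensitivity"], 242)
})

test_that("empty strata are not calculable rather than division errors", {
  ps <- perf_stats(data.frame(tp = 0, fp = 0, tn = 0, fn = 0))
  expect_true(all(is.na(ps$percent)))
})

test_that("rounding is half away from zero at any precision", {
  expect_equal(percent_round(67, 68), 99)    # 98.53
  expect_equal(percent_round(312, 330), 95)  # 94.545 rounds up
  expect_equal(percent_round(44, 888, 1), 5.0)
  expect_equal(percent_round(76, 888, 1), 8.6)
  expect_equal(percent_round(1, 0), NA_real_)
})

test_that("agreement excludes non-assessable segments from either reader", {
  r1 <- rep("significant", 10)
  expect_equal(agreement(r1, r1)$percent, 100)
  r2 <- rep("non_significant", 10)
  expect_equal(agreement(r1, r2)$percent, 0)
  r1[1] <- "na_calcified"; r2 <- r1; r2[2] <- "na_stent"
  ag <- agreement(r1, r2)
  expect_equal(ag$denominator, 8)
  expect_equal(ag$percent, 100)
  expect_true(is.na(agreement(rep("na_stent", 3), rep("na_stent", 3))$percent))
})

test_that("identical outcomes give p = 1 and a single cluster errors", {
  set.seed(31)
  a <- rbinom(100, 1, 0.9)
  cl <- rep(1:10, each = 10)
  expect_equal(compare_clustered(a, a, cl, reps = 500, seed = 1)$p_value, 1)
  expect_error(compare_clustered(a, a, rep(1, 100)), "2 clusters")
  expect_error(compare_clustered(a, a[1:50], cl), "equal length")
})

test_that("the bootstrap p is invariant to cluster relabeling and order", {
  set.seed(32)
  a <- rbinom(200, 1, 0.92); b <- rbinom(200, 1, 0.86)
  cl <- rep(1:20, each = 10)
  p1 <- compare_clustered(a, b, cl, reps = 2000, seed = 9)$p_value
  # relabel clusters and permute segments within clusters
  perm <- order(rep(sample(20), each = 10), sample(200))
  relab <- sample(LETTERS[1:20])[match(cl, 1:20)]
  p2 <- compare_clustered(a[perm], b[perm], relab[perm], reps = 2000,
                          seed = 9)$p_value
  expect_equal(p1, p2)
})

test_that("the clustered test detects a real accuracy difference", {
  set.seed(33)
  hits <- replicate(100, {
    cl <- rep(1:40, each = 20)
    a <- rbinom(800, 1, 0.93); b <- rbinom(800, 1, 0.85)
    compare_clustered(a, b, cl, reps = 1000)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the sandwich-variance variant agrees in direction", {
  set.seed(34)
  cl <- rep(1:40, each = 20)
  a <- rbinom(800, 1, 0.95); b <- rbinom(800, 1, 0.80)
  pb <- compare_clustered(a, b, cl, reps = 2000, seed = 2)
  pr <- compare_clustered(a, b, cl, method = "robust")
  expect_lt(pb$p_value, 0.05)
  expect_lt(pr$p_value, 0.05)
  expect_equal(pb$diff, pr$diff)
})
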