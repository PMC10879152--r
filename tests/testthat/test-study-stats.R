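test_that("rating summaries are medians +/- SD, invariant to row order", {
  tab <- data.frame(participant = "S1",
                    encoding = rep(c("BIOM_FULL", "LIN"), each = 5),
                    naturalness = c(4, 4, 4, 4, 4, 1, 2, 3, 4, 5))
  s <- summarizeRatings(tab)
  expect_equal(s$median[s$encoding == "BIOM_FULL"], 4)
  expect_equal(s$sd[s$encoding == "BIOM_FULL"], 0)
  expect_equal(s$median[s$encoding == "LIN"], 3)

  shuffled <- tab[sample(nrow(tab)), ]
  s2 <- summarizeRatings(shuffled)
  expect_equal(s2[order(s2$encoding), ], s[order(s$encoding), ],
               ignore_attr = TRUE)
  expect_error(summarizeRatings(tab, value = "nope"), "value")
})

test_that("group comparison reproduces the brute-force H statistic", {
  # enumeration oracle on small samples with ties: tie-corrected H from the
  # rank definition must match the implementation exactly
  bruteH <- function(groups) {
    values <- unlist(groups)
    r <- rank(values)
    N <- length(values)
    idx <- rep(seq_along(groups), lengths(groups))
    H <- 12 / (N * (N + 1)) *
      sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
    tie <- table(values)
    H / (1 - sum(tie^3 - tie) / (N^3 - N))
  }
  cases <- list(
    list(a = c(1, 2, 2), b = c(2, 3), c = c(1, 4, 4)),
    list(a = c(5, 5, 7), b = c(6, 8, 8)),
    list(a = c(0.1, 0.4), b = c(0.2, 0.4), c = c(0.3, 0.9)))
  for (cs in cases) {
    gc <- compareGroups(cs)
    expect_equal(gc@statistic, bruteH(cs), tolerance = 1e-12)
  }
})

test_that("group comparison has sane null behaviour, power and post-hocs", {
  same <- compareGroups(list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5)))
  expect_gt(same@pValue, 0.9)

  set.seed(1)
  strong <- compareGroups(list(a = rnorm(50), b = rnorm(50, 3)))
  expect_lt(strong@pValue, 0.001)
  expect_gt(strong@effectSizeF, 0.5)

  set.seed(2)
  three <- compareGroups(list(a = rnorm(20), b = rnorm(20, 1),
                              c = rnorm(20, 2)))
  expect_true(all(three@pairwise$pAdjusted >= three@pairwise$p - 1e-15))
  expect_true(all(three@pairwise$pAdjusted <= 1))
  expect_equal(nrow(three@pairwise), 3)
  expect_equal(three@groupSummary$n, c(20, 20, 20))

  expect_error(compareGroups(list(a = rep(2, 5), b = rep(2, 4))),
               "degenerate")
  expect_error(compareGroups(list(a = 1:5)), "length")
  expect_error(compareGroups(list(a = 1:5, b = 2)), "two observations")
})

test_that("normality screen has its nominal level and detects skew", {
  rejections <- vapply(1:10, function(s) {
    set.seed(s)
    normalityScreen(rnorm(1e4))$reject
  }, integer(1))
  expect_gte(sum(rejections == 0), 9)

  set.seed(3)
  expect_equal(normalityScreen(rexp(1e4))$reject, 1L)

  set.seed(4)
  sc <- normalityScreen(rnorm(2000))
  dev <- abs(sc$qq$theoretical - sc$qq$sample)
  expect_lt(median(dev), 0.05)
  expect_equal(sum(sc$histogram$counts), 2000)
  expect_error(normalityScreen(1:3), "at least 5")
})

test_that("learning effect is the Spearman rank correlation", {
  expect_equal(learningEffect(c(1, 2, 5, 9)), 1)
  expect_equal(learningEffect(c(9, 7, 3, 1)), -1)
  # brute-force rank formula oracle on small n
  set.seed(5)
  for (i in 1:5) {
    x <- sample(20, 7)
    rho <- 1 - 6 * sum((rank(x) - rank(seq_len(7)))^2) / (7 * (7^2 - 1))
    expect_equal(learningEffect(x), rho, tolerance = 1e-12)
  }
  expect_warning(out <- learningEffect(rep(4, 5)), "constant")
  expect_true(is.na(out))
  expect_error(learningEffect(c(1, 2)), "three sessions")
})

test_that("tables round-trip through CSV with schema validation", {
  dir <- withr::local_tempdir()
  ratings <- data.frame(participant = "S1", site = "AS3", region = "Heel",
                        encoding = c("BIOM_FULL", "LIN"), trial = 1:2,
                        naturalness = c(3, 1))
  rp <- file.path(dir, "ratings.csv")
  write.csv(ratings, rp, row.names = FALSE)
  expect_equal(readRatingsTable(rp)$naturalness, c(3, 1))

  bad <- ratings; bad$naturalness <- c(3, 7)
  write.csv(bad, rp, row.names = FALSE)
  expect_error(readRatingsTable(rp), "\\[0, 5\\]")

  # YAML column mapping adapts foreign headers
  foreign <- data.frame(subj = "S1", site = "AS3", region = "Heel",
                        enc = "BIOM_FULL", trial = 1, vas = 2.5)
  fp <- file.path(dir, "foreign.csv")
  write.csv(foreign, fp, row.names = FALSE)
  mp <- file.path(dir, "map.yaml")
  writeLines(c("participant: subj", "encoding: enc", "naturalness: vas"), mp)
  mapped <- readRatingsTable(fp, mappingYaml = mp)
  expect_equal(mapped$naturalness, 2.5)

  tasks <- data.frame(participant = "S1", condition = "BIOM", session = 1:3,
                      metric = "laps_per_session", value = c(5, 4.9, 4.8))
  tp <- file.path(dir, "tasks.csv")
  write.csv(tasks, tp, row.names = FALSE)
  expect_equal(nrow(readTaskTable(tp)), 3)

  bench <- depositedBenchmarks(dir = {
    write.csv(ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
    dir
  })
  expect_true(any(bench$naturalness$family == "biomimetic"))
  expect_equal(bench$stairSpeed$laps_per_session[1], mean(c(5, 4.9, 4.8)))
})

test_that("stim trains round-trip through CSV", {
  dir <- withr::local_tempdir()
  tr <- makeSinusoidalPw(50, 1, pwMinUs = 100, pwMaxUs = 500)
  path <- file.path(dir, "train.csv")
  writeStimTrainCsv(tr, path)
  back <- readStimTrainCsv(path)
  expect_equal(onsets(back), onsets(tr))
  expect_equal(back@pulseWidthUs, tr@pulseWidthUs)
  expect_identical(back@encoding, "SINUS_PW")
  expect_equal(chargePerPulse(back), chargePerPulse(tr))
})
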