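test_that("the GCi is the log prediction-error ratio", {
  expect_equal(gci(c(1, 1, 1), c(1, 1, 1)), c(0, 0, 0))
  expect_equal(gci(1, 2), log(2))
  expect_error(gci(c(1, 0), c(1, 1)), "timepoint 2")
  expect_error(gci(1, c(1, 2)), "equal length")
  # time-averaged GCi agrees with the classic OLS log variance-ratio
  # Granger statistic on stationary data
  ts <- simulateMvar(twoChannelNet(coupling = 0.5, self = 0.4),
                     4000, seed = 1)
  cfg <- analysisConfig(modelOrder = 1,
                        windowMs = c(100, ncol(seriesValues(ts)) - 1))
  g <- edgeGci(ts, "ch1", "ch2", cfg)
  v <- seriesValues(ts)
  n <- ncol(v)
  rFull <- resid(lm(v[2, 2:n] ~ t(v[, 1:(n - 1)]) - 1))
  rRed <- resid(lm(v[2, 2:n] ~ v[2, 1:(n - 1)] - 1))
  olsG <- 0.5 * log(var(rRed) / var(rFull))  # log SD ratio
  expect_lt(abs(mean(gciValues(g)) - olsG), 0.01)
})

test_that("significant timepoints are counted by threshold inside the window", {
  mk <- function(p) new("GciSeries", source = "a", target = "b",
                        condition = "", gci = numeric(length(p)), p = p,
                        sig = p < 0.05, tIndex = seq_along(p),
                        samplingRate = 1000, t0Ms = 0)
  cfg <- analysisConfig()
  expect_equal(countSignificant(mk(rep(1, 50)), cfg), 0L)
  expect_equal(countSignificant(mk(rep(0, 401)), cfg), 401L)
  p <- rep(0.5, 100); p[sample(100, 40)] <- 0.01
  expect_equal(countSignificant(mk(p), cfg), 40L)
})

test_that("the condition comparison is an exact conditional binomial", {
  # exact summation oracle for the two-sided tail
  twoSided <- function(a, b) {
    k <- a + b
    if (k == 0) return(1)
    tail <- sum(dbinom(0:min(a, b), k, 0.5))
    min(1, 2 * tail)
  }
  cases <- rbind(c(40, 10), c(10, 40), c(25, 25), c(0, 0), c(401, 0),
                 c(3, 7), c(100, 120))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, 1]; b <- cases[i, 2]
    res <- compareConditions(a, b, 401)
    expect_equal(res$p, twoSided(a, b), info = paste(a, b))
  }
  expect_equal(compareConditions(25, 25, 401)$p, 1)
  expect_equal(compareConditions(0, 0, 401)$p, 1)
  expect_equal(compareConditions(0, 0, 401)$favored, "tie")
  # symmetry: swapping counts preserves p, flips the favored side
  r1 <- compareConditions(40, 10, 401)
  r2 <- compareConditions(10, 40, 401)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$favored, "A")
  expect_equal(r2$favored, "B")
})

test_that("FDR control follows the Benjamini-Hochberg step-up rule", {
  cfg <- analysisConfig()
  expect_true(all(fdrCorrect(rep(0.001, 10), cfg)))
  expect_false(any(fdrCorrect(rep(0.9, 10), cfg)))
  # hand-executed step-up: ranks 1..5, cutoffs k/5 * 0.05
  dec <- fdrCorrect(c(0.01, 0.02, 0.03, 0.2, 0.9), cfg)
  expect_identical(dec, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(fdrCorrect(numeric(0), cfg), logical(0))
  expect_error(fdrCorrect(c(0.5, 1.2), cfg), "0, 1")
})

test_that("bootstrap significance flags a strong edge and spares its reverse", {
  cfg <- analysisConfig(nBootstrap = 100)
  ks <- kalmanSettings()
  ts <- simulateMvar(twoChannelNet(coupling = 0.6, self = 0.4),
                     501, seed = 2)
  fm <- fitFullModel(ts, cfg, ks)
  gTrue <- edgeSignificance(ts, "ch1", "ch2", cfg, ks, seed = 3,
                            fullModels = fm)
  expect_gt(mean(gTrue@sig), 0.9)
  gNull <- edgeSignificance(ts, "ch2", "ch1", cfg, ks, seed = 4,
                            fullModels = fm)
  expect_lt(mean(gNull@sig), 0.5)
  expect_true(all(gciPvalues(gTrue) >= 0 & gciPvalues(gTrue) <= 1))
})

test_that("GCi for an edge ignores permutation of unrelated channels", {
  # 3 channels; edge 1 -> 2 assessed with channel 3 relabeled/permuted
  A <- array(0, c(3, 3, 1)); diag(A[, , 1]) <- 0.4; A[2, 1, 1] <- 0.5
  ts <- simulateMvar(groundTruthNetwork(A), 400, seed = 5)
  cfg <- analysisConfig()
  g <- edgeGci(ts, "ch1", "ch2", cfg)
  v <- seriesValues(ts)[c(3, 1, 2), ]
  tsPerm <- multiTimeSeries(v, labels = c("ch3", "ch1", "ch2"))
  gPerm <- edgeGci(tsPerm, "ch1", "ch2", cfg)
  expect_equal(gciValues(gPerm), gciValues(g))
})

test_that("influence reports filter by focus and direction", {
  cmp <- data.frame(source = c("a", "b", "c", "x"),
                    target = c("x", "x", "x", "a"),
                    count_a = c(50, 40, 10, 30),
                    count_b = c(10, 35, 10, 2),
                    n_window = 401,
                    diff = c(40, 5, 0, 28),
                    binomial_p = c(1e-6, 0.5, 1, 1e-4),
                    favored_condition = c("T", "T", "tie", "T"),
                    fdr_significant = c(TRUE, FALSE, FALSE, TRUE))
  onto <- influenceReport(cmp, "x", "onto")
  expect_identical(onto$source, "a")
  from <- influenceReport(cmp, "x", "from")
  expect_identical(from$target, "a")
  none <- influenceReport(cmp, "b", "from")
  expect_equal(nrow(none), 0L)
  expect_error(influenceReport(cmp, "zz"), "unknown focus")
  # ranking follows the count difference
  cmp2 <- cmp; cmp2$fdr_significant <- TRUE
  r <- influenceReport(cmp2, "x", "onto")
  expect_identical(r$source, c("a", "b", "c"))
})

test_that("two-condition comparison joins counts and controls FDR", {
  mkRes <- function(counts, cond) {
    list(edges = list(), condition = cond, nWindow = 401,
         counts = data.frame(source = c("a", "a", "b"),
                             target = c("b", "c", "a"),
                             count = counts, edge_p = 0.5))
  }
  cmp <- compareConnectivity(mkRes(c(300, 10, 5), "Trained"),
                             mkRes(c(50, 12, 5), "Naive"),
                             analysisConfig())
  expect_equal(cmp$diff, c(250, -2, 0))
  expect_equal(cmp$favored_condition, c("Trained", "Naive", "tie"))
  expect_true(cmp$fdr_significant[1])
  expect_false(any(cmp$fdr_significant[2:3]))
  expect_equal(cmp$binomial_p[3], 1)
})
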