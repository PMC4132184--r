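test_that("count reconstruction rounds half-up and repairs residuals deterministically", {
  expect_equal(unname(countsFromPercent(c(100, 0, 0, 0, 0), 102)),
               c(102L, 0L, 0L, 0L, 0L))
  expect_equal(unname(countsFromPercent(c(99, 0, 1, 0, 0), 102)),
               c(101L, 0L, 1L, 0L, 0L))
  cc <- countsFromPercent(c(25, 13, 11, 46, 4), 114)
  expect_equal(sum(cc), 114L)
  expect_equal(unname(cc[1]), 29L)  # 28.5 rounds half-up, no repair needed

  ## residual repair: (50,50) at n=3 -> provisional (2,2); the tie on
  ## fractional parts breaks by column order, so 'normal' gives one back
  expect_equal(unname(countsFromPercent(c(50, 50, 0, 0, 0), 3)),
               c(1L, 2L, 0L, 0L, 0L))
  expect_error(countsFromPercent(c(200, 200, 0, 0, 0), 10), "inconsistent")
  expect_error(countsFromPercent(c(99, 0, 1, 0, 0), 0), ">= 1")
  expect_error(countsFromPercent(c(-1, 0, 1, 0, 0), 10), "non-negative")
})

test_that("reconstruction inverts the printed percentages of the screen table", {
  tab <- read.delim(screenFixturePath(), comment.char = "#")
  for (i in seq_len(nrow(tab))) {
    pct <- as.numeric(tab[i, c("normal", "extra_turn", "wandering",
                               "overshoot", "other")])
    cts <- countsFromPercent(pct, tab$n[i])
    expect_equal(sum(cts), tab$n[i])
    expect_equal(unname(percentsFromCounts(cts)), as.integer(pct))
  }
  ## and for random integer-percent tables at large n, where rounding is
  ## lossless enough to invert exactly
  set.seed(7)
  for (r in 1:25) {
    parts <- sort(sample(0:100, 4))
    pct <- diff(c(0, parts, 100))
    n <- sample(400:2000, 1)
    expect_equal(unname(percentsFromCounts(countsFromPercent(pct, n))),
                 as.integer(pct))
  }
})

test_that("fisher test of normal vs defective matches hand-derived values and tiers", {
  same <- data.frame(treatment = "x", normal = 50L, extra_turn = 0L,
                     wandering = 0L, overshoot = 50L, other = 0L, n = 100L)
  ft <- fisherNormalVsControl(same, same)
  expect_equal(ft$p_two_sided, 1)
  expect_equal(ft$tier, "ns")

  ## [[3,1],[1,3]]: full enumeration over C(8,4)=70 tables gives 34/70
  ft2 <- fisherNormalVsControl(c(normal = 3, n = 4), c(normal = 1, n = 4))
  expect_equal(ft2$p_two_sided, 34 / 70, tolerance = 1e-12)

  expect_error(fisherNormalVsControl(c(normal = 0, n = 0),
                                     c(normal = 1, n = 2)), "degenerate")
  expect_error(fisherNormalVsControl(c(normal = 5, n = 4),
                                     c(normal = 1, n = 2)), "exceeds")
})

test_that("fisher p is invariant to swapping group order and outcome columns", {
  set.seed(3)
  for (r in 1:20) {
    a <- sample(0:30, 1); n1 <- a + sample(1:30, 1)
    b <- sample(0:30, 1); n2 <- b + sample(1:30, 1)
    p1 <- fisherNormalVsControl(c(normal = a, n = n1),
                                c(normal = b, n = n2))$p_two_sided
    p2 <- fisherNormalVsControl(c(normal = b, n = n2),
                                c(normal = a, n = n1))$p_two_sided
    ## swapping outcome columns = testing defective instead of normal
    p3 <- fisherNormalVsControl(c(normal = n1 - a, n = n1),
                                c(normal = n2 - b, n = n2))$p_two_sided
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("two-sided p equals the brute-force hypergeometric enumeration on all tables up to n=40", {
  maxN <- 40L
  worst <- 0
  for (n in 2:maxN) {
    for (n1 in 1:(n - 1)) {
      n2 <- n - n1
      for (a in 0:n1) for (b in 0:n2) {
        tab <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
        pImpl <- fisherNormalVsControl(c(normal = a, n = n1),
                                       c(normal = b, n = n2))$p_two_sided
        worst <- max(worst, abs(pImpl - min(1, bruteFisherP(tab))))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("screen summary counts significant interactors and keeps unscored treatments out", {
  ctrl <- data.frame(treatment = "control", normal = 99L, extra_turn = 0L,
                     wandering = 0L, overshoot = 1L, other = 0L, n = 100L)
  trts <- data.frame(
    treatment = c("hit", "null", "arrested"),
    normal = c(40L, 98L, NA), extra_turn = c(10L, 1L, NA),
    wandering = c(10L, 0L, NA), overshoot = c(35L, 1L, NA),
    other = c(5L, 0L, NA), n = c(100L, 100L, NA))
  ss <- screenSummary(trts, ctrl, interactorIds = c("hit", "null", "arrested"))
  expect_equal(nSignificant(ss), 1L)
  expect_equal(ss@totalScreened, 2L)
  res <- screenResults(ss)
  expect_equal(res$tier[res$treatment == "arrested"], "unscored")
  expect_equal(res$tier[res$treatment == "hit"], "four_star")

  ## identical treatments yield no significance
  nullTrt <- ctrl; nullTrt$treatment <- "t1"
  expect_equal(nSignificant(screenSummary(nullTrt, ctrl)), 0L)
  dup <- rbind(nullTrt, nullTrt)
  expect_error(screenSummary(dup, ctrl), "duplicated")
})

test_that("screen power: simulated hits at halved normal probability are recovered", {
  ## hit rows halve the control normal-call probability (0.99 -> 0.495),
  ## defect mass dominated by overshoot; with n=100 animals per treatment
  ## the count of significant calls should recover the number of planted
  ## hits in >= 90% of simulations
  k <- 4L
  recovered <- 0L
  nSim <- 200L
  for (s in seq_len(nSim)) {
    sim <- makeScreen(nTreatments = 12L, nHits = k,
                      animalsPerTreatment = 100L,
                      hitProbs = c(0.495, 0.065, 0.06, 0.33, 0.05),
                      seed = 5000 + s)
    ctrl <- sim$counts[sim$counts$treatment == "control", ]
    trts <- sim$counts[sim$counts$treatment != "control", ]
    ss <- screenSummary(trts, ctrl)
    res <- screenResults(ss)
    called <- res$treatment[res$tier != "ns"]
    if (length(called) == k && setequal(called, sim$hitIds))
      recovered <- recovered + 1L
  }
  expect_gte(recovered / nSim, 0.9)
})
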