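test_that("pair contingency enumerates the 2x2 cells and is symmetric", {
  st <- make_stratum(list(c("E11", "I10"), "E11", "I10", "K29"))
  ct <- pair_contingency(st, "E11", "I10")
  expect_equal(ct[c("a", "b", "c", "d")], list(a = 1, b = 1, c = 1, d = 1))
  expect_equal(ct$n, 4)
  swapped <- pair_contingency(st, "I10", "E11")
  expect_equal(swapped$a, ct$a)
  expect_equal(swapped$d, ct$d)
  expect_equal(swapped$b, ct$c)
  expect_equal(swapped$c, ct$b)
  # never co-occurring
  expect_equal(pair_contingency(st, "E11", "K29")$a, 0)
  expect_error(pair_contingency(st, "E11", "Z99"), "Z99")
})

test_that("association estimate equals the cross-product ratio and glm MLE", {
  est <- estimate_association(30, 20, 10, 940)
  expect_equal(est$or, 141)
  # independence table
  expect_equal(estimate_association(25, 25, 25, 25)$or, 1)
  # zero cell: non-finite, unusable
  z <- estimate_association(10, 0, 5, 85)
  expect_false(z$usable)
  expect_true(is.na(z$p))
  # a = 0: odds ratio 0, never a candidate
  expect_equal(estimate_association(0, 10, 5, 85)$or, 0)

  # dual route: the closed form must agree with the logistic fit (MLE,
  # likelihood-ratio deviance test, and Wald test)
  for (tab in list(c(30, 20, 10, 940), c(12, 7, 9, 101), c(3, 5, 8, 13))) {
    est <- estimate_association(tab[1], tab[2], tab[3], tab[4])
    y <- rep(c(1, 0, 1, 0), tab)
    x <- rep(c(1, 1, 0, 0), tab)
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    expect_equal(est$or, unname(exp(coef(fit)["x"])), tolerance = 1e-8)
    p_lrt <- pchisq(fit$null.deviance - fit$deviance, df = 1,
                    lower.tail = FALSE)
    expect_equal(est$p, p_lrt, tolerance = 1e-6)
    expect_equal(est$p_wald, summary(fit)$coefficients["x", 4],
                 tolerance = 1e-6)
  }
})

test_that("Bonferroni threshold divides alpha by the OR>1 pattern count", {
  expect_equal(bonferroni_threshold(rep(2, 1000))$threshold, 5e-5)
  expect_equal(bonferroni_threshold(2)$threshold, 0.05)
  or <- c(rep(2, 200), rep(0.5, 300))
  bt <- bonferroni_threshold(or)
  expect_equal(bt$n_bonferroni, 200)
  expect_equal(bt$threshold, 2.5e-4)
  expect_true(is.na(bonferroni_threshold(c(0.5, 0.9))$threshold))
})

test_that("network edges are exactly the pairs passing all three criteria", {
  # planted strong pair A00-C00 plus weak/no association elsewhere
  set.seed(1)
  n <- 5000
  cells <- joint_from_or(0.10, 0.12, 8)
  cell <- sample.int(4, n, replace = TRUE, prob = cells)
  codes <- Map(function(ab, z1, z2) {
    v <- c(if (ab %in% c(1, 2)) "A00", if (ab %in% c(1, 3)) "C00",
           if (z1) "E11", if (z2) "I10", "K29")
    v
  }, cell, runif(n) < 0.1, runif(n) < 0.1)
  st <- make_stratum(codes)
  net <- build_network(st)
  expect_s3_class(net, "mm_network")
  keys <- paste(net$edges$x, net$edges$y)
  expect_true("A00 C00" %in% keys)
  # E11 and I10 are independent of everything: their pair is not an edge
  expect_false("E11 I10" %in% keys)
  # nodes include every observed disease, even isolated ones
  expect_setequal(net$nodes, c("A00", "C00", "E11", "I10", "K29"))
  # every accepted edge passes the criteria strictly
  thr <- net$criteria$threshold
  expect_true(all(net$edges$or > 1))
  expect_true(all(net$edges$p < thr))
  expect_true(all(net$edges$prevalence > net$criteria$prevalence_floor))
  expect_equal(net$total_pattern_frequency, sum(net$edges$frequency))
})

test_that("edge set is invariant to record order", {
  set.seed(2)
  codes <- lapply(1:800, function(i) {
    code_pool(12)[runif(12) < c(rep(0.25, 4), rep(0.08, 8))]
  })
  codes <- codes[lengths(codes) > 0]
  st <- make_stratum(codes)
  net1 <- build_network(st)
  perm <- sample(nrow(st))
  st2 <- make_stratum(codes[perm])
  net2 <- build_network(st2)
  key <- function(nn) sort(paste(nn$edges$x, nn$edges$y))
  expect_equal(key(net1), key(net2))
  expect_equal(net1$criteria$n_bonferroni, net2$criteria$n_bonferroni)
})

test_that("tightening any criterion never adds edges", {
  set.seed(3)
  codes <- lapply(1:1500, function(i) {
    code_pool(10)[runif(10) < c(rep(0.3, 3), rep(0.1, 7))]
  })
  codes <- codes[lengths(codes) > 0]
  st <- make_stratum(codes)
  base <- build_network(st)
  key <- function(nn) paste(nn$edges$x, nn$edges$y)
  tighter <- list(
    network_criteria(alpha = 0.01),
    network_criteria(or_floor = 1.5),
    network_criteria(prevalence_floor = 5e-3)
  )
  for (cr in tighter) {
    nt <- build_network(st, criteria = cr)
    expect_true(all(key(nt) %in% key(base)))
  }
})
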