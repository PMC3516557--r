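test_that("hypergeometric upper tail matches enumeration and is monotone", {
  expect_identical(hypergeometric_upper_tail(0, 5, 4, 10), 1)
  # (C(4,3) C(6,2) + C(4,4) C(6,1)) / C(10,5) = 66/252
  expect_equal(hypergeometric_upper_tail(3, 5, 4, 10), 66 / 252,
               tolerance = 1e-12)
  # small exhaustive sweep against the combinatorial oracle
  for (N in c(7, 12, 20)) for (K in c(0, 3, N %/% 2, N)) for (n in c(1, N %/% 3, N)) {
    for (k in max(0, n + K - N):min(n, K)) {
      expect_equal(hypergeometric_upper_tail(k, n, K, N),
                   enum_upper_tail(k, n, K, N), tolerance = 1e-12)
    }
  }
  ks <- 0:4
  ps <- hypergeometric_upper_tail(ks, 5, 4, 10)
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeometric_upper_tail(5, 5, 4, 10), "require")
  expect_error(hypergeometric_upper_tail(1, 11, 4, 10), "require")
})

test_that("collection enrichment honors its contracts", {
  bg <- sprintf("G%03d", 1:100)
  coll <- list(S1 = bg[1:10], S2 = bg[11:40], ALL = bg)
  r0 <- enrich_collection(character(0), coll, bg)
  expect_true(all(r0$k == 0) && all(r0$p_value == 1) && !any(r0$significant))

  r <- enrich_collection(bg[1:20], coll, bg, collection_label = "KEGG")
  whole <- r[r$set_name == "ALL", ]
  expect_identical(whole$k, whole$n)
  expect_equal(whole$p_value, 1)

  expect_warning(rw <- enrich_collection(c(bg[1:5], "MISSING"), coll, bg),
                 "outside the background")
  expect_identical(unique(rw$n), 5L)

  expect_error(enrich_collection(bg[1:5], coll, character(0)), "empty")
  # percent_mapped always recomputable from k and K
  expect_equal(r$percent_mapped, 100 * r$k / r$K)
  # sorted by p then name
  expect_false(is.unsorted(r$p_value))
})

test_that("per-collection alphas drive the significance flag", {
  bg <- sprintf("G%03d", 1:200)
  query <- bg[1:30]
  coll <- list(ENR = c(bg[1:4], bg[150:155]))   # overlap with 0.01 < p < 0.1
  p <- enrich_collection(query, coll, bg, collection_label = "KEGG")$p_value
  pol <- significance_policy()
  expect_identical(
    enrich_collection(query, coll, bg, pol, "C2")$significant, p < 0.01)
  expect_identical(
    enrich_collection(query, coll, bg, pol, "KEGG")$significant, p < 0.1)
})

test_that("GO pruning filters big terms and keeps max-overlap chain members", {
  mk <- function(name, k, K, p, sig = TRUE) {
    data.frame(set_name = name, collection = "GO", k = k, K = K, n = 50,
               N = 1000, p_value = p, percent_mapped = 100 * k / K,
               significant = sig, member_hits = "", stringsAsFactors = FALSE)
  }
  res <- rbind(mk("parent", 10, 60, 0.01), mk("child", 4, 20, 0.005),
               mk("big", 12, 501, 1e-6), mk("other", 3, 30, 0.2, sig = FALSE))
  edges <- data.frame(child_id = "child", parent_id = "parent",
                      stringsAsFactors = FALSE)

  none <- prune_go_results(res, edges[0, , drop = FALSE])
  expect_identical(sort(none$results$set_name), c("child", "other", "parent"))

  pr <- prune_go_results(res, edges)
  expect_true("parent" %in% pr$results$set_name)     # max overlap wins
  expect_false("child" %in% pr$results$set_name)
  expect_false("big" %in% pr$results$set_name)       # size filter beats tiny p
  expect_true("other" %in% pr$results$set_name)      # non-significant untouched
  expect_identical(sort(pr$log$reason), c("hierarchy", "term_size"))
  # no removal without a retained ancestor/descendant
  h <- pr$log[pr$log$reason == "hierarchy", ]
  expect_true(all(grepl("parent", h$detail)))

  cyc <- data.frame(child_id = c("a", "b"), parent_id = c("b", "a"))
  expect_error(prune_go_results(rbind(mk("a", 2, 5, 0.01), mk("b", 2, 5, 0.02)),
                                cyc), "cycle")
})

test_that("pruning works across transitive ancestor chains", {
  mk <- function(name, k, p) {
    data.frame(set_name = name, collection = "GO", k = k, K = 30, n = 50,
               N = 1000, p_value = p, percent_mapped = 100 * k / 30,
               significant = TRUE, member_hits = "", stringsAsFactors = FALSE)
  }
  res <- rbind(mk("grandparent", 9, 0.02), mk("parent", 7, 0.01),
               mk("child", 5, 0.005))
  edges <- data.frame(child_id = c("child", "parent"),
                      parent_id = c("parent", "grandparent"))
  pr <- prune_go_results(res, edges)
  # grandparent and child are related through the closure: only the
  # max-overlap term of the whole chain survives
  expect_identical(pr$results$set_name, "grandparent")
})

test_that("null rejection rate is conservative and matches the exact achievable level", {
  # The hypergeometric p-value is discrete, so P(p < alpha) under the
  # null is the achievable level alpha* <= alpha, computable exactly from
  # the null mass on the rejection region. The empirical rate must (a)
  # never exceed the nominal alpha beyond sampling error and (b) sit
  # within binomial 99% bounds of alpha*.
  bg <- sprintf("G%04d", 1:2000)
  alpha <- 0.1
  n_query <- 120
  eff <- planted_effects(n_sets = 100, set_size_range = c(20, 60),
                         n_planted = 0)
  achievable <- function(K, n, N) {
    ks <- 0:min(K, n)
    tails <- hypergeometric_upper_tail(ks, n, K, N)
    sum(stats::dhyper(ks[tails < alpha], K, N - K, n))
  }
  rejected <- 0; n_tests <- 0; exp_level <- numeric(0)
  for (i in 1:50) {
    sets <- generate_genesets(bg, character(0), eff, seed = 1234 + i)$sets
    query <- withr::with_seed(5678 + i, sample(bg, n_query))
    res <- enrich_collection(query, sets, bg, collection_label = "KEGG")
    rejected <- rejected + sum(res$p_value < alpha)
    n_tests <- n_tests + nrow(res)
    exp_level <- c(exp_level, vapply(res$K, achievable, numeric(1),
                                     n = n_query, N = 2000))
  }
  rate <- rejected / n_tests
  astar <- mean(exp_level)
  expect_lte(astar, alpha)
  bounds <- stats::qbinom(c(0.005, 0.995), n_tests, astar) / n_tests
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
  expect_lte(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / n_tests))
})
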