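test_that("LPT assigns descending weights to the least-loaded locality", {
  # the worked example: [5, 4, 3, 3, 3] on 2 localities -> loads (8, 10)
  res <- lpt_assign(c(5, 4, 3, 3, 3), 2)
  expect_equal(res$loads, c(8, 10))
  expect_equal(res$makespan, 10)
  # four unit weights over two localities balance exactly
  expect_equal(lpt_assign(rep(1, 4), 2)$loads, c(2, 2))
  # single locality holds the total
  expect_equal(lpt_assign(c(2, 3, 4), 1)$loads, 9)
  expect_equal(lpt_assign(numeric(0), 3)$loads, c(0, 0, 0))
  expect_error(lpt_assign(c(1, -1), 2), "positive")
})

test_that("LPT stays within the 4/3 - 1/(3m) bound of the exhaustive optimum", {
  withr::with_seed(99, {
    for (rep in 1:120) {
      m <- sample(2:3, 1L)
      n <- sample(4:12, 1L)
      w <- round(stats::runif(n, 1, 20), 2)
      lpt <- lpt_assign(w, m)$makespan
      opt <- opt_makespan(w, m)
      expect_lte(lpt, (4 / 3 - 1 / (3 * m)) * opt + 1e-9)
      expect_gte(lpt, opt - 1e-9)
    }
  })
  # the worked example: OPT = 9, LPT = 10 <= (4/3 - 1/6) * 9
  expect_equal(opt_makespan(c(5, 4, 3, 3, 3), 2), 9)
})

test_that("the locality threshold is the tolerant mean", {
  expect_equal(compute_locality_threshold(80, 10, 0.10), 8.8)
  expect_equal(compute_locality_threshold(80, 10, 0), 8)
  expect_gte(compute_locality_threshold(42, 1), 42)
})

test_that("overloaded localities shed terminal groups largest-first", {
  # one neuron of weight 10 with terminal groups {3, 1}; threshold 8.8
  w_big <- structure(list(total = 10, groups = list(
    list(root_subtree = 2L, parent_subtree = 1L, cost = 3, size = 1L,
         members = 2L),
    list(root_subtree = 3L, parent_subtree = 1L, cost = 1, size = 1L,
         members = 3L)
  ), n_subtrees = 3L), class = "neuron_weight")
  w_small <- structure(list(total = 6, groups = list(), n_subtrees = 1L),
                       class = "neuron_weight")
  bal <- balance_with_splitting(list(w_big, w_small), 2, tolerance = 0.10)
  expect_equal(bal$threshold, 8.8)
  expect_equal(nrow(bal$delegations), 1L)
  expect_equal(bal$delegations$root_subtree, 2L)   # the cost-3 group moved
  home <- bal$home[1]
  expect_equal(bal$loads[home], 7)                  # 10 - 3
  # conservation
  expect_equal(sum(bal$loads), 16)

  # all neurons under threshold: no splits, identical to plain LPT
  wts <- lapply(c(4, 4, 4, 4), function(tot) {
    structure(list(total = tot, groups = list(), n_subtrees = 1L),
              class = "neuron_weight")
  })
  bal2 <- balance_with_splitting(wts, 2)
  expect_equal(nrow(bal2$delegations), 0L)
  expect_equal(bal2$loads, lpt_assign(rep(4, 4), 2)$loads)

  # a delegable group larger than the threshold is placed with a warning
  w_huge <- structure(list(total = 20, groups = list(
    list(root_subtree = 2L, parent_subtree = 1L, cost = 18, size = 1L,
         members = 2L)
  ), n_subtrees = 2L), class = "neuron_weight")
  w_rest <- structure(list(total = 1, groups = list(), n_subtrees = 1L),
                      class = "neuron_weight")
  expect_warning(balance_with_splitting(list(w_huge, w_rest), 2),
                 "exceeds the locality threshold")
})

test_that("subtree groups are leaf-ward closures and delegation forms a star", {
  withr::with_seed(55, {
    for (rep in 1:40) {
      n <- sample(8:40, 1L)
      tree <- toy_tree(random_parent_vector(n))
      costs <- stats::runif(n, 0.5, 4)
      plan <- cluster_subtrees(tree, costs, sum(costs) / 4)
      w <- neuron_subtree_groups(plan)
      # group costs are consistent and every group excludes the root subtree
      for (g in w$groups) {
        expect_false(1L %in% g$members)
        expect_equal(g$cost,
                     sum(vapply(plan$subtrees[g$members], `[[`, 1, "cost")))
      }
      # delegations from an overloaded home keep a star topology: delegated
      # groups are disjoint, and each group root's parent stays at home
      # tolerance 0 forces aggressive shedding; oversized groups may warn
      bal <- suppressWarnings(balance_with_splitting(list(w), 2, tolerance = 0))
      if (nrow(bal$delegations) > 0L) {
        dele <- unlist(bal$delegation_members)
        expect_equal(anyDuplicated(dele), 0L)
        for (i in seq_len(nrow(bal$delegations))) {
          root <- bal$delegations$root_subtree[i]
          par <- plan$subtrees[[root]]$parent
          expect_false(par %in% dele)      # channel partner is on home
        }
      }
    }
  })
})

test_that("locality vectors place delegated closures off-home", {
  tree <- toy_tree(c(NA, 1:9))
  plan <- cluster_subtrees(tree, rep(1, 10), 3)      # 4 subtrees chain
  w <- neuron_subtree_groups(plan)
  bal <- suppressWarnings(balance_with_splitting(list(w), 2, tolerance = 0))
  loc <- assignment_localities(bal, list(w))[[1]]
  expect_length(loc, 4L)
  expect_equal(sort(unique(loc)), 1:2)
  # a delegated subtree's descendants travel with it
  dele <- which(loc != bal$home[1])
  if (length(dele) > 0L) {
    expect_equal(dele, seq(min(dele), 4L))           # chain closure
  }
  rep <- load_report(bal)
  expect_equal(sum(rep$loads), 10)
})
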