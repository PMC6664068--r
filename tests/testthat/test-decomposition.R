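test_that("the workload threshold follows k * runtime / cores", {
  expect_equal(max_work(32, 16, 1.8), 3.6)
  expect_equal(max_work(10, 4, 1), 2.5)
  expect_equal(max_work(7, 1, 1), 7)       # single core, k = 1: whole neuron
  expect_error(max_work(-1, 4, 1), "positive")
  expect_error(max_work(10, 4, 0), "positive")
})

test_that("clustering a chain closes subtrees before exceeding the threshold", {
  tree <- toy_tree(c(NA, 1:9))             # unbranched chain of 10
  plan <- cluster_subtrees(tree, rep(1, 10), threshold = 3)
  sizes <- vapply(plan$subtrees, function(s) length(s$members), 1L)
  expect_equal(sizes, c(3L, 3L, 3L, 1L))
  expect_true(validate_plan(plan, tree, rep(1, 10))$valid)

  # threshold >= total cost: a single subtree holds everything
  plan1 <- cluster_subtrees(tree, rep(1, 10), threshold = 10)
  expect_length(plan1$subtrees, 1L)
  expect_equal(plan1$subtrees[[1]]$members, 1:10)

  # a compartment costlier than the threshold becomes a forced singleton
  plan2 <- cluster_subtrees(tree, c(1, 9, rep(1, 8)), threshold = 3)
  val <- validate_plan(plan2, tree, c(1, 9, rep(1, 8)))
  expect_true(val$valid)
  expect_true(any(grepl("forced singleton", val$exceptions)))
})

test_that("the 17-compartment worked morphology clusters into 5 subtrees", {
  tree <- worked_17_tree()
  plan <- cluster_subtrees(tree, rep(1, 17), threshold = 5)
  expect_length(plan$subtrees, 5L)
  expect_equal(plan$n, 17L)
  expect_true(validate_plan(plan, tree, rep(1, 17))$valid)
  # the trunk closes at the trifurcation; each branch is tested independently
  expect_equal(plan$subtrees[[1]]$members, 1:2)
  roots <- vapply(plan$subtrees, `[[`, 1L, "root")
  expect_true(all(c(3L, 7L, 11L) %in% roots))
})

test_that("bifurcation branches are all-or-none", {
  # root chain + two branches that jointly fit the budget: one subtree
  tree <- toy_tree(c(NA, 1, 2, 2, 3, 4))
  plan <- cluster_subtrees(tree, rep(1, 6), threshold = 6)
  expect_length(plan$subtrees, 1L)
  # budget too small for both branches: each starts its own subtree even
  # though one alone would fit
  plan2 <- cluster_subtrees(tree, rep(1, 6), threshold = 4)
  expect_length(plan2$subtrees, 3L)
  expect_true(validate_plan(plan2, tree, rep(1, 6))$valid)
})

test_that("cluster plans are valid on random trees and monotone in threshold", {
  withr::with_seed(101, {
    for (rep in 1:60) {
      n <- sample(5:80, 1L)
      tree <- toy_tree(random_parent_vector(n))
      costs <- stats::runif(n, 0.5, 3)
      thr <- stats::runif(1, 1, sum(costs))
      plan <- cluster_subtrees(tree, costs, thr)
      val <- validate_plan(plan, tree, costs)
      expect_true(val$valid, info = paste(val$violations, collapse = "; "))
      # partition is exact
      expect_setequal(unlist(lapply(plan$subtrees, `[[`, "members")),
                      seq_len(n))
      # a smaller threshold never yields fewer subtrees
      plan_small <- cluster_subtrees(tree, costs, thr / 2)
      expect_gte(length(plan_small$subtrees), length(plan$subtrees))
    }
  })
})

test_that("plan validation reports broken plans", {
  tree <- toy_tree(c(NA, 1:4))
  plan <- cluster_subtrees(tree, rep(1, 5), 2)
  # duplicate a compartment across subtrees
  broken <- plan
  broken$subtrees[[2]]$members <- c(broken$subtrees[[1]]$members[1],
                                    broken$subtrees[[2]]$members)
  expect_false(validate_plan(broken, tree)$valid)
  expect_match(validate_plan(broken, tree)$violations, "partition",
               all = FALSE)
  expect_error(cluster_subtrees(tree, rep(1, 5), -1), "positive")
})

test_that("analytic workloads sum base and mechanism costs; measured mode runs", {
  tree <- toy_tree(c(NA, 1, 2, 3, 4))
  m <- neuron_model(tree)
  plan <- cluster_subtrees(tree, rep(1, 5), 100)
  expect_equal(measure_workload(plan$subtrees[[1]], m), 5)
  # two compartments each carrying one mechanism of cost 3
  m2 <- neuron_model(toy_tree(c(NA, 1)))
  register_mechanism("test_cost3", "density", character(), c(g = 0),
                     function(v, s, p, t) list(i = 0 * v, g = 0 * v), cost = 3)
  m2 <- add_mechanism(m2, "test_cost3", 1:2)
  plan2 <- cluster_subtrees(m2$tree, compartment_costs(m2), 100)
  expect_equal(measure_workload(plan2$subtrees[[1]], m2), 8)
  # measured mode: positive, and repeatable within sampling noise
  cmod <- cost_model("measured", reps = 3, tstop = 2)
  w <- measure_workload(plan2$subtrees[[1]], m2, cmod)
  expect_gt(w, 0)
})

test_that("the default granularity constant interpolates over core counts", {
  expect_equal(default_k(16), 1.8)
  expect_equal(default_k(64), 2)
  expect_equal(default_k(4), 1)
  expect_lt(default_k(2), default_k(8))
})
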