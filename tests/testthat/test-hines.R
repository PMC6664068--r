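test_that("matrix set-up produces the documented diagonal and RHS", {
  # single passive compartment at equilibrium: dV must be exactly 0
  ar <- solver_arrays(NA_integer_, a = 0, b = 0, d = 0, rhs = 0, v = -65)
  ar <- setup_matrix(ar, G = 0.1, i_total = 0, C = 1, dt = 0.025)
  expect_equal(ar$d, 1 / 0.025 + 0.1)         # 40.1 uS
  expect_equal(ar$rhs, 0)
  expect_equal(solve_tree(ar), 0)

  # two-compartment chain at equal voltage: axial RHS terms vanish
  ar2 <- solver_arrays(c(NA, 1L), a = c(0, -2), b = c(0, -2),
                       d = numeric(2), rhs = numeric(2), v = c(-65, -65))
  ar2 <- setup_matrix(ar2, G = c(0, 0), i_total = c(0, 0), C = c(1, 1),
                      dt = 0.025)
  expect_equal(ar2$rhs, c(0, 0))
  expect_equal(ar2$d, c(42, 42))              # C/dt + 1/r on both rows

  # a subtree root must be given the cached parent boundary voltage
  ar3 <- solver_arrays(NA_integer_, a = -1, b = -1, d = 0, rhs = 0, v = -65)
  expect_error(setup_matrix(ar3, G = 0, i_total = 0, C = 1, dt = 0.025),
               "parent boundary")
  ar3 <- setup_matrix(ar3, G = 0, i_total = 0, C = 1, dt = 0.025,
                      parent_boundary_v = -60)
  expect_equal(ar3$rhs, 1 * 5)                # (v_p - v) / r
})

test_that("backward triangulation folds children into parent rows", {
  # chain of 2: f = a/d = -0.25 folds (d, rhs) = (4, 8) into the parent
  ch <- solver_arrays(c(NA, 1L), a = c(0, -1), b = c(0, -1),
                      d = c(4, 4), rhs = c(8, 8))
  tri <- backward_triangulate(ch)
  expect_equal(tri$arrays$d[1], 3.75)
  expect_equal(tri$arrays$rhs[1], 10)
  expect_null(tri$boundary)
  # and substitution returns the dense solution (8/3, 8/3)
  out <- forward_substitute(tri$arrays)
  expect_equal(out$rhs, c(8 / 3, 8 / 3), tolerance = 1e-12)

  # Y tree: two children each fold -0.5 into the root diagonal
  y <- solver_arrays(c(NA, 1L, 1L), a = c(0, -1, -1), b = c(0, -1, -1),
                     d = c(3, 2, 2), rhs = c(1, 0, 0))
  triy <- backward_triangulate(y)
  expect_equal(triy$arrays$d[1], 2)
  expect_equal(triy$arrays$rhs[1], 1)
  dv <- forward_substitute(triy$arrays)$rhs
  expect_equal(dv, c(0.5, 0.25, 0.25))

  # a and b are never modified by the solve
  expect_identical(triy$arrays$a, y$a)
  expect_identical(triy$arrays$b, y$b)
})

test_that("an eliminated subtree root emits its boundary contribution", {
  leaf <- solver_arrays(NA_integer_, a = -1, b = -1, d = 2, rhs = 4)
  tri <- backward_triangulate(leaf)
  expect_equal(tri$boundary$delta_d, -0.5)    # -(a/d) b = -(-0.5)(-1)
  expect_equal(tri$boundary$delta_rhs, 2)     # -(-0.5)(4)
  # substitution on the subtree needs the parent's dV
  expect_error(forward_substitute(tri$arrays), "parent dV")
})

test_that("splitting a chain across a boundary reproduces the monolithic solve", {
  # monolithic 4-chain with a = b = -1 and d, rhs as below
  d <- c(5, 4, 4, 3); rhs <- c(1, 8, 8, 2)
  mono <- solver_arrays(c(NA, 1L, 2L, 3L), a = c(0, -1, -1, -1),
                        b = c(0, -1, -1, -1), d = d, rhs = rhs)
  dv_mono <- solve_tree(mono)
  # split: rows 1-2 parent subtree, rows 3-4 child subtree
  top <- solver_arrays(c(NA, 1L), a = c(0, -1), b = c(0, -1),
                       d = d[1:2], rhs = rhs[1:2])
  bot <- solver_arrays(c(NA, 1L), a = c(-1, -1), b = c(-1, -1),
                       d = d[3:4], rhs = rhs[3:4])
  tb <- backward_triangulate(bot)
  top$d[2] <- top$d[2] + tb$boundary$delta_d
  top$rhs[2] <- top$rhs[2] + tb$boundary$delta_rhs
  tt <- backward_triangulate(top)
  top_dv <- forward_substitute(tt$arrays)$rhs
  bot_dv <- forward_substitute(tb$arrays, parent_delta_v = top_dv[2])$rhs
  expect_equal(c(top_dv, bot_dv), dv_mono, tolerance = 1e-13)
})

test_that("solve_tree matches a dense solve on random trees", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      n <- sample(2:200, 1L)
      sys <- random_tree_system(n)
      dv <- solve_tree(sys)
      dense <- solve(as_dense_matrix(sys), sys$rhs)
      expect_lt(max(abs(dv - dense)) / max(abs(dense)), 1e-10)
    }
  })
  # identity-like system passes rhs through
  idn <- solver_arrays(c(NA, 1L, 1L), a = numeric(3), b = numeric(3),
                       d = rep(1, 3), rhs = c(3, 1, 2))
  expect_equal(solve_tree(idn), c(3, 1, 2))
  # singular pivot is reported
  bad <- solver_arrays(c(NA, 1L), a = c(0, -1), b = c(0, -1),
                       d = c(1, 0), rhs = c(1, 1))
  expect_error(solve_tree(bad), "singular")
})
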