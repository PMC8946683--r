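test_that("asynchronous successors flip exactly one unstable node", {
  m <- toy_mutual_activation()
  succ <- async_successors(m, c(1, 0))
  expect_equal(state_keys(succ), c("00", "11"))
  # fixed points have no successors
  expect_equal(nrow(async_successors(m, c(0, 0))), 0L)
  expect_true(is_fixed_point(m, c(1, 1)))
  expect_false(is_fixed_point(m, c(0, 1)))
})

test_that("reachable STG of the toggle switch from (0,0)", {
  m <- toy_toggle()
  stg <- build_stg(m, c(0, 0))
  # (0,0) can flip either node to reach the two stable states; (1,1)
  # has no incoming path from (0,0)
  expect_equal(state_keys(stg$states), c("00", "01", "10"))
  expect_equal(length(stg$from), 2L)
  atts <- find_attractors(stg)
  expect_equal(length(atts), 2L)
  expect_true(all(vapply(atts, `[[`, "", "kind") == "fixed_point"))
  # STG rooted at a fixed point is a single state without transitions
  stg1 <- build_stg(m, c(1, 0))
  expect_equal(nrow(stg1$states), 1L)
  expect_equal(length(stg1$from), 0L)
})

test_that("a negative feedback loop yields one 4-state cyclic attractor", {
  m <- toy_negative_loop()
  atts <- find_attractors(build_stg(m, c(0, 0)))
  expect_equal(length(atts), 1L)
  expect_equal(atts[[1]]$kind, "cyclic")
  expect_equal(nrow(atts[[1]]$states), 4L)
  expect_equal(nrow(fixed_points(m)), 0L)
})

test_that("fixed-point enumeration handles self-loops and clamps", {
  m <- toy_self_activator()
  expect_equal(state_keys(fixed_points(m)), c("0", "1"))
  expect_equal(state_keys(fixed_points(m, perturbation(A = 1))), "1")
})

test_that("branch-and-prune fixed points match synchronous fixed points", {
  # fixed points are update-scheme independent: f(x) = x
  for (s in 1:15) {
    m <- random_boolean_network(7, max_in_degree = 3, seed = s,
                                rule_template = "random_monotone")
    all_states <- as.matrix(expand.grid(rep(list(0:1), 7)))
    sync_fp <- all_states[apply(all_states, 1, function(x) {
      all(vapply(m$nodes$name, function(nm)
        evaluate_rule(m, nm, x) == x[match(nm, m$nodes$name)], TRUE))
    }), , drop = FALSE]
    expect_equal(state_keys(fixed_points(m)), state_keys(sync_fp),
                 info = paste("seed", s))
  }
})

test_that("exact absorption splits a symmetric branch evenly", {
  m <- toy_toggle()
  dist <- exact_absorption(build_stg(m, c(0, 0)))
  expect_equal(sort(dist$probability), c(0.5, 0.5))
  expect_equal(sum(dist$probability), 1)
  # absorbed at the root itself
  d1 <- exact_absorption(build_stg(m, c(1, 0)))
  expect_equal(d1$probability, 1)
})

test_that("Monte Carlo agrees with the exact solve within 3 sigma", {
  for (s in c(3, 8)) {
    m <- random_boolean_network(8, max_in_degree = 3, seed = s)
    root <- rep(0L, 8)
    stg <- build_stg(m, root)
    ex <- exact_absorption(stg)
    n <- 20000
    mc <- monte_carlo_phenotypes(m, root, n_runs = n, seed = 42)
    exk <- vapply(attr(ex, "attractors"), function(a)
      paste(sort(apply(a$states, 1, paste, collapse = "")), collapse = "|"), "")
    mck <- vapply(attr(mc, "attractors"), function(a)
      paste(sort(apply(a$states, 1, paste, collapse = "")), collapse = "|"), "")
    for (k in seq_along(exk)) {
      p <- ex$probability[k]
      phat <- if (exk[k] %in% mck) mc$probability[match(exk[k], mck)] else 0
      se <- sqrt(max(p * (1 - p), 1e-9) / n)
      expect_lt(abs(phat - p), max(3 * se, 0.005))
    }
  }
})

test_that("Monte Carlo is bit-reproducible for a fixed seed", {
  m <- random_boolean_network(8, seed = 5)
  a <- monte_carlo_phenotypes(m, rep(0L, 8), n_runs = 2000, seed = 7)
  b <- monte_carlo_phenotypes(m, rep(0L, 8), n_runs = 2000, seed = 7)
  expect_identical(a$probability, b$probability)
  c <- monte_carlo_phenotypes(m, rep(0L, 8), n_runs = 2000, seed = 8)
  expect_false(identical(a$probability, c$probability))
})

test_that("walks absorbed in a cycle are routed to the cyclic attractor", {
  m <- toy_negative_loop()
  dist <- monte_carlo_phenotypes(m, c(0, 0), n_runs = 200, seed = 1,
                                 max_steps = 50)
  expect_equal(nrow(dist), 1L)
  expect_equal(dist$kind, "cyclic")
  expect_equal(dist$probability, 1)
})

test_that("the STG state budget triggers an explicit error", {
  m <- random_boolean_network(10, max_in_degree = 3, seed = 2)
  expect_error(build_stg(m, rep(0L, 10), max_states = 4),
               "state budget")
})
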