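test_that("rule evaluation follows the truth table", {
  m <- boolean_model(
    nodes = data.frame(name = c("A", "B", "C"), kind = "internal"),
    edges = data.frame(source = c("A", "B", "A", "B", "C"),
                       target = c("C", "C", "B", "A", "A"),
                       sign = c(1L, -1L, 1L, 1L, 1L)),
    rules = list(C = "A & !B", B = "A", A = "B | C"))
  expect_equal(evaluate_rule(m, "C", c(A = 1, B = 0, C = 0)), 1L)
  expect_equal(evaluate_rule(m, "C", c(A = 1, B = 1, C = 0)), 0L)
  expect_equal(evaluate_rule(m, "C", c(A = 0, B = 0, C = 1)), 0L)
  # truth table enumerates contexts in binary counting order
  expect_equal(rule_truth_table(m, "C"), c(0L, 1L, 0L, 0L))
  expect_error(evaluate_rule(m, "nope", c(A = 1, B = 0, C = 0)),
               "unknown node")
})

test_that("validation rejects malformed models", {
  nodes <- data.frame(name = c("A", "B"), kind = "internal")
  edges <- data.frame(source = c("A", "B"), target = c("B", "A"),
                      sign = c(1L, 1L))
  # monotonicity violated: declared activation acting as inhibition
  expect_error(boolean_model(nodes, edges, list(A = "B", B = "!A")),
               "not monotone")
  # rule variable set must match incoming edges
  expect_error(boolean_model(nodes, edges, list(A = "B", B = "B")),
               "rule/edge mismatch")
  # ineffective regulator (edge never changes the rule value)
  e2 <- data.frame(source = c("A", "A", "B"), target = c("B", "A", "A"),
                   sign = c(1L, 1L, 1L))
  expect_error(boolean_model(nodes, e2, list(A = "A | (B & A)", B = "A")),
               "never effective")
  # outputs cannot regulate
  n3 <- data.frame(name = c("A", "B"), kind = c("output", "internal"))
  expect_error(boolean_model(n3, edges, list(A = "B", B = "A")),
               "outgoing edges")
  # duplicated node names
  expect_error(
    boolean_model(data.frame(name = c("A", "A"), kind = "internal"),
                  edges, list(A = "B", B = "A")),
    "duplicated node names")
})

test_that("edge signs are recoverable from the rules", {
  m <- toy_toggle()
  inferred <- infer_edge_signs(m)
  expect_equal(
    inferred[order(inferred$source), c("source", "target", "sign")],
    m$edges[order(m$edges$source), c("source", "target", "sign")],
    ignore_attr = TRUE)
})

test_that("perturbations clamp rules and are idempotent", {
  m <- toy_toggle()
  # empty perturbation leaves the model unchanged
  m0 <- apply_perturbation(m, perturbation())
  expect_equal(m0$rules, m$rules)
  p <- perturbation(A = 1)
  m1 <- apply_perturbation(m, p)
  expect_equal(m1$rules$A, quote(TRUE))
  expect_equal(m1$rules$B, m$rules$B)
  # original untouched; applying twice equals applying once
  expect_equal(m$rules$A, quote(!B))
  m2 <- apply_perturbation(m1, p)
  expect_equal(m2$rules, m1$rules)
  expect_equal(attr(m2, "clamped"), attr(m1, "clamped"))
  expect_error(apply_perturbation(m, perturbation(Z = 0)), "unknown node")
  expect_error(perturbation(A = 2), "0 \\(KO\\) or 1 \\(E1\\)")
})

test_that("clamped nodes never update and hold their value", {
  m <- toy_toggle()
  # A clamped ON: from (1,1), only B may move
  succ <- async_successors(m, c(1, 1), perturbation(A = 1))
  expect_equal(nrow(succ), 1L)
  expect_equal(unname(succ[1, ]), c(1L, 0L))
  fp <- fixed_points(m, perturbation(A = 1))
  expect_true(all(fp[, "A"] == 1L))
})

test_that("attractor phenotype classification reads the output nodes", {
  m <- toy_with_outputs()
  expect_equal(classify_attractor(m, c(I = 1, X = 1, Good = 1, Bad = 0)),
               "Good")
  expect_equal(classify_attractor(m, c(I = 0, X = 0, Good = 0, Bad = 0)),
               "None")
  expect_equal(classify_attractor(m, c(I = 1, X = 1, Good = 1, Bad = 1)),
               "Mixed")
  # cyclic attractor whose states disagree on outputs
  states <- rbind(c(1, 1, 1, 0), c(1, 0, 0, 1))
  colnames(states) <- m$nodes$name
  expect_equal(classify_attractor(m, states), "Mixed")
})

test_that("states can be given named in any order", {
  m <- toy_with_outputs()
  s <- as_state(m, c(Bad = 0, I = 1, Good = 1, X = 1))
  expect_equal(s, c(1L, 1L, 1L, 0L))
  expect_error(as_state(m, c(I = 1, X = 1)), "every node")
  expect_error(as_state(m, c(1, 2, 0, 0)), "0/1")
})
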