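test_that("circuit signs multiply along the cycle", {
  m <- toy_toggle()
  circ <- enumerate_circuits(m)
  expect_equal(length(circ), 1L)
  expect_equal(circ[[1]]$sign, 1)         # (-1) * (-1)
  expect_equal(sort(circ[[1]]$nodes), c("A", "B"))
  mn <- toy_negative_loop()
  expect_equal(enumerate_circuits(mn)[[1]]$sign, -1)
})

test_that("circuit enumeration matches a brute-force cycle search", {
  # independent oracle: depth-first enumeration of simple cycles with
  # canonical rotation, no smallest-root blocking
  brute_cycles <- function(edges, n) {
    adj <- lapply(seq_len(n), function(i) edges$to[edges$from == i])
    found <- new.env()
    path <- integer(0)
    dfs <- function(v, start) {
      path <<- c(path, v)
      for (w in adj[[v]]) {
        if (w == start) {
          rot <- which.min(path)
          key <- paste(c(path[rot:length(path)],
                         path[seq_len(rot - 1L)]), collapse = "-")
          assign(key, TRUE, found)
        } else if (!(w %in% path) && w >= start) {
          dfs(w, start)
        }
      }
      path <<- path[-length(path)]
    }
    for (s in seq_len(n)) dfs(s, s)
    sort(ls(found))
  }
  for (s in 1:10) {
    m <- random_boolean_network(7, max_in_degree = 3, seed = s)
    circ <- enumerate_circuits(m)
    got <- sort(vapply(circ, function(cc) {
      idx <- match(cc$nodes, m$nodes$name)
      paste(idx, collapse = "-")
    }, ""))
    edges <- data.frame(from = match(m$edges$source, m$nodes$name),
                        to = match(m$edges$target, m$nodes$name))
    expect_equal(got, brute_cycles(edges, m$n), info = paste("seed", s))
  }
})

test_that("bounded enumeration respects the length cap", {
  b <- nsclc_cached()
  short <- enumerate_circuits(b$model, max_length = 3)
  expect_true(all(vapply(short, function(cc) length(cc$nodes), 0L) <= 3L))
  all_c <- enumerate_circuits(b$model)
  expect_equal(sum(vapply(all_c, function(cc) length(cc$nodes), 0L) <= 3L),
               length(short))
})

test_that("edge derivatives behave as discrete Jacobian entries", {
  m <- boolean_model(
    nodes = data.frame(name = c("A", "B", "T"), kind = "internal"),
    edges = data.frame(source = c("A", "B", "T", "T"),
                       target = c("T", "T", "A", "B"),
                       sign = c(1L, 1L, 1L, 1L)),
    rules = list(T = "A & B", A = "T", B = "T"))
  expect_equal(edge_derivative(m, "A", "T", c(0, 1, 0)), 1L)
  expect_equal(edge_derivative(m, "A", "T", c(0, 0, 0)), 0L)
  expect_error(edge_derivative(m, "A", "B", c(0, 0, 0)), "no edge")
})

test_that("nonzero derivatives always carry the declared edge sign", {
  for (s in 1:10) {
    m <- random_boolean_network(6, max_in_degree = 3, seed = s,
                                rule_template = "nested_canalyzing")
    states <- as.matrix(expand.grid(rep(list(0:1), 6)))
    for (e in sample(nrow(m$edges), min(4, nrow(m$edges)))) {
      src <- m$edges$source[e]; tgt <- m$edges$target[e]
      d <- apply(states, 1, function(x) edge_derivative(m, src, tgt, x))
      expect_true(all(d[d != 0] == m$edges$sign[e]))
      expect_true(any(d != 0))   # validated models have effective edges
    }
  }
})

test_that("functionality search agrees with exhaustive state checking", {
  brute_functional <- function(m, circ) {
    states <- as.matrix(expand.grid(rep(list(0:1), m$n)))
    for (r in seq_len(nrow(states))) {
      ok <- TRUE
      for (k in seq_len(nrow(circ$edges))) {
        if (edge_derivative(m, circ$edges$source[k], circ$edges$target[k],
                            states[r, ]) == 0L) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  for (s in c(2, 4, 9)) {
    m <- random_boolean_network(6, max_in_degree = 3, seed = s,
                                rule_template = "random_monotone")
    circ <- enumerate_circuits(m)
    for (cc in circ[seq_len(min(6, length(circ)))]) {
      got <- is_functional(m, cc)
      expect_equal(got$functional, brute_functional(m, cc),
                   info = paste("seed", s, paste(cc$nodes, collapse = "/")))
      if (got$functional) {
        # the witness certifies every edge derivative nonzero
        for (k in seq_len(nrow(cc$edges)))
          expect_true(edge_derivative(m, cc$edges$source[k],
                                      cc$edges$target[k], got$witness) != 0L)
      }
    }
  }
})

test_that("clamping a circuit node makes the circuit non-functional", {
  m <- toy_toggle()
  cc <- enumerate_circuits(m)[[1]]
  expect_true(is_functional(m, cc)$functional)
  expect_false(is_functional(m, cc, perturbation(A = 0))$functional)
  expect_false(is_functional(m, cc, perturbation(B = 1))$functional)
})

test_that("a constant-rule self-loop is rejected, a true self-loop works", {
  m <- toy_self_activator()
  cc <- enumerate_circuits(m)
  expect_equal(length(cc), 1L)
  expect_equal(length(cc[[1]]$nodes), 1L)
  expect_true(is_functional(m, cc[[1]])$functional)
})
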