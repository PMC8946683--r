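#' Enumerate elementary circuits of the regulatory graph
#'
#' Finds every elementary cycle (no repeated node) of the signed
#' regulatory graph, by rooted depth-first search over increasing node
#' indices (each cycle reported once, rooted at its smallest node).
#' Self-loops are circuits of length 1.  Input nodes cannot be circuit
#' members (they have no incoming edges).  The circuit sign is the
#' product of its edge signs: positive circuits support multistability,
#' negative circuits sustained oscillations.
#'
#' @param model a [boolean_model()].
#' @param max_length longest circuit (node count) to report; `0` means
#'   unbounded.
#' @return list of `circuit` objects; each has `nodes` (cyclic order,
#'   smallest-index node first), `edges` (data.frame source, target,
#'   sign) and `sign`.
#' @export
enumerate_circuits <- function(model, max_length = 0L) {
  n <- model$n
  if (max_length <= 0L) max_length <- n
  adj <- lapply(seq_len(n), function(i)
    sort(match(model$edges$target[model$edges$source == model$nodes$name[i]],
               model$nodes$name)))
  sign_of <- function(i, j)
    model$edges$sign[model$edges$source == model$nodes$name[i] &
                     model$edges$target == model$nodes$name[j]]
  out <- list()
  path <- integer(0)
  on_path <- rep(FALSE, n)
  root <- 0L
  dfs <- function(v) {
    path[length(path) + 1L] <<- v
    on_path[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == root) {
        out[[length(out) + 1L]] <<- path
      } else if (w > root && !on_path[w] && length(path) < max_length) {
        dfs(w)
      }
    }
    on_path[v] <<- FALSE
    path <<- path[-length(path)]
  }
  for (r in seq_len(n)) {
    if (!length(adj[[r]])) next
    root <- r
    dfs(r)
  }
  lapply(out, function(idx) {
    nodes <- model$nodes$name[idx]
    src <- nodes
    tgt <- nodes[c(seq_along(nodes)[-1L], 1L)]
    sg <- mapply(function(i, j) sign_of(i, j),
                 idx, idx[c(seq_along(idx)[-1L], 1L)])
    structure(list(nodes = nodes,
                   edges = data.frame(source = src, target = tgt,
                                      sign = as.integer(sg),
                                      stringsAsFactors = FALSE),
                   sign = prod(sg)),
              class = "circuit")
  })
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("%s circuit: %s (length %d)%s\n",
              if (x$sign > 0) "positive" else "negative",
              paste(x$nodes, collapse = " -> "), length(x$nodes),
              if (!is.null(x$functional))
                if (x$functional) " [functional]" else " [non-functional]"
              else ""))
  invisible(x)
}

#' Discrete derivative of a rule along one edge
#'
#' `f_target(state[source := 1]) - f_target(state[source := 0])`: the
#' discrete Jacobian entry of the network map at `state`.  For a
#' monotone rule its sign, when nonzero, equals the declared edge sign.
#'
#' @param model a [boolean_model()].
#' @param source,target edge endpoints (the edge must exist).
#' @param state a state vector.
#' @return -1, 0 or +1.
#' @export
edge_derivative <- function(model, source, target, state) {
  if (!any(model$edges$source == source & model$edges$target == target))
    stop("no edge ", source, " -> ", target)
  state <- as_state(model, state)
  i <- node_index(model, source)
  s1 <- state; s1[i] <- 1L
  s0 <- state; s0[i] <- 0L
  evaluate_rule(model, target, s1) - evaluate_rule(model, target, s0)
}

#' Circuit functionality (discrete Jacobian test)
#'
#' A circuit is functional iff some network state makes the discrete
#' derivative of every circuit edge nonzero -- the feedback loop then
#' actively shapes the dynamics (positive loops enabling
#' multistability, negative loops oscillations).  The test is exact but
#' local: the derivative of an edge depends only on the target's other
#' regulators, so the search runs over the circuit's regulator context,
#' never over all 2^n states.  Each edge contributes the set of local
#' contexts with nonzero derivative; a backtracking search over the
#' shared context variables (with per-edge forward filtering) decides
#' whether the conjunction is satisfiable.  Clamping any circuit node
#' fixes its rule and makes the circuit non-functional.
#'
#' @param model a [boolean_model()].
#' @param circuit a `circuit` from [enumerate_circuits()].
#' @param p a [perturbation()].
#' @return the circuit with `functional` (logical) and, when
#'   functional, `witness` (one witness state) filled in.
#' @export
is_functional <- function(model, circuit, p = perturbation()) {
  p <- as_perturbation(p)
  if (any(circuit$nodes %in% names(p))) {
    circuit$functional <- FALSE
    return(circuit)
  }
  pm <- apply_perturbation(model, p)
  edges <- circuit$edges
  ne <- nrow(edges)
  # per-edge: matrix of local contexts (regulators of target minus the
  # source) with nonzero derivative, one row per good context
  goods <- vector("list", ne)
  for (r in seq_len(ne)) {
    regs <- regulators(pm, edges$target[r])
    tt <- rule_truth_table(pm, edges$target[r])
    j <- match(edges$source[r], regs)
    others <- regs[-j]
    ko <- length(others)
    ctxs <- if (ko) {
      as.matrix(expand.grid(rep(list(0:1), ko)))[, seq_len(ko), drop = FALSE]
    } else matrix(integer(), 1L, 0L)
    colnames(ctxs) <- others
    keep <- logical(nrow(ctxs))
    pos_others <- which(seq_along(regs) != j)
    for (a in seq_len(nrow(ctxs))) {
      idx <- if (ko) sum(ctxs[a, ] * bitwShiftL(1L, pos_others - 1L)) else 0L
      keep[a] <- tt[idx + bitwShiftL(1L, j - 1L) + 1L] != tt[idx + 1L]
    }
    if (!any(keep)) { circuit$functional <- FALSE; return(circuit) }
    goods[[r]] <- ctxs[keep, , drop = FALSE]
  }
  vars <- unique(unlist(lapply(goods, colnames)))
  # clamped context variables are fixed to their clamp value
  fixed <- intersect(vars, names(p))
  alive <- lapply(goods, function(g) rep(TRUE, nrow(g)))
  assign_var <- function(alive, v, b) {
    for (r in seq_len(ne)) {
      g <- goods[[r]]
      if (v %in% colnames(g)) {
        alive[[r]] <- alive[[r]] & (g[, v] == b)
        if (!any(alive[[r]])) return(NULL)
      }
    }
    alive
  }
  for (v in fixed) {
    alive <- assign_var(alive, v, as.integer(p[[v]]))
    if (is.null(alive)) { circuit$functional <- FALSE; return(circuit) }
  }
  free <- setdiff(vars, fixed)
  assignment <- integer(0)
  found <- NULL
  search <- function(alive, free, assignment) {
    if (!is.null(found)) return(invisible())
    if (!length(free)) { found <<- assignment; return(invisible()) }
    v <- free[[1L]]
    for (b in 0:1) {
      a2 <- assign_var(alive, v, b)
      if (!is.null(a2))
        search(a2, free[-1L], c(assignment, stats::setNames(b, v)))
      if (!is.null(found)) return(invisible())
    }
  }
  search(alive, free, assignment)
  if (is.null(found)) {
    circuit$functional <- FALSE
  } else {
    circuit$functional <- TRUE
    w <- stats::setNames(rep(0L, model$n), pm$nodes$name)
    if (length(p)) w[names(p)] <- as.integer(p)
    if (length(found)) w[names(found)] <- found
    circuit$witness <- w
  }
  circuit
}

#' Circuit inventory with functionality
#'
#' Enumerates circuits and tags each with its functionality status.
#' @inheritParams enumerate_circuits
#' @param p a [perturbation()].
#' @return data.frame (nodes, length, sign, functional) with the
#'   circuit objects in attribute `circuits`.
#' @export
circuit_inventory <- function(model, max_length = 0L, p = perturbation()) {
  circ <- enumerate_circuits(model, max_length)
  circ <- lapply(circ, function(cc) is_functional(model, cc, p))
  df <- data.frame(
    nodes = vapply(circ, function(cc) paste(cc$nodes, collapse = "/"), ""),
    length = vapply(circ, function(cc) length(cc$nodes), 0L),
    sign = vapply(circ, function(cc) as.integer(cc$sign), 0L),
    functional = vapply(circ, function(cc) isTRUE(cc$functional), TRUE),
    stringsAsFactors = FALSE)
  attr(df, "circuits") <- circ
  df
}
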