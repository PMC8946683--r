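#' @useDynLib g1sbn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a Boolean network model
#'
#' A `boolean_model` couples a signed regulatory graph with one logical
#' update rule per non-input node.  Nodes are binary (0 = inactive/OFF,
#' 1 = active/ON); rules are Boolean expressions over the node's
#' regulators written with `&`, `|`, `!` and parentheses.  Input nodes
#' carry no rule: they are parameters of a run, held constant by the
#' dynamics.  Output nodes (phenotype read-outs) must have no outgoing
#' edges.
#'
#' Edge signs are not free annotations: every rule must be monotone in
#' each of its regulators, non-decreasing for an activator (+1) and
#' non-increasing for an inhibitor (-1).  [validate_model()] checks this
#' exhaustively over all regulator contexts (in-degree capped at 12),
#' and checks that the variables appearing in the rules reconstruct the
#' declared edge set exactly.
#'
#' @param nodes data.frame with columns `name` (syntactic identifiers,
#'   unique), `kind` (one of `"input"`, `"internal"`, `"output"`) and
#'   optionally `symbol` (display label, e.g. `"miR-34a"` for node
#'   `miR34a`; defaults to `name`).
#' @param edges data.frame with columns `source`, `target` (node names)
#'   and `sign` (+1 activation, -1 inhibition).
#' @param rules named list (one entry per non-input node) of rule
#'   strings or unevaluated R expressions over regulator names.
#' @param validate check all model invariants (recommended).
#' @return An object of class `boolean_model` with components `nodes`,
#'   `edges`, `rules` (named list of language objects) and `n`.
#' @examples
#' toggle <- boolean_model(
#'   nodes = data.frame(name = c("A", "B"), kind = "internal"),
#'   edges = data.frame(source = c("A", "B"), target = c("B", "A"),
#'                      sign = c(-1L, -1L)),
#'   rules = list(A = "!B", B = "!A"))
#' fixed_points(toggle)
#' @export
boolean_model <- function(nodes, edges, rules, validate = TRUE) {
  stopifnot(is.data.frame(nodes), all(c("name", "kind") %in% names(nodes)))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$name <- as.character(nodes$name)
  nodes$kind <- as.character(nodes$kind)
  if (is.null(nodes$symbol)) nodes$symbol <- nodes$name
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = as.character(edges$source),
                        target = as.character(edges$target),
                        sign = as.integer(edges$sign),
                        stringsAsFactors = FALSE)
  }
  rules <- lapply(rules, function(r) {
    if (is.character(r)) str2lang(r) else r
  })
  m <- structure(
    list(nodes = nodes, edges = edges, rules = rules,
         n = nrow(nodes)),
    class = "boolean_model")
  if (validate) validate_model(m)
  m
}

#' @export
print.boolean_model <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, c("input", "internal", "output")))
  cat(sprintf(
    "Boolean network: %d nodes (%d input, %d internal, %d output), %d signed edges\n",
    x$n, kinds[["input"]], kinds[["internal"]], kinds[["output"]],
    nrow(x$edges)))
  for (nm in x$nodes$name) {
    if (nm %in% names(x$rules)) {
      cat(sprintf("  %s <- %s\n", nm, deparse1(x$rules[[nm]])))
    } else {
      cat(sprintf("  %s <- <input>\n", nm))
    }
  }
  invisible(x)
}

node_index <- function(model, names) {
  i <- match(names, model$nodes$name)
  if (anyNA(i)) stop("unknown node(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  i
}

#' Regulators of a node
#'
#' Sources of the edges entering `node`, in declared node order.
#' @param model a [boolean_model()].
#' @param node node name.
#' @return character vector of node names.
#' @export
regulators <- function(model, node) {
  node_index(model, node)
  src <- model$edges$source[model$edges$target == node]
  model$nodes$name[sort(match(src, model$nodes$name))]
}

rule_variables <- function(expr) {
  all.vars(expr)
}

#' Validate a Boolean model
#'
#' Checks every structural invariant: unique node names; edges between
#' declared nodes with signs in {-1, +1} and no duplicated (source,
#' target) pairs; no outgoing edges from output nodes; exactly one rule
#' per non-input node and none for inputs; rule variable sets that
#' reconstruct the edge set exactly; and monotonicity of every rule in
#' every regulator, in the direction of the declared edge sign
#' (exhaustive over the 2^(k-1) regulator contexts, in-degree k <= 12).
#'
#' @param model a [boolean_model()].
#' @param max_in_degree largest in-degree for which monotonicity is
#'   checked exhaustively; larger in-degrees are an error.
#' @return `model`, invisibly; stops with a message on the first
#'   violated invariant.
#' @export
validate_model <- function(model, max_in_degree = 12L) {
  nodes <- model$nodes; edges <- model$edges
  if (anyDuplicated(nodes$name))
    stop("duplicated node names: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  if (!all(nodes$kind %in% c("input", "internal", "output")))
    stop("node kind must be input/internal/output")
  bad <- setdiff(c(edges$source, edges$target), nodes$name)
  if (length(bad)) stop("edges refer to undeclared node(s): ",
                        paste(unique(bad), collapse = ", "))
  if (!all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 or -1")
  if (anyDuplicated(edges[c("source", "target")]))
    stop("duplicated (source, target) edge")
  out_nodes <- nodes$name[nodes$kind == "output"]
  if (any(edges$source %in% out_nodes))
    stop("output node(s) with outgoing edges: ",
         paste(intersect(edges$source, out_nodes), collapse = ", "))
  non_input <- nodes$name[nodes$kind != "input"]
  if (!setequal(names(model$rules), non_input))
    stop("rules must cover exactly the non-input nodes; mismatch: ",
         paste(union(setdiff(names(model$rules), non_input),
                     setdiff(non_input, names(model$rules))), collapse = ", "))
  # rule variables == incoming edge sources, per target
  for (nm in non_input) {
    vars <- rule_variables(model$rules[[nm]])
    regs <- edges$source[edges$target == nm]
    if (!setequal(vars, regs))
      stop(sprintf("rule/edge mismatch at %s: rule uses {%s}, edges give {%s}",
                   nm, paste(sort(vars), collapse = ","),
                   paste(sort(regs), collapse = ",")))
    if (anyDuplicated(regs))
      stop("duplicate incoming edges at ", nm)
    if (length(regs) > max_in_degree)
      stop(sprintf("in-degree %d at %s exceeds monotonicity-check cap %d",
                   length(regs), nm, max_in_degree))
    check_monotone(model, nm)
  }
  inputs <- nodes$name[nodes$kind == "input"]
  if (any(inputs %in% edges$target))
    stop("input node(s) with incoming edges: ",
         paste(intersect(inputs, edges$target), collapse = ", "))
  invisible(model)
}

# Exhaustive monotonicity check of one rule against its declared edge
# signs; the truth table over k regulators has 2^k rows.
check_monotone <- function(model, node) {
  regs <- regulators(model, node)
  k <- length(regs)
  if (k == 0L) return(invisible(TRUE))
  tt <- rule_truth_table(model, node)
  signs <- model$edges$sign[model$edges$target == node]
  names(signs) <- model$edges$source[model$edges$target == node]
  for (j in seq_len(k)) {
    # pairs of contexts differing only in regulator j (bit j-1)
    bit <- bitwShiftL(1L, j - 1L)
    idx0 <- which(bitwAnd(seq_len(2L^k) - 1L, bit) == 0L)
    d <- tt[idx0 + bit] - tt[idx0]
    s <- signs[[regs[j]]]
    if (s == 1L && any(d < 0L))
      stop(sprintf("rule for %s is not monotone increasing in activator %s",
                   node, regs[j]))
    if (s == -1L && any(d > 0L))
      stop(sprintf("rule for %s is not monotone decreasing in inhibitor %s",
                   node, regs[j]))
    if (all(d == 0L))
      stop(sprintf("edge %s -> %s is never effective (regulator absent from dynamics)",
                   regs[j], node))
  }
  invisible(TRUE)
}

#' Truth table of one node's rule
#'
#' Rows enumerate the 2^k regulator contexts in binary counting order:
#' row `i` (0-based) assigns regulator `j` (declared node order) the bit
#' `(i >> (j-1)) & 1`.
#'
#' @param model a [boolean_model()].
#' @param node a non-input node name.
#' @return integer vector of length 2^k with the rule value per context.
#' @export
rule_truth_table <- function(model, node) {
  regs <- regulators(model, node)
  k <- length(regs)
  if (k > 20L) stop("truth table too large (in-degree ", k, ")")
  expr <- model$rules[[node]]
  if (is.null(expr)) stop("no rule for node ", node, " (input?)")
  idx <- 0:(2L^k - 1L)
  env <- new.env(parent = baseenv())
  for (j in seq_len(k)) {
    assign(regs[j], as.logical(bitwAnd(bitwShiftR(idx, j - 1L), 1L)),
           envir = env)
  }
  as.integer(eval(expr, env))
}

#' Evaluate one node's rule at a state
#'
#' @param model a [boolean_model()].
#' @param node a non-input node name.
#' @param state binary vector in declared node order (named vectors are
#'   reordered by name).
#' @return 0 or 1.
#' @export
evaluate_rule <- function(model, node, state) {
  node_index(model, node)
  expr <- model$rules[[node]]
  if (is.null(expr)) stop("node ", node, " has no rule (input node)")
  state <- as_state(model, state)
  vars <- rule_variables(expr)
  env <- as.list(as.logical(state[node_index(model, vars)]))
  names(env) <- vars
  as.integer(eval(expr, env, baseenv()))
}

#' Coerce a state vector
#'
#' Accepts an unnamed binary vector in declared node order or a named
#' binary vector (any order, all nodes present) and returns the
#' canonical unnamed 0/1 integer vector.
#' @param model a [boolean_model()].
#' @param state binary vector.
#' @return integer vector of length `model$n`.
#' @export
as_state <- function(model, state) {
  if (!is.null(names(state))) {
    hits <- sum(names(state) %in% model$nodes$name)
    if (hits == length(state) && setequal(names(state), model$nodes$name)) {
      state <- state[model$nodes$name]
    } else if (hits > 0L) {
      stop("named state must name every node exactly once")
    }
    # names foreign to the model (e.g. expand.grid defaults) are ignored
  }
  state <- as.integer(state)
  if (length(state) != model$n) stop("state length != node count")
  if (!all(state %in% c(0L, 1L))) stop("state entries must be 0/1")
  state
}

#' Derive the signed edge list from rules
#'
#' For each rule and regulator, scans all regulator contexts and
#' classifies the dependence as activating (+1) if some context gives a
#' positive discrete derivative and none negative, inhibiting (-1) in
#' the symmetric case.  Non-monotone dependence is an error.  Used to
#' cross-check a declared edge table or to build one from rules alone.
#'
#' @param model a [boolean_model()] (edge signs ignored).
#' @return data.frame (source, target, sign).
#' @export
infer_edge_signs <- function(model) {
  out <- list()
  for (nm in names(model$rules)) {
    regs <- sort(match(rule_variables(model$rules[[nm]]), model$nodes$name))
    regs <- model$nodes$name[regs]
    k <- length(regs)
    if (k == 0L) next
    tt <- local({
      expr <- model$rules[[nm]]
      idx <- 0:(2L^k - 1L)
      env <- new.env(parent = baseenv())
      for (j in seq_len(k))
        assign(regs[j], as.logical(bitwAnd(bitwShiftR(idx, j - 1L), 1L)),
               envir = env)
      as.integer(eval(expr, env))
    })
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      idx0 <- which(bitwAnd(seq_len(2L^k) - 1L, bit) == 0L)
      d <- tt[idx0 + bit] - tt[idx0]
      s <- if (any(d > 0L) && !any(d < 0L)) 1L
           else if (any(d < 0L) && !any(d > 0L)) -1L
           else if (all(d == 0L)) 0L
           else stop(sprintf("non-monotone dependence of %s on %s", nm, regs[j]))
      if (s != 0L)
        out[[length(out) + 1L]] <- data.frame(source = regs[j], target = nm,
                                              sign = s)
    }
  }
  if (!length(out))
    return(data.frame(source = character(), target = character(),
                      sign = integer()))
  do.call(rbind, out)
}
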