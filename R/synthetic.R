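#' Seeded random Boolean networks
#'
#' Draws a reproducible random Boolean network for engine validation:
#' every node is internal, in-degrees are uniform on
#' `1..max_in_degree`, regulators are sampled without replacement
#' (self-loops allowed), and each regulation is an activation with
#' probability `activation_fraction` (else an inhibition).  Rules come
#' from one of three monotone families:
#' \describe{
#'   \item{`and_not`}{`(OR of activators) & !(OR of inhibitors)` -- the
#'     default template of the NSCLC checkpoint model, so engine tests
#'     exercise the same rule shapes the analysis uses.}
#'   \item{`nested_canalyzing`}{a random monotone nested canalyzing
#'     function over the regulators in random order.}
#'   \item{`random_monotone`}{a random monotone DNF (OR of up to three
#'     AND-terms of signed literals), resampled until every regulator
#'     is effective.}
#' }
#' Identical `config` (including `seed`) gives a byte-identical model.
#'
#' @param n_nodes node count (use <= 14 with the brute-force oracle).
#' @param max_in_degree largest in-degree (< `n_nodes` + 1).
#' @param activation_fraction probability that a regulation activates.
#' @param rule_template `"and_not"`, `"nested_canalyzing"` or
#'   `"random_monotone"`.
#' @param seed integer seed.
#' @return a validated [boolean_model()].
#' @export
random_boolean_network <- function(n_nodes, max_in_degree = 3L,
                                   activation_fraction = 0.5,
                                   rule_template = c("and_not",
                                                     "nested_canalyzing",
                                                     "random_monotone"),
                                   seed = 1L) {
  rule_template <- match.arg(rule_template)
  stopifnot(n_nodes >= 1L, max_in_degree >= 1L,
            activation_fraction >= 0, activation_fraction <= 1)
  if (max_in_degree > n_nodes)
    stop("max_in_degree exceeds node count (regulators are sampled ",
         "without replacement)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  names <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- data.frame(name = names, kind = "internal", symbol = names,
                      stringsAsFactors = FALSE)
  edges <- list(); rules <- list()
  for (i in seq_len(n_nodes)) {
    repeat {
      k <- sample.int(max_in_degree, 1L)
      regs <- sort(sample.int(n_nodes, k))
      sg <- ifelse(stats::runif(k) < activation_fraction, 1L, -1L)
      expr <- switch(rule_template,
        and_not = and_not_rule(names[regs], sg),
        nested_canalyzing = ncf_rule(names[regs], sg),
        random_monotone = dnf_rule(names[regs], sg))
      if (all_regulators_effective(expr, names[regs], sg)) break
    }
    edges[[i]] <- data.frame(source = names[regs], target = names[i],
                             sign = sg, stringsAsFactors = FALSE)
    rules[[names[i]]] <- expr
  }
  boolean_model(nodes, do.call(rbind, edges), rules)
}

lit <- function(name, sign) {
  if (sign > 0) as.name(name) else call("!", as.name(name))
}

and_not_rule <- function(regs, signs) {
  act <- regs[signs > 0]; inh <- regs[signs < 0]
  or_join <- function(v) Reduce(function(a, b) call("|", a, b),
                                lapply(v, as.name))
  if (!length(inh)) return(or_join(act))
  inh_part <- call("!", if (length(inh) > 1L)
    call("(", or_join(inh)) else as.name(inh))
  if (!length(act)) return(inh_part)
  act_part <- if (length(act) > 1L) call("(", or_join(act)) else as.name(act)
  call("&", act_part, inh_part)
}

ncf_rule <- function(regs, signs) {
  ord <- sample.int(length(regs))
  expr <- lit(regs[ord[1L]], signs[ord[1L]])
  for (j in seq_along(ord)[-1L]) {
    op <- if (stats::runif(1) < 0.5) "&" else "|"
    expr <- call(op, lit(regs[ord[j]], signs[ord[j]]), call("(", expr))
  }
  expr
}

dnf_rule <- function(regs, signs) {
  k <- length(regs)
  m <- sample.int(3L, 1L)
  terms <- lapply(seq_len(m), function(i) {
    pick <- which(stats::runif(k) < 0.6)
    if (!length(pick)) pick <- sample.int(k, 1L)
    Reduce(function(a, b) call("&", a, b),
           lapply(pick, function(j) lit(regs[j], signs[j])))
  })
  Reduce(function(a, b) call("|", a, call("(", b)), terms)
}

all_regulators_effective <- function(expr, regs, signs) {
  k <- length(regs)
  idx <- 0:(2L^k - 1L)
  env <- new.env(parent = baseenv())
  for (j in seq_len(k))
    assign(regs[j], as.logical(bitwAnd(bitwShiftR(idx, j - 1L), 1L)),
           envir = env)
  tt <- as.integer(eval(expr, env))
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    i0 <- which(bitwAnd(idx, bit) == 0L)
    d <- tt[i0 + bit] - tt[i0]
    ok <- if (signs[j] > 0) any(d > 0L) && !any(d < 0L)
          else any(d < 0L) && !any(d > 0L)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Brute-force attractor oracle
#'
#' Computes attractors from the FULL 2^n asynchronous state transition
#' graph (every state, not just a reachable set) by terminal-SCC
#' analysis.  Exhaustive and therefore exact; guarded at n <= 14 nodes.
#' Used to validate [fixed_points()], [find_attractors()] and the
#' Monte Carlo engine on synthetic fixtures.
#'
#' @param model a [boolean_model()].
#' @param p a [perturbation()].
#' @return list of attractors as in [find_attractors()].
#' @export
brute_force_attractors <- function(model, p = perturbation()) {
  n <- model$n
  if (n > 14L) stop("brute-force oracle limited to 14 nodes (2^n states)")
  p <- as_perturbation(p)
  all_states <- as.matrix(expand.grid(rep(list(0:1), n))[, seq_len(n)])
  colnames(all_states) <- model$nodes$name
  if (length(p)) {
    # only clamp-consistent states exist under a perturbation
    ci <- node_index(model, names(p))
    keep <- rowSums(all_states[, ci, drop = FALSE] ==
                      matrix(as.integer(p), nrow(all_states), length(p),
                             byrow = TRUE)) == length(p)
    all_states <- all_states[keep, , drop = FALSE]
  }
  ns_all <- nrow(all_states)
  from <- list(); to <- list()
  key <- function(m) apply(m, 1L, paste, collapse = "")
  keys <- key(all_states)
  # compile once per input-value combination (inputs are frozen)
  input_idx <- which(model$nodes$kind == "input")
  input_sig <- if (length(input_idx))
    apply(all_states[, input_idx, drop = FALSE], 1L, paste, collapse = "")
  else rep("", nrow(all_states))
  for (sig in unique(input_sig)) {
    rows <- which(input_sig == sig)
    cm <- compile_model(model, p, all_states[rows[1L], ])
    for (r in rows) {
      succ <- .cpp_async_successors(cm, all_states[r, ])
      if (nrow(succ)) {
        from[[length(from) + 1L]] <- rep(r, nrow(succ))
        to[[length(to) + 1L]] <- match(key(succ), keys)
      }
    }
  }
  from <- unlist(from); to <- unlist(to)
  if (is.null(from)) from <- integer(0)
  if (is.null(to)) to <- integer(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = TRUE, vertices = data.frame(name = seq_len(ns_all)))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership[as.character(seq_len(ns_all))]
  leaving <- unique(memb[from][memb[from] != memb[to]])
  terminal <- setdiff(seq_len(comp$no), leaving)
  out <- list()
  for (tc in terminal) {
    idx <- which(memb == tc)
    states <- all_states[idx, , drop = FALSE]
    out[[length(out) + 1L]] <- list(
      states = states,
      kind = if (length(idx) == 1L) "fixed_point" else "cyclic",
      phenotype = classify_attractor(model, states))
  }
  out[order(vapply(out, function(a)
    paste(a$states[1L, ], collapse = ""), ""))]
}

#' Write a random-network fixture to disk
#'
#' Generates a seeded random network, writes its `.bnet` file next to a
#' YAML manifest recording the generator configuration and the
#' attractor count established by the brute-force oracle, so a fixture
#' can be regenerated and re-verified from its manifest alone.
#'
#' @inheritParams random_boolean_network
#' @param dir output directory (created if missing).
#' @param name fixture base name (default `net_<seed>`).
#' @return invisibly, a list with `bnet` and `manifest` paths.
#' @export
write_network_fixture <- function(dir, n_nodes, max_in_degree = 3L,
                                  activation_fraction = 0.5,
                                  rule_template = "and_not",
                                  seed = 1L,
                                  name = sprintf("net_%03d", seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- random_boolean_network(n_nodes, max_in_degree, activation_fraction,
                              rule_template, seed)
  atts <- brute_force_attractors(m)
  bnet <- file.path(dir, paste0(name, ".bnet"))
  manifest <- file.path(dir, paste0(name, ".yaml"))
  write_bnet(m, bnet)
  yaml::write_yaml(list(
    name = name,
    config = list(n_nodes = as.integer(n_nodes),
                  max_in_degree = as.integer(max_in_degree),
                  activation_fraction = activation_fraction,
                  rule_template = rule_template,
                  seed = as.integer(seed)),
    oracle = list(
      n_attractors = length(atts),
      n_fixed_points = sum(vapply(atts, `[[`, "", "kind") == "fixed_point")
    )), manifest)
  invisible(list(bnet = bnet, manifest = manifest))
}
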