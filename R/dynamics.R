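#' Compile a model for the dynamics engine
#'
#' Lowers a [boolean_model()] to per-node truth tables plus a clamp
#' vector, the representation the C++ stepping kernel consumes.  Input
#' nodes are clamped to their value in `root` (inputs are parameters of
#' a run, never updated); perturbation clamps override everything.
#'
#' @param model a [boolean_model()].
#' @param p a [perturbation()] (default wild type).
#' @param root state supplying the input-node values.
#' @return opaque list consumed by the `.cpp_*` kernels.
#' @keywords internal
compile_model <- function(model, p = perturbation(), root) {
  root <- as_state(model, root)
  cl <- clamp_vector(model, p, root)
  regs <- vector("list", model$n)
  tables <- vector("list", model$n)
  for (i in seq_len(model$n)) {
    if (cl[i] >= 0L) next
    nm <- model$nodes$name[i]
    rg <- regulators(model, nm)
    regs[[i]] <- match(rg, model$nodes$name) - 1L
    tables[[i]] <- rule_truth_table(model, nm)
  }
  list(n = model$n, regs = regs, tables = tables, clamp = cl)
}

#' Asynchronous successors of a state
#'
#' One successor per unclamped, non-input node whose rule value
#' disagrees with its current value; each successor flips exactly that
#' node.  The empty set identifies a fixed point.  Successor rows
#' follow declared node order of the flipped node.
#'
#' @param model a [boolean_model()].
#' @param state a state vector (see [as_state()]).
#' @param p a [perturbation()].
#' @return integer matrix, one successor state per row (possibly 0 rows).
#' @export
async_successors <- function(model, state, p = perturbation()) {
  state <- as_state(model, state)
  cm <- compile_model(model, p, state)
  out <- .cpp_async_successors(cm, state)
  colnames(out) <- model$nodes$name
  out
}

#' Is a state a fixed point?
#' @inheritParams async_successors
#' @return logical scalar.
#' @export
is_fixed_point <- function(model, state, p = perturbation()) {
  nrow(async_successors(model, state, p)) == 0L
}

#' Reachable state transition graph
#'
#' Breadth-first closure of the asynchronous dynamics from `root`.
#' Vertices are network states, arcs are single-node updates.  Errors
#' if more than `max_states` states are reachable (the scenario then
#' needs sampling, not exhaustive enumeration).
#'
#' @inheritParams async_successors
#' @param root initial state.
#' @param max_states state budget (default 2e6).
#' @return An object of class `stg`: list with `states` (matrix, row 1
#'   = root), `from`/`to` (1-based arc indices into `states`), `model`,
#'   `perturbation`.
#' @export
build_stg <- function(model, root, p = perturbation(), max_states = 2e6) {
  root <- as_state(model, root)
  cm <- compile_model(model, p, root)
  res <- .cpp_build_stg(cm, root, as.double(max_states))
  if (isTRUE(res$overflow))
    stop("state budget exceeded (", max_states,
         " states); use sampling instead of exhaustive STG")
  colnames(res$states) <- model$nodes$name
  structure(list(states = res$states, from = res$from, to = res$to,
                 model = model, perturbation = as_perturbation(p)),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat(sprintf("Asynchronous STG: %d states, %d transitions\n",
              nrow(x$states), length(x$from)))
  invisible(x)
}

#' Attractors of a state transition graph
#'
#' Terminal strongly connected components of the STG: components with
#' no arc leaving them.  A singleton terminal component with no
#' self-arc is a fixed point (steady state); a terminal component with
#' two or more states is a cyclic attractor.  Each attractor is tagged
#' with its phenotype from the model's output nodes.
#'
#' @param stg an [build_stg()] result.
#' @return list of attractors, each a list with `states` (matrix),
#'   `kind` (`"fixed_point"`/`"cyclic"`) and `phenotype`.  Ordered by
#'   first-reached state.
#' @export
find_attractors <- function(stg) {
  ns <- nrow(stg$states)
  g <- igraph::graph_from_data_frame(
    data.frame(from = stg$from, to = stg$to),
    directed = TRUE, vertices = data.frame(name = seq_len(ns)))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership[as.character(seq_len(ns))]
  # terminal: no arc from the component to another component
  leaving <- unique(memb[stg$from][memb[stg$from] != memb[stg$to]])
  terminal <- setdiff(seq_len(comp$no), leaving)
  out <- list()
  for (tc in terminal) {
    idx <- which(memb == tc)
    states <- stg$states[idx, , drop = FALSE]
    kind <- if (length(idx) == 1L) "fixed_point" else "cyclic"
    out[[length(out) + 1L]] <- list(
      states = states, kind = kind,
      phenotype = classify_attractor(stg$model, states))
  }
  out[order(vapply(out, function(a) min(match(
    apply(a$states, 1L, paste, collapse = ""),
    apply(stg$states, 1L, paste, collapse = ""))), 1)) ]
}

#' Complete fixed-point enumeration
#'
#' Finds every steady state of the asynchronous dynamics (equivalently,
#' of the synchronous dynamics: fixed points are update-scheme
#' independent) by depth-first branch-and-prune with unit propagation
#' over partial node assignments -- never by enumerating 2^n states.  A
#' node whose regulators are all assigned has a forced value; any
#' contradiction with an existing assignment prunes the branch.
#'
#' Input nodes: if `inputs` is `NULL` they are treated as free branch
#' variables, so the result covers every input combination (the NSCLC
#' wild type yields its three fixed points in one call).  Supplying
#' `inputs` (named 0/1 vector) restricts to those input values.
#'
#' @param model a [boolean_model()].
#' @param p a [perturbation()].
#' @param inputs optional named 0/1 vector over the input nodes.
#' @return integer matrix, one fixed point per row (0 rows if none),
#'   columns named by node.
#' @export
fixed_points <- function(model, p = perturbation(), inputs = NULL) {
  p <- as_perturbation(p)
  n <- model$n
  cl <- rep(NA_integer_, n)
  if (length(p)) cl[node_index(model, names(p))] <- as.integer(p)
  if (!is.null(inputs)) {
    i <- node_index(model, names(inputs))
    if (!all(model$nodes$kind[i] == "input"))
      stop("`inputs` must name input nodes only")
    free <- is.na(cl[i])
    cl[i[free]] <- as.integer(inputs)[free]
  }
  is_input <- model$nodes$kind == "input"
  regs <- vector("list", n)
  tabs <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_input[i]) next
    rg <- regulators(model, model$nodes$name[i])
    regs[[i]] <- match(rg, model$nodes$name)
    tabs[[i]] <- rule_truth_table(model, model$nodes$name[i])
  }
  # constrained node: has a rule and is not clamped by the perturbation
  constrained <- !is_input & is.na(cl)
  found <- list()

  forced_value <- function(a, i) {
    # value of node i's rule under full regulator assignment (NA if not
    # all regulators assigned yet)
    r <- regs[[i]]
    if (length(r) && anyNA(a[r])) return(NA_integer_)
    idx <- if (length(r)) sum(a[r] * bitwShiftL(1L, seq_along(r) - 1L)) else 0L
    tabs[[i]][idx + 1L]
  }

  propagate <- function(a) {
    repeat {
      changed <- FALSE
      for (i in which(constrained)) {
        v <- forced_value(a, i)
        if (is.na(v)) next
        if (is.na(a[i])) { a[i] <- v; changed <- TRUE }
        else if (a[i] != v) return(NULL)
      }
      if (!changed) return(a)
    }
  }

  search <- function(a) {
    a <- propagate(a)
    if (is.null(a)) return(invisible())
    i <- which(is.na(a))[1L]
    if (is.na(i)) {
      found[[length(found) + 1L]] <<- a
      return(invisible())
    }
    for (v in c(0L, 1L)) { a2 <- a; a2[i] <- v; search(a2) }
  }

  search(cl)
  if (!length(found)) {
    out <- matrix(integer(), 0L, n)
  } else {
    out <- do.call(rbind, found)
    out <- out[order(apply(out, 1L, paste, collapse = "")), , drop = FALSE]
  }
  colnames(out) <- model$nodes$name
  rownames(out) <- NULL
  out
}

#' Exact phenotype absorption probabilities
#'
#' Treats the STG as a finite Markov chain with uniform probability
#' over the enabled transitions of each state, lumps each terminal SCC
#' into one absorbing class, and solves the linear system
#' `(I - Q) x = b` for the absorption probabilities from the STG root.
#' This is the deterministic cross-check for [monte_carlo_phenotypes()].
#'
#' @param stg a [build_stg()] result (complete, >= 1 terminal SCC).
#' @return A `phenotype_distribution`: data.frame with one row per
#'   attractor (`attractor`, `kind`, `phenotype`, `probability`) and
#'   attributes `method = "exact"`, `attractors`.
#' @export
exact_absorption <- function(stg) {
  atts <- find_attractors(stg)
  if (!length(atts)) stop("STG has no terminal SCC")
  ns <- nrow(stg$states)
  keys <- apply(stg$states, 1L, paste, collapse = "")
  class_of <- rep(NA_integer_, ns)
  for (k in seq_along(atts)) {
    class_of[match(apply(atts[[k]]$states, 1L, paste, collapse = ""), keys)] <- k
  }
  transient <- which(is.na(class_of))
  probs <- numeric(length(atts))
  if (!length(transient)) {
    probs[class_of[1L]] <- 1
  } else {
    outdeg <- tabulate(stg$from, nbins = ns)
    w <- 1 / outdeg[stg$from]
    tr_id <- match(seq_len(ns), transient)   # NA for absorbed states
    ft <- tr_id[stg$from]
    keep <- !is.na(ft)
    tt <- tr_id[stg$to]
    # Q: transient -> transient
    qk <- keep & !is.na(tt)
    Q <- Matrix::sparseMatrix(i = ft[qk], j = tt[qk], x = w[qk],
                              dims = c(length(transient), length(transient)))
    # B: transient -> attractor class
    bk <- keep & is.na(tt)
    B <- Matrix::sparseMatrix(i = ft[bk], j = class_of[stg$to[bk]],
                              x = w[bk],
                              dims = c(length(transient), length(atts)))
    root_id <- tr_id[1L]
    if (is.na(root_id)) {
      probs[class_of[1L]] <- 1
    } else if (length(transient) <= 2e5) {
      X <- Matrix::solve(Matrix::Diagonal(length(transient)) - Q, B)
      probs <- as.numeric(X[root_id, ])
    } else {
      # large chain: sparse LU fill-in is prohibitive, iterate
      # p <- Q p + B instead (geometric convergence for absorbing
      # chains)
      P <- as.matrix(B[, , drop = FALSE]) * 0
      P <- Matrix::Matrix(P, sparse = FALSE)
      for (it in seq_len(100000L)) {
        P2 <- Q %*% P + B
        delta <- max(abs(P2 - P))
        P <- P2
        if (delta < 1e-12) break
      }
      if (delta >= 1e-12)
        stop("absorption iteration did not converge")
      probs <- as.numeric(P[root_id, ])
    }
  }
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  phenotype_distribution(atts, probs, method = "exact",
                         n_runs = NA_integer_, seed = NA_integer_)
}

phenotype_distribution <- function(attractors, probs, method, n_runs, seed) {
  df <- data.frame(
    attractor = seq_along(attractors),
    kind = vapply(attractors, `[[`, "", "kind"),
    phenotype = vapply(attractors, `[[`, "", "phenotype"),
    probability = probs,
    stringsAsFactors = FALSE)
  structure(df, method = method, n_runs = n_runs, seed = seed,
            attractors = attractors,
            class = c("phenotype_distribution", "data.frame"))
}

#' @export
print.phenotype_distribution <- function(x, ...) {
  meth <- attr(x, "method")
  hdr <- if (identical(meth, "monte_carlo"))
    sprintf("Monte Carlo phenotype distribution (%d runs, seed %d)\n",
            attr(x, "n_runs"), attr(x, "seed"))
  else "Exact absorption phenotype distribution\n"
  cat(hdr)
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Phenotype probabilities per output label
#'
#' Collapses a [monte_carlo_phenotypes()] / [exact_absorption()] result
#' over attractors sharing a phenotype label.
#' @param dist a `phenotype_distribution`.
#' @return named numeric vector of probabilities summing to 1.
#' @export
phenotype_probabilities <- function(dist) {
  tapply(dist$probability, dist$phenotype, sum)[unique(dist$phenotype)]
}

#' Monte Carlo phenotype probability estimation
#'
#' Simulates `n_runs` random walks from `root`, drawing the successor
#' uniformly among the enabled asynchronous transitions, until
#' absorption in a fixed point.  Walks still unabsorbed after
#' `max_steps` steps are routed to cycle detection: the reachable STG
#' from the stranded state is closed and, when it contains a single
#' (cyclic) attractor, the walk is credited to it; if no cyclic
#' attractor exists anywhere in the reachable dynamics this is an
#' inconsistency and a hard error.  Reproducible per `seed`.
#'
#' @inheritParams build_stg
#' @param n_runs number of walks (>= 1).
#' @param seed integer RNG seed.
#' @param max_steps per-walk step budget before cycle routing.
#' @return A `phenotype_distribution` with `method = "monte_carlo"`;
#'   fractions have denominator `n_runs`.
#' @export
monte_carlo_phenotypes <- function(model, root, p = perturbation(),
                                   n_runs = 1e5, seed = 1L,
                                   max_steps = 10000L) {
  stopifnot(n_runs >= 1)
  root <- as_state(model, root)
  cm <- compile_model(model, p, root)
  set.seed(seed)
  res <- .cpp_monte_carlo(cm, root, as.integer(n_runs),
                          as.integer(max_steps))
  canon <- function(states)
    paste(sort(apply(states, 1L, paste, collapse = "")), collapse = "|")
  counts <- list()   # canonical state-set key -> list(states, kind, count)
  nab <- nrow(res$absorbed_states)
  if (nab) for (r in seq_len(nab)) {
    st <- matrix(res$absorbed_states[r, ], 1L,
                 dimnames = list(NULL, model$nodes$name))
    counts[[canon(st)]] <-
      list(states = st, kind = "fixed_point", count = res$absorbed_count[r])
  }
  nun <- nrow(res$unresolved_states)
  if (nun) for (r in seq_len(nun)) {
    st <- res$unresolved_states[r, ]
    sub <- build_stg(model, st, p)
    atts <- find_attractors(sub)
    if (!any(vapply(atts, `[[`, "", "kind") == "cyclic"))
      stop("walk exceeded max_steps but the reachable dynamics has no ",
           "cyclic attractor -- inconsistent simulation state")
    if (length(atts) != 1L)
      stop("unabsorbed walk can still reach ", length(atts),
           " attractors; increase max_steps")
    key <- canon(atts[[1L]]$states)
    if (is.null(counts[[key]]))
      counts[[key]] <- list(states = atts[[1L]]$states, kind = "cyclic",
                            count = 0L)
    counts[[key]]$count <- counts[[key]]$count + res$unresolved_count[r]
  }
  ord <- order(names(counts))
  counts <- counts[ord]
  atts <- lapply(counts, function(a)
    list(states = a$states, kind = a$kind,
         phenotype = classify_attractor(model, a$states)))
  probs <- vapply(counts, function(a) a$count / n_runs, 0)
  phenotype_distribution(atts, unname(probs), method = "monte_carlo",
                         n_runs = as.integer(n_runs),
                         seed = as.integer(seed))
}
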