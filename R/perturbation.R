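#' In silico perturbations (KO / E1)
#'
#' A perturbation is a clamp map from node names to 0 (knockout, loss
#' of function, "KO") or 1 (ectopic over-expression, gain of function,
#' "E1").  Clamped nodes are frozen: their rules are replaced by
#' constants and the dynamics never updates them.  The empty map is the
#' wild type.
#'
#' @param ... clamps given as `name = value` pairs, or a single named
#'   vector/list.
#' @return An object of class `perturbation` (named integer vector).
#' @examples
#' perturbation(miR34a = 1, UFC1 = 0)   # miR-34a E1 + UFC1 KO
#' perturbation()                       # wild type
#' @export
perturbation <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1L]]) || length(args[[1L]]) != 1L ||
       !is.null(names(args[[1L]])))) {
    args <- as.list(args[[1L]])
  }
  v <- vapply(args, function(x) as.integer(x), integer(1))
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
    stop("every clamp must be named")
  if (!all(v %in% c(0L, 1L))) stop("clamp values must be 0 (KO) or 1 (E1)")
  if (anyDuplicated(names(v))) stop("duplicated clamp for ",
                                    names(v)[duplicated(names(v))][1])
  structure(v, class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  if (!length(x)) {
    cat("wild type (no clamps)\n")
  } else {
    cat(paste0(names(x), ifelse(unclass(x) == 1L, " E1", " KO"),
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply a perturbation to a model
#'
#' Returns a new model in which each clamped node's rule is the
#' constant 0 or 1 and its incoming edges are removed (a clamped node
#' no longer listens to its regulators).  The original model is left
#' untouched; applying the same perturbation twice is idempotent.
#' Clamping an input node fixes the input's value for every run.
#'
#' @param model a [boolean_model()].
#' @param p a [perturbation()].
#' @return a `boolean_model` with an added `clamped` attribute (named
#'   integer vector of clamps).
#' @export
apply_perturbation <- function(model, p) {
  p <- as_perturbation(p)
  if (!length(p)) {
    attr(model, "clamped") <- integer()
    return(model)
  }
  node_index(model, names(p))
  m <- model
  for (nm in names(p)) {
    if (m$nodes$kind[match(nm, m$nodes$name)] != "input") {
      m$rules[[nm]] <- if (p[[nm]] == 1L) quote(TRUE) else quote(FALSE)
    }
    m$edges <- m$edges[m$edges$target != nm, , drop = FALSE]
  }
  attr(m, "clamped") <- stats::setNames(as.integer(p), names(p))
  m
}

as_perturbation <- function(p) {
  if (inherits(p, "perturbation")) return(p)
  if (is.null(p)) return(perturbation())
  perturbation(p)
}

# Clamp vector in node order: -1 free, 0/1 clamped.  Input nodes are
# clamped to their value in `state0` (inputs are run parameters, never
# updated).
clamp_vector <- function(model, p, state0) {
  p <- as_perturbation(p)
  cl <- rep(-1L, model$n)
  inputs <- which(model$nodes$kind == "input")
  cl[inputs] <- as.integer(state0[inputs])
  if (length(p)) cl[node_index(model, names(p))] <- as.integer(p)
  cl
}

#' Phenotype of an attractor
#'
#' Reads the output nodes of every state in an attractor.  A fixed
#' point maps to the unique output that is ON (`"None"` when all are
#' OFF); a state with two or more outputs ON, or a cyclic attractor
#' whose member states disagree on the outputs, is `"Mixed"`.  The
#' NSCLC checkpoint model is expected never to produce `"Mixed"`: its
#' outputs are mutually exclusive in every reachable attractor, and the
#' analysis functions assert this.
#'
#' @param model a [boolean_model()].
#' @param states matrix of attractor states (rows) or a single state
#'   vector.
#' @return character scalar: one of the output-node display symbols,
#'   `"None"`, or `"Mixed"`.
#' @export
classify_attractor <- function(model, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  if (nrow(states) == 0L) stop("empty attractor")
  out_idx <- which(model$nodes$kind == "output")
  if (!length(out_idx)) return("None")
  labels <- apply(states, 1L, function(s) {
    on <- out_idx[s[out_idx] == 1L]
    if (length(on) == 0L) "None"
    else if (length(on) > 1L) "Mixed"
    else model$nodes$symbol[on]
  })
  if (length(unique(labels)) > 1L) "Mixed" else labels[[1L]]
}
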