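# Shared fixtures: tiny hand-checkable networks and a cached copy of
# the NSCLC bundle (building it enumerates the wild-type fixed points,
# so do it once per test run).

toy_toggle <- function() {
  # mutual inhibition: bistable toggle switch
  boolean_model(
    nodes = data.frame(name = c("A", "B"), kind = "internal"),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       sign = c(-1L, -1L)),
    rules = list(A = "!B", B = "!A"))
}

toy_negative_loop <- function() {
  # A activates B, B inhibits A: sustained oscillation
  boolean_model(
    nodes = data.frame(name = c("A", "B"), kind = "internal"),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       sign = c(1L, -1L)),
    rules = list(A = "!B", B = "A"))
}

toy_mutual_activation <- function() {
  boolean_model(
    nodes = data.frame(name = c("A", "B"), kind = "internal"),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       sign = c(1L, 1L)),
    rules = list(A = "B", B = "A"))
}

toy_self_activator <- function() {
  boolean_model(
    nodes = data.frame(name = "A", kind = "internal"),
    edges = data.frame(source = "A", target = "A", sign = 1L),
    rules = list(A = "A"))
}

toy_with_outputs <- function() {
  # input -> X -> two exclusive outputs
  boolean_model(
    nodes = data.frame(name = c("I", "X", "Good", "Bad"),
                       kind = c("input", "internal", "output", "output")),
    edges = data.frame(source = c("I", "X", "X"),
                       target = c("X", "Good", "Bad"),
                       sign = c(1L, 1L, -1L)),
    rules = list(X = "I", Good = "X", Bad = "!X"))
}

attractor_keys <- function(atts) {
  sort(vapply(atts, function(a)
    paste(sort(apply(a$states, 1L, paste, collapse = "")), collapse = "|"),
    ""))
}

state_keys <- function(m) {
  if (nrow(m) == 0L) return(character())
  sort(apply(m, 1L, paste, collapse = ""))
}

nsclc_cached <- local({
  bundle <- NULL
  function() {
    if (is.null(bundle)) bundle <<- build_nsclc_model()
    bundle
  }
})
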