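#' The NSCLC G1/S checkpoint model
#'
#' Loads the packaged 32-node Boolean model of the DNA-damage-activated
#' G1/S checkpoint in non-small cell lung cancer, in which the lncRNAs
#' ANRIL and UFC1 sponge miR-34a, miR-34a silences eight
#' proliferation/survival factors (Myc, HDAC1, Sirt-1, E2F1, Cdc25A,
#' BCL2 and both G1/S cyclin-CDK complexes), and a two-arm p53 module
#' (arrester p53-A vs killer p53-K) decides between senescence and
#' apoptosis.  The single input is DNA damage; the outputs are
#' Proliferation, Senescence and Apoptosis.
#'
#' The returned bundle carries the validated [boolean_model()], the
#' named scenario catalogue (every knockout/over-expression experiment
#' analysed with the model, plus the 24 circuit-screen triples), and
#' the proliferative root state used by the dynamics runs.
#'
#' @return An object of class `nsclc_bundle`: list with `model`,
#'   `scenarios` (named list of `list(input, clamps, expected)`) and
#'   `fixed_points` (the three wild-type fixed points).
#' @examples
#' bundle <- build_nsclc_model()
#' bundle$model
#' fixed_points(bundle$model)
#' @export
build_nsclc_model <- function() {
  path <- system.file("extdata", "nsclc_g1s.bnet", package = "g1sbn",
                      mustWork = TRUE)
  model <- read_bnet(path)
  scen_path <- system.file("extdata", "scenarios.yaml", package = "g1sbn",
                           mustWork = TRUE)
  scenarios <- yaml::read_yaml(scen_path)
  scenarios <- lapply(scenarios, function(s) {
    list(input = as.integer(s$input),
         clamps = if (length(s$clamps)) unlist(s$clamps) else integer(),
         expected = as.character(s$expected))
  })
  # the 24 circuit-perturbation triples of the three novel circuits
  for (circ in list(c("miR34a", "E2F1", "ANRIL"),
                    c("miR34a", "E2F1", "UFC1"),
                    c("miR34a", "Myc", "ANRIL"))) {
    for (a in 0:1) for (b in 0:1) for (d in 0:1) {
      vals <- c(a, b, d)
      nm <- paste0("screen_", paste(circ, collapse = "_"), "_",
                   paste(ifelse(vals == 1, "E1", "KO"), collapse = "_"))
      scenarios[[nm]] <- list(
        input = 1L,
        clamps = stats::setNames(vals, circ),
        # senescence is recovered only when miR-34a is forced ON while
        # its circuit partner (E2F1 or Myc) is knocked out
        expected = if (a == 1 && b == 0) c("Senescence", "Apoptosis")
                   else "Apoptosis")
    }
  }
  fps <- fixed_points(model)
  structure(list(model = model, scenarios = scenarios,
                 fixed_points = fps),
            class = "nsclc_bundle")
}

#' @export
print.nsclc_bundle <- function(x, ...) {
  cat("NSCLC G1/S checkpoint model bundle\n")
  print(x$model)
  cat(length(x$scenarios), "catalogued scenarios\n")
  invisible(x)
}

#' Resolve a scenario by name
#'
#' @param bundle an [build_nsclc_model()] bundle.
#' @param name scenario name (see `names(bundle$scenarios)`), e.g.
#'   `"WT_damage"`, `"UFC1_KO_miR34a_E1"`,
#'   `"screen_miR34a_E2F1_ANRIL_E1_KO_KO"`.
#' @return list with `input` (DNA_Damage value), `perturbation` (a
#'   [perturbation()]) and `expected` (phenotype labels).
#' @export
nsclc_scenario <- function(bundle, name) {
  s <- bundle$scenarios[[name]]
  if (is.null(s)) stop("unknown scenario: ", name)
  list(input = s$input,
       perturbation = if (length(s$clamps)) perturbation(as.list(s$clamps))
                      else perturbation(),
       expected = s$expected)
}

#' Root state of a dynamics run
#'
#' The biological initial condition: the wild-type damage-free
#' proliferative fixed point, with `DNA_Damage` switched to the
#' scenario's input value and the perturbation's clamps applied (a
#' cycling cell hit by genotoxic stress under the given genetic
#' background).
#'
#' @param bundle an [build_nsclc_model()] bundle.
#' @param input 0/1 DNA damage value.
#' @param p a [perturbation()].
#' @return named state vector over the model's nodes.
#' @export
nsclc_root_state <- function(bundle, input = 1L, p = perturbation()) {
  fps <- bundle$fixed_points
  prolif <- fps[fps[, "DNA_Damage"] == 0 &
                  fps[, "Proliferation"] == 1, , drop = FALSE]
  stopifnot(nrow(prolif) == 1L)
  root <- prolif[1L, ]
  root["DNA_Damage"] <- as.integer(input)
  p <- as_perturbation(p)
  if (length(p)) root[names(p)] <- as.integer(p)
  root
}

# The three output nodes never regulate anything (a validated
# invariant), so dynamics can run on the 29-node subnetwork and the
# phenotype be read off the output rules afterwards.  This cuts the
# reachable state space by up to 2^3 without changing attractors or
# absorption probabilities.
drop_outputs <- function(model) {
  keep <- model$nodes$kind != "output"
  nodes <- model$nodes[keep, , drop = FALSE]
  out_rules <- model$rules[model$nodes$name[!keep]]
  rules <- model$rules[intersect(names(model$rules), nodes$name)]
  edges <- model$edges[model$edges$target %in% nodes$name, , drop = FALSE]
  list(model = boolean_model(nodes, edges, rules, validate = FALSE),
       out_rules = out_rules,
       out_symbols = stats::setNames(model$nodes$symbol[!keep],
                                     model$nodes$name[!keep]))
}

output_phenotype <- function(red, state) {
  env <- as.list(as.logical(state))
  names(env) <- red$model$nodes$name
  on <- names(red$out_rules)[vapply(red$out_rules, function(e)
    isTRUE(eval(e, env, baseenv())), TRUE)]
  if (length(on) == 0L) "None"
  else if (length(on) > 1L) "Mixed"
  else unname(red$out_symbols[on])
}

#' Run one scenario of the NSCLC model
#'
#' Applies the scenario's input and clamps, starts from
#' [nsclc_root_state()], and estimates the phenotype distribution by
#' Monte Carlo random walks (the study-scale estimator) and/or the
#' exact absorption solve (feasible when the reachable STG fits the
#' state budget).  Dynamics run on the output-free subnetwork; the
#' phenotype of each attractor is evaluated from the output rules.
#'
#' @param bundle an [build_nsclc_model()] bundle.
#' @param name scenario name.
#' @param n_runs Monte Carlo walks (default 1e5 as in the reference
#'   experiments).
#' @param seed RNG seed.
#' @param method `"monte_carlo"` or `"exact"`.
#' @param max_states STG budget for the exact method.
#' @return data.frame with columns `phenotype`, `probability` (and
#'   attributes `method`, `n_runs`, `seed`, `attractors`).
#' @export
run_scenario <- function(bundle, name, n_runs = 1e5, seed = 1L,
                         method = c("monte_carlo", "exact"),
                         max_states = 2e6) {
  method <- match.arg(method)
  sc <- nsclc_scenario(bundle, name)
  red <- drop_outputs(bundle$model)
  root <- nsclc_root_state(bundle, sc$input, sc$perturbation)
  root <- root[red$model$nodes$name]
  dist <- if (method == "monte_carlo") {
    monte_carlo_phenotypes(red$model, root, sc$perturbation,
                           n_runs = n_runs, seed = seed)
  } else {
    exact_absorption(build_stg(red$model, root, sc$perturbation,
                               max_states = max_states))
  }
  atts <- attr(dist, "attractors")
  ph <- vapply(atts, function(a) output_phenotype(red, a$states[1L, ]), "")
  agg <- tapply(dist$probability, ph, sum)
  out <- data.frame(phenotype = names(agg),
                    probability = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$probability), , drop = FALSE]
  rownames(out) <- NULL
  # outputs must be mutually exclusive in every reachable attractor
  if (any(out$phenotype == "Mixed"))
    warning("attractor with more than one output ON in scenario ", name)
  structure(out, method = method,
            n_runs = if (method == "monte_carlo") as.integer(n_runs) else NA,
            seed = if (method == "monte_carlo") as.integer(seed) else NA,
            scenario = name, attractors = atts,
            class = c("scenario_result", "data.frame"))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s (%s%s)\n", attr(x, "scenario"), attr(x, "method"),
              if (!is.na(attr(x, "n_runs")))
                sprintf(", %d runs, seed %d", attr(x, "n_runs"), attr(x, "seed"))
              else ""))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fixed points of a scenario
#'
#' Complete enumeration of the steady states under the scenario's
#' clamps at its DNA-damage value, with phenotype labels -- the
#' machine-readable analogue of one block of the published fixed-point
#' matrix.
#'
#' @inheritParams run_scenario
#' @return integer matrix of fixed points with a `phenotype` attribute
#'   (character vector, one label per row).
#' @export
scenario_fixed_points <- function(bundle, name) {
  sc <- nsclc_scenario(bundle, name)
  fp <- fixed_points(bundle$model, sc$perturbation,
                     inputs = c(DNA_Damage = sc$input))
  ph <- if (nrow(fp)) apply(fp, 1L, function(s)
    classify_attractor(bundle$model, s)) else character()
  attr(fp, "phenotype") <- ph
  fp
}

#' Check the model's calibration constraints
#'
#' Asserts every behavioural property the model is calibrated against:
#' exactly three wild-type fixed points (proliferative without damage;
#' senescent and apoptotic under damage, marked by p53-A and p53-K);
#' lncRNA knockouts force miR-34a ON in every damage fixed point;
#' lncRNA or Myc over-expression forces miR-34a OFF; miR-34a knockout
#' combinations leave only apoptosis; miR-34a over-expression or Myc
#' knockout shuts both lncRNAs down while preserving both
#' damage-response fates; and all 24 circuit-screen rows reproduce
#' their expected phenotype sets at the fixed-point level.
#'
#' @param bundle an [build_nsclc_model()] bundle.
#' @return `TRUE` invisibly; stops at the first violated constraint.
#' @export
check_nsclc_calibration <- function(bundle) {
  m <- bundle$model
  fps <- bundle$fixed_points
  stopifnot(nrow(fps) == 3L)
  ph <- apply(fps, 1L, function(s) classify_attractor(m, s))
  stopifnot(sort(ph) == c("Apoptosis", "Proliferation", "Senescence"))
  pro <- fps[ph == "Proliferation", ]
  stopifnot(pro["DNA_Damage"] == 0,
            all(pro[c("CDK46_CycD", "CDK2_CycE", "Cdc25A", "Myc",
                      "ANRIL", "UFC1")] == 1),
            pro["miR34a"] == 0)
  sen <- fps[ph == "Senescence", ]
  apo <- fps[ph == "Apoptosis", ]
  stopifnot(sen["DNA_Damage"] == 1, apo["DNA_Damage"] == 1,
            sen["p53A"] == 1, sen["p21"] == 1,
            apo["p53K"] == 1, apo["Casp3"] == 1)
  for (nm in names(bundle$scenarios)) {
    if (bundle$scenarios[[nm]]$input != 1L) next
    fp <- scenario_fixed_points(bundle, nm)
    got <- sort(unique(attr(fp, "phenotype")))
    want <- sort(bundle$scenarios[[nm]]$expected)
    if (!identical(got, want))
      stop(sprintf("scenario %s: fixed-point phenotypes {%s}, expected {%s}",
                   nm, paste(got, collapse = ","), paste(want, collapse = ",")))
    cl <- bundle$scenarios[[nm]]$clamps
    mir_free <- !"miR34a" %in% names(cl)
    if (mir_free && any(names(cl) %in% c("ANRIL", "UFC1") & cl == 0))
      stopifnot(all(fp[, "miR34a"] == 1))
    if (mir_free && any(names(cl) %in% c("ANRIL", "UFC1", "Myc") & cl == 1))
      stopifnot(all(fp[, "miR34a"] == 0))
    lnc_drivers_forced <- isTRUE(cl["E2F1"] == 1L) || isTRUE(cl["Myc"] == 1L)
    if ((isTRUE(cl["miR34a"] == 1L) || isTRUE(cl["Myc"] == 0L)) &&
        !lnc_drivers_forced) {
      for (lnc in setdiff(c("ANRIL", "UFC1"), names(cl)))
        stopifnot(all(fp[, lnc] == 0))
    }
  }
  invisible(TRUE)
}
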