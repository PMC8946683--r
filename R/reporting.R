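#' Fixed-point table across scenarios
#'
#' One row per (scenario, fixed point) with every node's value and the
#' phenotype -- the machine-readable twin of the published fixed-point
#' matrices.
#'
#' @param bundle an [build_nsclc_model()] bundle.
#' @param scenarios character vector of scenario names (default: the
#'   full named catalogue except the circuit screen).
#' @return data.frame: `scenario`, `input`, one column per node,
#'   `phenotype`.
#' @export
run_fixed_point_table <- function(bundle,
                                  scenarios = grep("^screen_",
                                                   names(bundle$scenarios),
                                                   value = TRUE,
                                                   invert = TRUE)) {
  rows <- list()
  for (nm in scenarios) {
    fp <- scenario_fixed_points(bundle, nm)
    ph <- attr(fp, "phenotype")
    for (r in seq_len(nrow(fp))) {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = nm,
                   input = bundle$scenarios[[nm]]$input,
                   stringsAsFactors = FALSE),
        as.data.frame(t(fp[r, ])),
        data.frame(phenotype = ph[r], stringsAsFactors = FALSE))
    }
  }
  do.call(rbind, rows)
}

#' Phenotype-probability report
#'
#' Monte Carlo (and optionally exact) phenotype probabilities per
#' scenario, as fractions with their run counts so the sampling error
#' stays interpretable; format as percentages only when rendering.
#'
#' @param bundle an [build_nsclc_model()] bundle.
#' @param scenarios scenario names (default: the six perturbation
#'   comparisons plus the damaged wild type).
#' @param n_runs walks per scenario.
#' @param seed RNG seed (each scenario runs with this seed).
#' @param exact also compute the exact absorption probabilities where
#'   the reachable STG fits `max_states`.
#' @param max_states STG budget for the exact cross-check.
#' @return data.frame: `scenario`, `phenotype`, `probability`,
#'   `method`, `n_runs`, `seed`.
#' @export
run_probability_report <- function(bundle,
                                   scenarios = c("WT_damage",
                                                 "UFC1_KO",
                                                 "UFC1_KO_miR34a_E1",
                                                 "ANRIL_KO",
                                                 "ANRIL_KO_miR34a_E1"),
                                   n_runs = 1e5, seed = 1L,
                                   exact = FALSE, max_states = 2e6) {
  out <- list()
  for (nm in scenarios) {
    mc <- run_scenario(bundle, nm, n_runs = n_runs, seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      scenario = nm, phenotype = mc$phenotype,
      probability = mc$probability, method = "monte_carlo",
      n_runs = n_runs, seed = seed, stringsAsFactors = FALSE)
    if (exact) {
      ex <- tryCatch(
        run_scenario(bundle, nm, method = "exact", max_states = max_states),
        error = function(e) NULL)
      if (!is.null(ex))
        out[[length(out) + 1L]] <- data.frame(
          scenario = nm, phenotype = ex$phenotype,
          probability = ex$probability, method = "exact",
          n_runs = NA, seed = NA, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Circuit report
#'
#' Full elementary-circuit inventory with signs and functionality, the
#' subset with at most three elements, and the 24-row perturbation
#' screen of the three novel sponge circuits.
#'
#' @param bundle an [build_nsclc_model()] bundle.
#' @param n_runs walks per screen row.
#' @param seed RNG seed.
#' @param screen run the 24-row circuit-perturbation screen (slower).
#' @return list with `inventory` (data.frame as [circuit_inventory()]),
#'   `short_functional` (functional circuits with <= 3 nodes), counts
#'   `n_functional` / `n_short_functional`, and (when `screen = TRUE`)
#'   `screen`: data.frame (circuit, perturbation, phenotypes).
#' @export
run_circuit_report <- function(bundle, n_runs = 3000, seed = 1L,
                               screen = TRUE) {
  inv <- circuit_inventory(bundle$model)
  short <- inv[inv$functional & inv$length <= 3L, , drop = FALSE]
  res <- list(inventory = inv,
              short_functional = short,
              n_functional = sum(inv$functional),
              n_short_functional = nrow(short))
  # reference inventory (GINsim analysis of the original rule file): 28
  # functional circuits, 16 with at most three elements; differences
  # under this rule reconstruction are reported, not silently accepted
  if (res$n_functional != 28L || res$n_short_functional != 16L)
    warning(sprintf(paste0(
      "functional-circuit counts (%d total, %d short) differ from the ",
      "reference inventory (28 total, 16 short)"),
      res$n_functional, res$n_short_functional), call. = FALSE)
  if (screen) {
    rows <- list()
    for (nm in grep("^screen_", names(bundle$scenarios), value = TRUE)) {
      pr <- run_scenario(bundle, nm, n_runs = n_runs, seed = seed)
      reached <- sort(pr$phenotype[pr$probability > 0])
      parts <- strsplit(sub("^screen_", "", nm), "_")[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        circuit = paste(parts[1:3], collapse = "/"),
        perturbation = paste(parts[4:6], collapse = "/"),
        phenotypes = paste(reached, collapse = " and "),
        stringsAsFactors = FALSE)
    }
    res$screen <- do.call(rbind, rows)
  }
  res
}

#' Export a state transition graph
#'
#' Writes the STG as a plain edge list (`from<TAB>to` state strings in
#' declared node order) or Graphviz DOT.
#'
#' @param stg a [build_stg()] result.
#' @param path output file.
#' @param format `"edgelist"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_stg <- function(stg, path, format = c("edgelist", "dot")) {
  format <- match.arg(format)
  keys <- apply(stg$states, 1L, paste, collapse = "")
  lines <- if (format == "edgelist") {
    paste(keys[stg$from], keys[stg$to], sep = "\t")
  } else {
    c("digraph stg {",
      sprintf("  \"%s\" -> \"%s\";", keys[stg$from], keys[stg$to]),
      "}")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Bar chart of a probability report
#'
#' Renders the phenotype probabilities of [run_probability_report()] as
#' a grouped bar chart.  Requires ggplot2.
#'
#' @param report data.frame from [run_probability_report()].
#' @return a ggplot object.
#' @export
plot_probability_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  report$percent <- 100 * report$probability
  ggplot2::ggplot(report,
                  ggplot2::aes(x = scenario, y = percent,
                               fill = phenotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "phenotype probability (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

utils::globalVariables(c("scenario", "percent", "phenotype"))
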