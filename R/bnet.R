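#' Write a model in the .bnet dialect
#'
#' One line per node, `target, factors`, with `&`, `|`, `!` and
#' parentheses; an input node is declared by the self-referential line
#' `target, target`.  A structured header comment block records node
#' kinds, display symbols and edge signs so a model round-trips
#' losslessly:
#' ```
#' # node <name> <kind> <symbol>
#' # edge <source> <target> <+|->
#' ```
#'
#' @param model a [boolean_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bnet <- function(model, path) {
  hdr <- c("# g1sbn Boolean network model",
           sprintf("# node %s %s %s", model$nodes$name, model$nodes$kind,
                   model$nodes$symbol),
           sprintf("# edge %s %s %s", model$edges$source,
                   model$edges$target,
                   ifelse(model$edges$sign > 0, "+", "-")))
  body <- vapply(model$nodes$name, function(nm) {
    rhs <- if (nm %in% names(model$rules))
      deparse1(model$rules[[nm]]) else nm
    sprintf("%s, %s", nm, rhs)
  }, "")
  writeLines(c(hdr, "targets, factors", body), path)
  invisible(path)
}

#' Read a model from the .bnet dialect
#'
#' Inverse of [write_bnet()].  Without the structured header, node
#' kinds default to `internal` (inputs are still recognised from
#' self-referential `target, target` lines) and edge signs are inferred
#' from the rules via [infer_edge_signs()].  The loaded model is
#' re-validated in full.
#'
#' @param path file path.
#' @param validate run [validate_model()] on the result.
#' @return a [boolean_model()].
#' @export
read_bnet <- function(path, validate = TRUE) {
  lines <- trimws(readLines(path))
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  body <- body[tolower(gsub("[ ,]", "", body)) != "targetsfactors"]

  parse_meta <- function(prefix, nf) {
    rows <- meta[startsWith(meta, prefix)]
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(strsplit(sub(prefix, "", rows), "[[:space:]]+"),
                          function(x) x[seq_len(nf)]))
  }
  node_meta <- parse_meta("# node ", 3L)
  edge_meta <- parse_meta("# edge ", 3L)

  parts <- regmatches(body, regexpr(",", body), invert = TRUE)
  targets <- trimws(vapply(parts, `[`, "", 1L))
  factors <- trimws(vapply(parts, `[`, "", 2L))
  if (anyDuplicated(targets))
    stop("duplicate rule line for ", targets[duplicated(targets)][1L])
  is_input <- factors == targets

  if (!is.null(node_meta)) {
    nodes <- data.frame(name = node_meta[, 1L], kind = node_meta[, 2L],
                        symbol = node_meta[, 3L], stringsAsFactors = FALSE)
    if (!setequal(nodes$name, targets))
      stop("header nodes and rule lines disagree")
    targets_ord <- nodes$name
  } else {
    nodes <- data.frame(name = targets,
                        kind = ifelse(is_input, "input", "internal"),
                        symbol = targets, stringsAsFactors = FALSE)
    targets_ord <- targets
  }
  rules <- stats::setNames(
    lapply(factors[!is_input], str2lang),
    targets[!is_input])
  rules <- rules[intersect(targets_ord, names(rules))]

  if (!is.null(edge_meta)) {
    edges <- data.frame(source = edge_meta[, 1L], target = edge_meta[, 2L],
                        sign = ifelse(edge_meta[, 3L] == "+", 1L, -1L),
                        stringsAsFactors = FALSE)
  } else {
    tmp <- boolean_model(nodes,
                         data.frame(source = character(),
                                    target = character(), sign = integer()),
                         rules, validate = FALSE)
    edges <- infer_edge_signs(tmp)
  }
  boolean_model(nodes, edges, rules, validate = validate)
}
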