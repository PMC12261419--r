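# Boolean AND/OR formulas over marker-profile identifiers.
#
# Grammar:   expr := term (OR term)* ;  term := atom (AND atom)* ;
#            atom := identifier | "(" expr ")"
# AND binds tighter than OR; identifiers match [A-Za-z0-9_./-]+.
# There is no NOT operator: functions are called from the joint
# presence of markers, and the grammar is deliberately monotone.

#' Parse a Boolean marker formula
#'
#' @param text Formula text, e.g. `"acsB AND fthfs OR mtaB"`.
#' @return A `rule_formula`: nested list AST with leaves
#'   `list(op = "id", id = <identifier>)` and internal nodes
#'   `list(op = "and"|"or", args = <list of >= 2 children>)`.
#' @examples
#' parse_rule("mcrA OR mtaB AND mtbA")
#' @export
parse_rule <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(trimws(text))) {
    abort("empty formula")
  }
  toks <- tokenize_rule(text)
  st <- new.env(parent = emptyenv())
  st$tokens <- toks
  st$pos <- 1L
  ast <- parse_or(st)
  if (st$pos <= nrow(st$tokens)) {
    tk <- st$tokens[st$pos, ]
    abort(sprintf("unexpected '%s' at position %d", tk$text, tk$at))
  }
  structure(ast, class = "rule_formula")
}

tokenize_rule <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_./-]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) abort("empty formula")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  pieces <- substring(text, starts, starts + lens - 1)
  # anything outside tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (j in seq_along(starts)) {
    covered[starts[j]:(starts[j] + lens[j] - 1)] <- TRUE
  }
  chars <- strsplit(text, "")[[1]]
  stray <- which(!covered & !grepl("\\s", chars))
  if (length(stray) > 0) {
    abort(sprintf("unexpected character '%s' at position %d",
                  chars[stray[1]], stray[1]))
  }
  type <- ifelse(pieces == "(", "lparen",
          ifelse(pieces == ")", "rparen",
          ifelse(toupper(pieces) == "AND", "and",
          ifelse(toupper(pieces) == "OR", "or", "id"))))
  tibble(text = pieces, type = type, at = starts)
}

peek <- function(st) {
  if (st$pos > nrow(st$tokens)) NULL else st$tokens[st$pos, ]
}

parse_or <- function(st) {
  args <- list(parse_and(st))
  repeat {
    tk <- peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    args <- c(args, list(parse_and(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

parse_and <- function(st) {
  args <- list(parse_atom(st))
  repeat {
    tk <- peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    args <- c(args, list(parse_atom(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

parse_atom <- function(st) {
  tk <- peek(st)
  if (is.null(tk)) {
    abort("dangling operator at end of formula")
  }
  if (tk$type == "lparen") {
    st$pos <- st$pos + 1L
    inner <- parse_or(st)
    tk2 <- peek(st)
    if (is.null(tk2) || tk2$type != "rparen") {
      abort(sprintf("unbalanced parenthesis opened at position %d", tk$at))
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "id") {
    st$pos <- st$pos + 1L
    return(list(op = "id", id = tk$text))
  }
  abort(sprintf("unexpected '%s' at position %d", tk$text, tk$at))
}

#' @export
print.rule_formula <- function(x, ...) {
  cat("<rule_formula>", deparse_rule(x), "\n")
  invisible(x)
}

#' Render a rule formula back to text
#' @param formula A `rule_formula` or AST node.
#' @return A single string.
#' @export
deparse_rule <- function(formula) {
  node <- formula
  if (node$op == "id") return(node$id)
  sep <- if (node$op == "and") " AND " else " OR "
  parts <- map_chr(node$args, function(a) {
    s <- deparse_rule(a)
    if (a$op == "or" && node$op == "and") paste0("(", s, ")") else s
  })
  paste(parts, collapse = sep)
}

#' Leaf identifiers of a rule formula
#' @inheritParams deparse_rule
#' @return Character vector of the distinct profile identifiers.
#' @export
rule_leaves <- function(formula) {
  node <- formula
  if (node$op == "id") return(node$id)
  unique(unlist(map(node$args, rule_leaves)))
}

#' Evaluate a rule formula against a set of present profiles
#'
#' @param formula A `rule_formula` from [parse_rule()].
#' @param present Character vector of profile identifiers present.
#' @return Logical scalar.
#' @export
eval_rule <- function(formula, present) {
  node <- formula
  if (node$op == "id") return(node$id %in% present)
  vals <- map_lgl(node$args, eval_rule, present = present)
  if (node$op == "and") all(vals) else any(vals)
}

#' Read a function-definition table
#'
#' Reads a TSV with columns `function_name`, `cycle` (one of carbon,
#' nitrogen, sulfur, other) and `formula`, parsing each formula.  With
#' no argument, loads the packaged default definition set covering the
#' classic biogeochemical marker functions (methanogenesis via *mcrA*,
#' Wood-Ljungdahl acetogenesis via *acsB* and *fthfs*, dissimilatory
#' sulfate reduction via *dsrA*/*dsrB*, ...).  The packaged formulas are
#' editable data, not code.
#'
#' @param path TSV path; default the packaged rule set.
#' @return A tibble `function_name`, `cycle`, `formula` (text), `ast`
#'   (list of `rule_formula`).
#' @export
read_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rules",
                                "metabolic_functions.tsv",
                                package = "taxcycle", mustWork = TRUE)
  tb <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (!all(c("function_name", "cycle", "formula") %in% names(tb))) {
    abort("rule file must have columns function_name, cycle, formula")
  }
  dup <- tb$function_name[duplicated(tb$function_name)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate function name in rule file: %s", dup[1]))
  }
  bad_cycle <- setdiff(unique(tb$cycle),
                       c("carbon", "nitrogen", "sulfur", "other"))
  if (length(bad_cycle) > 0) {
    abort(sprintf("unknown cycle: %s", bad_cycle[1]))
  }
  tb$ast <- map(tb$formula, parse_rule)
  as_tibble(tb)
}

#' Call metabolic functions from per-taxon profile-presence sets
#'
#' Evaluates every function formula against every taxon's set of
#' detected marker profiles.  Formula identifiers that appear in no
#' profile collection (when `known_profiles` is given) trigger one
#' warning each and evaluate to absent.
#'
#' @param presence_sets Named list: taxon/observation id -> character
#'   vector of present profile identifiers (may be empty).
#' @param rules Rule tibble from [read_rules()].
#' @param known_profiles Optional character vector of all profile names
#'   in the HMM collection, used to warn about unmatched identifiers.
#' @return A wide tibble: column `taxon`, then one logical column per
#'   function, rows in `presence_sets` order.
#' @export
call_functions <- function(presence_sets, rules, known_profiles = NULL) {
  if (is.null(names(presence_sets)) && length(presence_sets) > 0) {
    abort("presence_sets must be a named list")
  }
  if (!is.null(known_profiles)) {
    used <- unique(unlist(map(rules$ast, rule_leaves)))
    unknown <- setdiff(used, known_profiles)
    walk(unknown, function(id) {
      warn(sprintf(
        "formula identifier '%s' matches no profile in the collection; treated as absent",
        id))
    })
    # an identifier with no profile backing can never be present
    presence_sets <- map(presence_sets, intersect, known_profiles)
  }
  cols <- map(seq_len(nrow(rules)), function(j) {
    map_lgl(presence_sets, eval_rule, formula = rules$ast[[j]])
  })
  out <- tibble(taxon = names(presence_sets) %||% character(0))
  for (j in seq_len(nrow(rules))) {
    out[[rules$function_name[j]]] <- unname(cols[[j]])
  }
  out
}

#' Write a function-presence matrix to TSV (0/1 cells)
#'
#' @param presence Wide presence tibble from [call_functions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_presence <- function(presence, path) {
  num <- presence
  for (j in setdiff(names(num), "taxon")) {
    num[[j]] <- as.integer(num[[j]])
  }
  write_tsv_file(num, path)
}
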