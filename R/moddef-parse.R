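# -- KO / module identifier helpers -------------------------------------------

#' Normalize and validate KEGG Ortholog identifiers
#'
#' KO accessions have the form `K` followed by five digits (e.g. `K00001`).
#' Input is upper-cased and deduplicated; anything that does not match the
#' pattern is an error.
#'
#' @param x Character vector of KO accessions.
#' @return Character vector of unique, normalized KO accessions.
#' @export
ko_id <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad <- x[!grepl("^K[0-9]{5}$", x)]
  if (length(bad) > 0L) {
    stop("invalid KO accession(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unique(x)
}

module_id_check <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (length(x) != 1L || !grepl("^M[0-9]{5}$", x)) {
    stop("invalid module id: ", paste(x, collapse = ", "),
         " (expected 'M' followed by 5 digits)", call. = FALSE)
  }
  x
}

# -- step constructors --------------------------------------------------------

step_atom <- function(ko) list(type = "atom", ko = ko)
step_gap <- function() list(type = "gap")
step_module <- function(module_id) list(type = "module", module_id = module_id)
step_complex <- function(ko, essential) {
  list(type = "complex",
       components = data.frame(ko = ko, essential = essential,
                               stringsAsFactors = FALSE))
}
step_alts <- function(branches) list(type = "alts", branches = branches)

is_atomic_step <- function(step) step$type %in% c("atom", "complex", "gap")

# -- tokenizer ----------------------------------------------------------------

# Token stream over a definition string. Recognized tokens: KO ids, module
# ids, the "--" gap marker, parentheses, comma, plus, minus, and runs of
# spaces. Any uncovered character is an unknown-token error with its position.
moddef_tokenize <- function(text) {
  pattern <- "K[0-9]{5}|M[0-9]{5}|--|\\(|\\)|,|\\+|-| +"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L) {
    stop("definition parse error: unknown token at position 1 in '",
         text, "'", call. = FALSE)
  }
  # every character must belong to some token
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) {
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  }
  if (!all(covered)) {
    pos <- which(!covered)[1]
    stop("definition parse error: unknown token at position ", pos,
         " ('", substr(text, pos, pos), "')", call. = FALSE)
  }
  values <- substring(text, starts, starts + lens - 1L)
  types <- character(length(values))
  types[grepl("^K[0-9]{5}$", values)] <- "KO"
  types[grepl("^M[0-9]{5}$", values)] <- "MID"
  types[values == "--"] <- "GAP"
  types[values == "("] <- "LPAREN"
  types[values == ")"] <- "RPAREN"
  types[values == ","] <- "COMMA"
  types[values == "+"] <- "PLUS"
  types[values == "-"] <- "MINUS"
  types[grepl("^ +$", values)] <- "SPACE"
  data.frame(type = types, value = values, pos = starts,
             stringsAsFactors = FALSE)
}

# -- recursive-descent parser -------------------------------------------------

# Grammar (loosest to tightest binding):
#   seq  := alt (SPACE alt)*          sequential steps
#   alt  := term (COMMA term)*        alternatives
#   term := unit ((PLUS|MINUS) unit)* enzyme complex
#   unit := KO | MID | "--" | "(" seq ")"
# A parenthesized group with no commas is spliced into the enclosing
# sequence; comma branches keep their own step sequences.

parser_state <- function(tokens, text) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env$text <- text
  env
}

pk_peek <- function(st) {
  if (st$i > nrow(st$tokens)) NULL else st$tokens[st$i, ]
}

pk_next <- function(st) {
  tok <- pk_peek(st)
  st$i <- st$i + 1L
  tok
}

pk_error <- function(st, msg, pos = NULL) {
  if (is.null(pos)) {
    tok <- pk_peek(st)
    pos <- if (is.null(tok)) nchar(st$text) + 1L else tok$pos
  }
  stop("definition parse error at position ", pos, ": ", msg,
       " in '", st$text, "'", call. = FALSE)
}

p_seq <- function(st, inside_parens = FALSE) {
  steps <- list()
  repeat {
    tok <- pk_peek(st)
    if (!is.null(tok) && tok$type == "SPACE") {
      pk_next(st)
      next
    }
    if (is.null(tok) || tok$type == "RPAREN") break
    steps <- c(steps, p_alt(st))
    tok <- pk_peek(st)
    if (is.null(tok) || tok$type %in% c("SPACE", "RPAREN")) next
    pk_error(st, paste0("unexpected '", tok$value, "'"))
  }
  steps
}

p_alt <- function(st) {
  branches <- list(p_term(st))
  repeat {
    tok <- pk_peek(st)
    if (is.null(tok) || tok$type != "COMMA") break
    pk_next(st)
    branches <- c(branches, list(p_term(st)))
  }
  if (length(branches) == 1L) return(branches[[1]])
  if (any(vapply(branches, length, integer(1)) == 0L)) {
    pk_error(st, "empty alternative branch")
  }
  list(step_alts(branches))
}

p_term <- function(st) {
  first <- p_unit(st)
  tok <- pk_peek(st)
  if (is.null(tok) || !tok$type %in% c("PLUS", "MINUS")) return(first)
  if (length(first) != 1L || first[[1]]$type != "atom") {
    pk_error(st, "complex components must be plain KO identifiers")
  }
  kos <- first[[1]]$ko
  essential <- TRUE
  while (!is.null(tok <- pk_peek(st)) && tok$type %in% c("PLUS", "MINUS")) {
    op <- pk_next(st)
    comp <- p_unit(st)
    if (length(comp) != 1L || comp[[1]]$type != "atom") {
      pk_error(st, "complex components must be plain KO identifiers")
    }
    kos <- c(kos, comp[[1]]$ko)
    essential <- c(essential, op$type == "PLUS")
  }
  list(step_complex(kos, essential))
}

p_unit <- function(st) {
  tok <- pk_next(st)
  if (is.null(tok)) pk_error(st, "unexpected end of definition")
  switch(tok$type,
    KO = list(step_atom(tok$value)),
    MID = list(step_module(tok$value)),
    GAP = list(step_gap()),
    LPAREN = {
      open_pos <- tok$pos
      steps <- p_seq(st, inside_parens = TRUE)
      closing <- pk_next(st)
      if (is.null(closing) || closing$type != "RPAREN") {
        pk_error(st, "unbalanced parentheses", pos = open_pos)
      }
      if (length(steps) == 0L) pk_error(st, "empty parentheses", pos = open_pos)
      steps
    },
    RPAREN = pk_error(st, "unbalanced parentheses", pos = tok$pos),
    pk_error(st, paste0("unexpected '", tok$value, "'"), pos = tok$pos)
  )
}

#' Parse a KEGG-style module definition string
#'
#' Definitions follow the KEGG flat-file DEFINITION convention: spaces
#' separate sequential steps, commas separate alternatives, `+` joins
#' essential components of an enzyme complex, `-` marks a non-essential
#' component, `--` is a reaction step with no known KO, parentheses group,
#' and `M#####` tokens reference other modules.
#'
#' @param module_id Module accession (`M` + 5 digits).
#' @param text The definition string.
#' @param registry Optional named list of previously parsed
#'   [module_definition] objects used to resolve nested module references at
#'   evaluation time. Not required for parsing.
#' @return A `module_definition` object: a list with `module_id`, `steps`
#'   (the parsed step sequence) and `raw_text`.
#' @examples
#' parse_definition("M00001", "(K00001,K00002) K00003")
#' @export
parse_definition <- function(module_id, text, registry = NULL) {
  module_id <- module_id_check(module_id)
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      nchar(trimws(text)) == 0L) {
    stop("definition text must be a non-empty string", call. = FALSE)
  }
  text <- toupper(trimws(text))
  st <- parser_state(moddef_tokenize(text), text)
  steps <- p_seq(st)
  leftover <- pk_peek(st)
  if (!is.null(leftover)) {
    pk_error(st, "unbalanced parentheses", pos = leftover$pos)
  }
  if (length(steps) == 0L) {
    stop("definition for ", module_id, " has no steps", call. = FALSE)
  }
  structure(list(module_id = module_id, steps = steps, raw_text = text),
            class = "module_definition")
}

# -- rendering ----------------------------------------------------------------

render_step <- function(step) {
  switch(step$type,
    atom = step$ko,
    gap = "--",
    module = step$module_id,
    complex = {
      comp <- step$components
      ops <- ifelse(comp$essential[-1], "+", "-")
      paste0(comp$ko[1], paste0(ops, comp$ko[-1], collapse = ""))
    },
    alts = {
      branch_txt <- vapply(step$branches, function(branch) {
        if (length(branch) == 1L) render_step(branch[[1]])
        else paste0("(", render_steps(branch), ")")
      }, character(1))
      paste0("(", paste(branch_txt, collapse = ","), ")")
    },
    stop("unknown step type: ", step$type, call. = FALSE)
  )
}

render_steps <- function(steps) {
  paste(vapply(steps, render_step, character(1)), collapse = " ")
}

#' Render a parsed module definition back to its normalized string form
#'
#' Re-parsing the rendered string yields a structurally identical
#' definition (parse/render idempotence); redundant grouping parentheses
#' present in the original input are not reproduced.
#'
#' @param defn A [module_definition].
#' @return A single definition string.
#' @export
render_definition <- function(defn) {
  stopifnot(inherits(defn, "module_definition"))
  render_steps(defn$steps)
}

#' @export
print.module_definition <- function(x, ...) {
  cat("<module_definition> ", x$module_id, "\n  ", render_definition(x),
      "\n", sep = "")
  invisible(x)
}
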