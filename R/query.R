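# ---------------------------------------------------------------------------
# Filter expression language.
#
# Grammar (EBNF):
#   expr       = or_expr ;
#   or_expr    = and_expr { "or" and_expr } ;
#   and_expr   = not_expr { "and" not_expr } ;
#   not_expr   = "not" not_expr | primary ;
#   primary    = "(" expr ")" | comparison ;
#   comparison = IDENT OP literal ;
#   OP         = "==" | "!=" | "<" | "<=" | ">" | ">=" ;
#   literal    = NUMBER | STRING ;  (STRING single- or double-quoted)
#
# Precedence: not > and > or; parentheses override. Keywords are
# case-insensitive; attribute names case-sensitive. Ordering operators
# (<, <=, >, >=) require a numeric literal -- enforced at parse time.
# ---------------------------------------------------------------------------

ORDERING_OPS <- c("<", "<=", ">", ">=")
ALL_OPS <- c("==", "!=", ORDERING_OPS)

stop_filter <- function(type, msg, pos = NULL) {
  if (!is.null(pos)) msg <- sprintf("%s (at character %d)", msg, pos)
  stop(structure(
    class = c(paste0("filter_", type), "filter_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

tokenize_filter <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    c1 <- chars[i]
    if (grepl("^\\s$", c1)) { i <- i + 1L; next }
    two <- if (i < n) paste0(c1, chars[i + 1L]) else ""
    if (two %in% c("==", "!=", "<=", ">=")) {
      push("op", two, i); i <- i + 2L; next
    }
    if (c1 %in% c("<", ">")) { push("op", c1, i); i <- i + 1L; next }
    if (c1 == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (c1 == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (c1 %in% c("'", "\"")) {
      j <- i + 1L
      buf <- character(0)
      while (j <= n && chars[j] != c1) {
        buf <- c(buf, chars[j]); j <- j + 1L
      }
      if (j > n) stop_filter("syntax_error", "unterminated string literal", i)
      push("string", paste(buf, collapse = ""), i)
      i <- j + 1L; next
    }
    if (grepl("^[0-9]$", c1) ||
        (c1 == "-" && i < n && grepl("^[0-9.]$", chars[i + 1L]))) {
      j <- i
      if (chars[j] == "-") j <- j + 1L
      while (j <= n && grepl("^[0-9.eE+-]$", chars[j])) {
        # stop a trailing +/- unless it follows an exponent marker
        if (chars[j] %in% c("+", "-") &&
            !(j > i && chars[j - 1L] %in% c("e", "E"))) break
        j <- j + 1L
      }
      lit <- paste(chars[i:(j - 1L)], collapse = "")
      num <- suppressWarnings(as.numeric(lit))
      if (is.na(num)) stop_filter("syntax_error",
                                  sprintf("malformed number '%s'", lit), i)
      push("number", num, i)
      i <- j; next
    }
    if (grepl("^[A-Za-z_]$", c1)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_.]$", chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      lw <- tolower(word)
      if (lw %in% c("and", "or", "not")) push(lw, lw, i)
      else push("ident", word, i)
      i <- j; next
    }
    stop_filter("syntax_error", sprintf("unexpected character '%s'", c1), i)
  }
  push("eof", "", n + 1L)
  toks
}

#' Parse a Boolean attribute filter
#'
#' Parses expressions such as `"snp_distance <= 10"` or
#' `"region == 'Tierralta' and not probability < 0.5"` into an expression
#' tree. Comparisons take the form *attribute operator literal* with
#' operators `==`, `!=`, `<`, `<=`, `>`, `>=`; string literals are quoted
#' (single or double), numbers are not. `not` binds tighter than `and`,
#' which binds tighter than `or`; parentheses override. The keywords are
#' case-insensitive, attribute names case-sensitive.
#'
#' @param text expression string.
#' @return a `filter_expression` tree.
#' @section Errors: syntax errors carry the character position; applying an
#'   ordering operator to a quoted string literal is a type error caught at
#'   parse time.
#' @examples
#' parse_filter("snp_distance <= 10")
#' parse_filter("a == 'x' and (b > 2 or not c == 'y')")
#' @export
parse_filter <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_filter(text)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() {
    t <- toks[[pos]]
    pos <<- pos + 1L
    t
  }
  expect <- function(type, what) {
    t <- peek()
    if (t$type != type) {
      stop_filter("syntax_error",
                  sprintf("expected %s but found '%s'", what,
                          if (t$type == "eof") "end of input" else t$value),
                  t$pos)
    }
    advance()
  }
  parse_or <- function() {
    lhs <- parse_and()
    while (peek()$type == "or") {
      advance()
      lhs <- list(type = "or", lhs = lhs, rhs = parse_and())
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_not()
    while (peek()$type == "and") {
      advance()
      lhs <- list(type = "and", lhs = lhs, rhs = parse_not())
    }
    lhs
  }
  parse_not <- function() {
    if (peek()$type == "not") {
      advance()
      return(list(type = "not", x = parse_not()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (t$type == "lparen") {
      advance()
      inner <- parse_or()
      expect("rparen", "')'")
      return(inner)
    }
    ident <- expect("ident", "an attribute name")
    op_tok <- peek()
    if (op_tok$type != "op") {
      stop_filter("syntax_error",
                  sprintf("expected a comparison operator after '%s'",
                          ident$value), op_tok$pos)
    }
    advance()
    lit <- peek()
    if (!lit$type %in% c("number", "string")) {
      stop_filter("syntax_error",
                  "expected a number or quoted string literal", lit$pos)
    }
    advance()
    if (op_tok$value %in% ORDERING_OPS && lit$type == "string") {
      stop_filter("type_error",
                  sprintf("ordering operator '%s' requires a numeric literal",
                          op_tok$value), lit$pos)
    }
    list(type = "cmp", attribute = ident$value, op = op_tok$value,
         value = lit$value)
  }
  expr <- parse_or()
  t <- peek()
  if (t$type != "eof") {
    stop_filter("syntax_error",
                sprintf("unexpected '%s' after complete expression", t$value),
                t$pos)
  }
  structure(expr, class = c("filter_expression", class(expr)))
}

as_filter <- function(expr) {
  if (inherits(expr, "filter_expression")) return(expr)
  if (is.character(expr) && length(expr) == 1L) return(parse_filter(expr))
  stop_filter("type_error",
              "expected a filter_expression or an expression string")
}

#' Evaluate a filter against an attribute map
#'
#' Evaluation is total: every attribute map yields `TRUE` or `FALSE`. By
#' default a comparison on an attribute the map does not carry evaluates
#' `FALSE` (so partially annotated nodes are simply not matched); in strict
#' mode it is an error naming the attribute. Equality compares after kind
#' unification: integers and floats are compared numerically, a string never
#' equals a number, string comparison is case-sensitive exact matching.
#' Ordering comparisons on a string-valued attribute are `FALSE`.
#'
#' @param expr a `filter_expression` from [parse_filter()], or an
#'   expression string.
#' @param attributes named list of attribute values.
#' @param strict error on missing attributes instead of returning `FALSE`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' evaluate_filter("d <= 10", list(d = 7))
#' evaluate_filter("region == 'Tierralta'", list(region = "Tierralta"))
#' @export
evaluate_filter <- function(expr, attributes, strict = FALSE) {
  expr <- as_filter(expr)
  eval_node <- function(e) {
    switch(e$type,
      "or"  = eval_node(e$lhs) || eval_node(e$rhs),
      "and" = eval_node(e$lhs) && eval_node(e$rhs),
      "not" = !eval_node(e$x),
      "cmp" = eval_cmp(e),
      stop_filter("type_error", sprintf("malformed node type '%s'", e$type)))
  }
  eval_cmp <- function(e) {
    if (!e$attribute %in% names(attributes)) {
      if (strict) {
        stop_filter("missing_attribute_error",
                    sprintf("attribute '%s' is not present", e$attribute))
      }
      return(FALSE)
    }
    val <- attributes[[e$attribute]]
    lit <- e$value
    if (e$op %in% c("==", "!=")) {
      eq <- if (is.character(val) != is.character(lit)) FALSE
            else if (is.character(val)) identical(val, lit)
            else as.numeric(val) == as.numeric(lit)
      return(if (e$op == "==") eq else !eq)
    }
    if (is.character(val)) return(FALSE)  # ordering undefined on strings
    switch(e$op,
      "<"  = as.numeric(val) <  as.numeric(lit),
      "<=" = as.numeric(val) <= as.numeric(lit),
      ">"  = as.numeric(val) >  as.numeric(lit),
      ">=" = as.numeric(val) >= as.numeric(lit))
  }
  isTRUE(eval_node(unclass(expr)))
}

#' Render a filter expression back to its canonical string
#'
#' The canonical form is fully parenthesised except at the top level, so
#' `parse_filter(format(e))` is structurally identical to `e`.
#'
#' @param x a `filter_expression`.
#' @param ... unused.
#' @return a single string.
#' @export
format.filter_expression <- function(x, ...) {
  # compound children are always parenthesised so associativity and
  # precedence survive re-parsing exactly
  child <- function(e) {
    if (e$type == "cmp") render(e) else paste0("(", render(e), ")")
  }
  render <- function(e) {
    switch(e$type,
      "cmp" = paste(e$attribute, e$op,
                    if (is.character(e$value))
                      paste0("'", e$value, "'")
                    else json_value(as.numeric(e$value))),
      "not" = paste0("not ", child(e$x)),
      "and" = paste(child(e$lhs), "and", child(e$rhs)),
      "or"  = paste(child(e$lhs), "or", child(e$rhs)))
  }
  render(unclass(x))
}

#' @export
print.filter_expression <- function(x, ...) {
  cat("<filter> ", format(x), "\n", sep = "")
  invisible(x)
}
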