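#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Rule grammar
#
#   var <name>:<arity> [input]
#   rule <bit> = <expr>
#
# where <bit> is <name> for a two-level variable or <name>_low / <name>_high
# for a three-level one, and <expr> is built from literals, `not`, `and`,
# `or`, parentheses, the constants 0/1 and level comparisons `<name> >= k`,
# `<name> == k`.  Comments start with `#`.  Precedence: or < and < not.
# ---------------------------------------------------------------------------

cs_tokenize <- function(line) {
  pat <- "([A-Za-z_][A-Za-z0-9_]*|>=|==|\\(|\\)|[0-9]+)"
  rest <- line
  toks <- character(0)
  while (nzchar(trimws(rest))) {
    rest <- sub("^\\s+", "", rest)
    if (!nzchar(rest)) break
    m <- regmatches(rest, regexpr(paste0("^", pat), rest))
    if (length(m) == 0 || !nzchar(m)) {
      stop(sprintf("unexpected character near '%s'", substr(rest, 1, 10)),
           call. = FALSE)
    }
    toks <- c(toks, m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  toks
}

# Recursive-descent parser producing an R language object with explicit
# structure, so `not` / `and` / `or` get the grammar's precedence rather
# than R's (`!x == k` would otherwise bind the wrong way).
cs_parse_expr <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  expect <- function(what) {
    t <- advance()
    if (is.na(t) || t != what) {
      stop(sprintf("expected '%s' but found '%s'", what,
                   if (is.na(t)) "end of expression" else t), call. = FALSE)
    }
    t
  }
  is_name <- function(t) !is.na(t) && grepl("^[A-Za-z_][A-Za-z0-9_]*$", t) &&
    !(t %in% c("not", "and", "or"))

  parse_or <- function() {
    lhs <- parse_and()
    while (identical(peek(), "or")) {
      advance()
      lhs <- call("|", lhs, parse_and())
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_not()
    while (identical(peek(), "and")) {
      advance()
      lhs <- call("&", lhs, parse_not())
    }
    lhs
  }
  parse_not <- function() {
    if (identical(peek(), "not")) {
      advance()
      return(call("!", parse_not()))
    }
    parse_atom()
  }
  parse_atom <- function() {
    t <- advance()
    if (is.na(t)) stop("unexpected end of expression", call. = FALSE)
    if (t == "(") {
      e <- parse_or()
      expect(")")
      return(e)
    }
    if (grepl("^[0-9]+$", t)) {
      v <- as.integer(t)
      if (!v %in% c(0L, 1L)) {
        stop(sprintf("numeric constant must be 0 or 1, found %s", t),
             call. = FALSE)
      }
      return(v)
    }
    if (!is_name(t)) stop(sprintf("unexpected token '%s'", t), call. = FALSE)
    nxt <- peek()
    if (!is.na(nxt) && nxt %in% c(">=", "==")) {
      op <- advance()
      k <- advance()
      if (is.na(k) || !grepl("^[0-9]+$", k)) {
        stop(sprintf("comparison '%s %s' needs an integer level", t, op),
             call. = FALSE)
      }
      return(call(op, as.name(t), as.integer(k)))
    }
    as.name(t)
  }

  out <- parse_or()
  if (!is.na(peek())) {
    stop(sprintf("trailing tokens starting at '%s'", peek()), call. = FALSE)
  }
  out
}

cs_bits_of <- function(name, arity) {
  if (arity == 2L) name else paste0(name, c("_low", "_high"))
}

# Symbols an expression may legally reference, given the variable table:
# bare bit names, plus variable names inside comparisons (any arity).
cs_validate_expr <- function(expr, vars, where) {
  bit_names <- unlist(mapply(cs_bits_of, vars$name, vars$arity,
                             SIMPLIFY = FALSE), use.names = FALSE)
  walk <- function(e, in_cmp = FALSE) {
    if (is.name(e)) {
      nm <- as.character(e)
      if (in_cmp) {
        if (!nm %in% vars$name) {
          stop(sprintf("%s: comparison references undeclared variable '%s'",
                       where, nm), call. = FALSE)
        }
      } else if (!nm %in% bit_names) {
        if (nm %in% vars$name) {
          stop(sprintf(
            "%s: three-level variable '%s' may only appear in a comparison",
            where, nm), call. = FALSE)
        }
        stop(sprintf("%s: undeclared variable '%s'", where, nm),
             call. = FALSE)
      }
      return(invisible(NULL))
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op %in% c(">=", "==")) {
        walk(e[[2]], in_cmp = TRUE)
        nm <- as.character(e[[2]])
        k <- e[[3]]
        ar <- vars$arity[match(nm, vars$name)]
        if (k < 0L || k > ar - 1L) {
          stop(sprintf("%s: level %d out of range for '%s' (arity %d)",
                       where, k, nm, ar), call. = FALSE)
        }
        return(invisible(NULL))
      }
      for (i in seq_along(e)[-1]) walk(e[[i]])
    }
    invisible(NULL)
  }
  walk(expr)
  invisible(NULL)
}

# Variable names referenced by a rule (regulators), for dependency checks.
cs_expr_vars <- function(expr, vars) {
  found <- character(0)
  walk <- function(e) {
    if (is.name(e)) {
      nm <- as.character(e)
      base <- sub("_(low|high)$", "", nm)
      found <<- c(found, if (base %in% vars$name) base else nm)
    } else if (is.call(e)) {
      for (i in seq_along(e)[-1]) walk(e[[i]])
    }
  }
  walk(expr)
  unique(found)
}

#' Parse a logical-model definition
#'
#' Reads the textual rule grammar (`var` declarations followed by `rule`
#' assignments, one per line) into a validated logical model.  Two-level
#' variables carry a single update rule; three-level variables are split into
#' `<name>_low` / `<name>_high` bits, each with its own rule, and their level
#' is the sum of the two bits.  Input variables (declared with the `input`
#' flag) have no rules: their level is fixed by the initial state or clamped
#' during simulation.
#'
#' @param text Model definition: a single string or character vector of lines.
#' @return An object of class `cs_model` with elements `vars` (data frame of
#'   name/arity/role), `rules` (named list of parsed expressions, one per
#'   non-input bit) and `rule_text` (the right-hand sides as written).
#' @examples
#' m <- parse_model(c("var A:2", "rule A = A"))
#' m$vars
#' @export
parse_model <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines_clean <- sub("#.*$", "", lines)

  vars <- data.frame(name = character(0), arity = integer(0),
                     role = character(0), stringsAsFactors = FALSE)
  rules <- list()
  rule_text <- character(0)

  for (i in seq_along(lines_clean)) {
    ln <- trimws(lines_clean[[i]])
    if (!nzchar(ln)) next
    err <- function(msg) stop(sprintf("line %d: %s", i, msg), call. = FALSE)

    if (grepl("^var\\b", ln)) {
      m <- regmatches(ln, regexec(
        "^var\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*([23])(\\s+input)?\\s*$",
        ln))[[1]]
      if (length(m) == 0) err("malformed variable declaration (need 'var name:2|3 [input]')")
      nm <- m[[2]]
      if (nm %in% vars$name) err(sprintf("duplicate variable '%s'", nm))
      vars <- rbind(vars, data.frame(
        name = nm, arity = as.integer(m[[3]]),
        role = if (nzchar(m[[4]])) "input" else "internal",
        stringsAsFactors = FALSE))
    } else if (grepl("^rule\\b", ln)) {
      m <- regmatches(ln, regexec(
        "^rule\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) == 0) err("malformed rule (need 'rule bit = expr')")
      bit <- m[[2]]
      rhs <- m[[3]]
      base <- sub("_(low|high)$", "", bit)
      row <- match(base, vars$name)
      if (is.na(row)) {
        row <- match(bit, vars$name)
        base <- bit
      }
      if (is.na(row)) err(sprintf("rule for undeclared variable '%s'", bit))
      if (vars$role[row] == "input") {
        err(sprintf("rule assigned to input variable '%s'", base))
      }
      legal_bits <- cs_bits_of(vars$name[row], vars$arity[row])
      if (!bit %in% legal_bits) {
        err(sprintf("'%s' is not a bit of variable '%s' (expected %s)",
                    bit, base, paste(legal_bits, collapse = "/")))
      }
      if (bit %in% names(rules)) err(sprintf("duplicate rule for '%s'", bit))
      expr <- tryCatch(cs_parse_expr(cs_tokenize(rhs)),
                       error = function(e) err(conditionMessage(e)))
      rules[[bit]] <- expr
      rule_text[[bit]] <- trimws(rhs)
    } else {
      err(sprintf("unrecognized directive '%s'", strsplit(ln, "\\s+")[[1]][1]))
    }
  }

  if (nrow(vars) == 0) stop("model declares no variables", call. = FALSE)
  for (bit in names(rules)) {
    cs_validate_expr(rules[[bit]], vars, sprintf("rule for '%s'", bit))
  }
  internal <- vars$name[vars$role == "internal"]
  need <- unlist(mapply(cs_bits_of, internal,
                        vars$arity[vars$role == "internal"],
                        SIMPLIFY = FALSE), use.names = FALSE)
  missing <- setdiff(need, names(rules))
  if (length(missing) > 0) {
    stop(sprintf("missing rule(s) for bit(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  structure(list(vars = vars, rules = rules[need], rule_text = rule_text[need]),
            class = "cs_model")
}

#' Serialize a logical model back to its text form
#'
#' @param model A `cs_model`.
#' @param path Optional file path; when `NULL` the text is returned invisibly.
#' @return Character vector of lines (invisibly when written to `path`).
#' @export
write_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "cs_model"))
  v <- model$vars
  lines <- c(
    sprintf("var %s:%d%s", v$name, v$arity,
            ifelse(v$role == "input", " input", "")),
    sprintf("rule %s = %s", names(model$rule_text), unname(model$rule_text))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.cs_model <- function(x, ...) {
  cat(sprintf("Logical model: %d variables (%d input), %d rules\n",
              nrow(x$vars), sum(x$vars$role == "input"), length(x$rules)))
  cat(paste0("  ", write_model(x), collapse = "\n"), "\n")
  invisible(x)
}

cs_internal_vars <- function(model) {
  model$vars$name[model$vars$role == "internal"]
}

cs_input_vars <- function(model) {
  model$vars$name[model$vars$role == "input"]
}

cs_arity <- function(model, name) {
  model$vars$arity[match(name, model$vars$name)]
}
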