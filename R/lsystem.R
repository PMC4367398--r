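## Parametric L-system engine.
##
## The closed alphabet: organ symbols carry a single integer `age` parameter
## (the special state `r`, stored internally as Inf, marks a stable organ);
## control characters carry bookkeeping parameters and never render;
## operators steer the 3D turtle and are never rewritten.

LSYS_ORGANS <- c("L", "l", "F", "S", "G", "P", "H", "Y", "y", "h", "f")
LSYS_CONTROLS <- c("A", "B", "C", "D")
LSYS_OPS <- c("/", "&", "#", "+", "-", "[", "]")

lsys_token <- function(letter, params = numeric(0)) {
  list(letter = letter, params = as.numeric(params))
}

new_lstring <- function(tokens, choice = NULL, variety = NULL,
                        validate = TRUE) {
  s <- structure(tokens, class = "lstring", choice = choice,
                 variety = variety)
  if (validate) {
    d <- 0L
    for (tk in tokens) {
      if (tk$letter == "[") d <- d + 1L
      if (tk$letter == "]") d <- d - 1L
      if (d < 0L) stopf("tomstem_structure_error", "unbalanced ']'")
    }
    if (d != 0L) stopf("tomstem_structure_error",
                       "unbalanced brackets (depth %d at end)", d)
  }
  s
}

fmt_param <- function(p) {
  if (is.infinite(p)) "r"
  else if (p == round(p)) sprintf("%d", as.integer(p))
  else sprintf("%g", p)
}

#' Parse and format bracketed L-system strings
#'
#' The textual form is the standard bracketed notation, e.g.
#' `"F(0)[&B(2,0)]A(1,1)"` or `"[+L(3)][-L(0)]"`: single-letter symbols
#' with an optional comma-separated parameter list in parentheses, the
#' rotation operators `+ - & # /` (bare or with an angle parameter), and
#' `[`/`]` delimiting branching structures. The reserved parameter token
#' `r` denotes the stable age state.
#'
#' @param text character scalar in bracketed notation.
#' @param validate check bracket balance (disable for rule fragments).
#' @return `parse_lstring` returns an object of class `lstring`;
#'   `lstring_to_string` its textual form.
#' @export
parse_lstring <- function(text, validate = TRUE) {
  chars <- strsplit(gsub("−", "-", text), "")[[1]]
  chars <- chars[!chars %in% c(" ", "\t", "\n")]
  toks <- list(); i <- 1L
  known <- c(LSYS_ORGANS, LSYS_CONTROLS, LSYS_OPS)
  while (i <= length(chars)) {
    ch <- chars[i]
    if (!ch %in% known)
      stopf("tomstem_parse_error", "unknown symbol '%s' at position %d", ch, i)
    params <- numeric(0)
    if (i < length(chars) && chars[i + 1L] == "(") {
      j <- i + 2L; buf <- character(0); cur <- ""
      while (j <= length(chars) && chars[j] != ")") {
        if (chars[j] == ",") { buf <- c(buf, cur); cur <- "" }
        else cur <- paste0(cur, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stopf("tomstem_parse_error", "unclosed '('")
      buf <- c(buf, cur)
      params <- vapply(buf, function(b) {
        if (b == "r") return(Inf)
        v <- suppressWarnings(as.numeric(b))
        if (is.na(v)) stopf("tomstem_parse_error", "bad parameter '%s'", b)
        v
      }, 0, USE.NAMES = FALSE)
      i <- j
    }
    toks[[length(toks) + 1L]] <- lsys_token(ch, params)
    i <- i + 1L
  }
  new_lstring(toks, validate = validate)
}

#' @rdname parse_lstring
#' @param s an `lstring`.
#' @export
lstring_to_string <- function(s) {
  paste(vapply(s, function(tk) {
    if (length(tk$params) == 0) tk$letter
    else paste0(tk$letter, "(",
                paste(vapply(tk$params, fmt_param, ""), collapse = ","), ")")
  }, ""), collapse = "")
}

#' @export
print.lstring <- function(x, ...) {
  cat(lstring_to_string(x), "\n")
  invisible(x)
}

#' @export
format.lstring <- function(x, ...) lstring_to_string(x)

# --- choice strings --------------------------------------------------------

#' Choice string: the predefined lateral-branch sequence
#'
#' A tomato plant has a single main stem; every lateral branch is one of
#' five forms: (1) a short shoot that is itself a compound leaf, (2) a
#' full-fledged branch bearing leaves, (3) a branch bearing flowers and
#' fruit, (4) the terminal branch atop the main stem bearing leaves only,
#' (5) the terminal branch bearing flowers. The choice string lists the
#' branch forms bottom to top: the plant consumes one code per growth
#' stage, each new branch emerging higher than all previous ones. Terminal
#' forms (4/5) may appear once, only in last position.
#'
#' @param codes integer vector of branch-form codes.
#' @return Validated integer vector of class `choice_string`.
#' @export
choice_string <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) == 0)
    stopf("tomstem_invalid_choice", "choice string must be non-empty")
  if (any(!codes %in% 1:5))
    stopf("tomstem_invalid_choice", "branch codes must be in 1..5 (got %s)",
          paste(codes[!codes %in% 1:5], collapse = ","))
  terminal <- which(codes %in% 4:5)
  if (length(terminal) > 1 ||
      (length(terminal) == 1 && terminal != length(codes)))
    stopf("tomstem_invalid_choice",
          "terminal forms 4/5 may appear once, only in last position")
  structure(codes, class = "choice_string")
}

#' Draw a random choice string
#'
#' Samples the number of lateral branches and their forms (short shoots,
#' leafy branches and flower branches in roughly the proportions seen on
#' greenhouse plants), appending a terminal form. Deterministic under
#' `seed`.
#'
#' @param seed integer seed.
#' @param n_branches range (min, max) of non-terminal branches.
#' @return A [choice_string].
#' @export
random_choice <- function(seed, n_branches = c(5, 9)) {
  with_seed(seed, {
    n <- sample(n_branches[1]:n_branches[2], 1)
    body <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
    choice_string(c(body, sample(4:5, 1)))
  })
}

#' Build the axiom for a tomato plant
#'
#' The axiom is a very young plant: one main-stem internode and the
#' main-stem control character `A(i, j)` with the choice-string traversal
#' index `i = 0` and the cumulative growth counter `j = 0`. As the plant
#' grows, `A` consumes one choice code per stage, so the branches appear in
#' choice order from bottom to top.
#'
#' @param choice a [choice_string] (or plain code vector).
#' @param variety `"ordinary"` or `"cherry"`.
#' @return An `lstring` carrying the choice string and variety as
#'   attributes.
#' @export
make_axiom <- function(choice, variety = c("ordinary", "cherry")) {
  variety <- match.arg(variety)
  choice <- choice_string(choice)
  new_lstring(list(lsys_token("F", 0), lsys_token("A", c(0, 0))),
              choice = choice, variety = variety)
}

# --- productions -----------------------------------------------------------

#' Parse a production rule set
#'
#' One rule per line, `pred : cond -> succ`; lines starting with `#` are
#' comments (inline comments are not supported: `#` is the leaf-angle
#' operator). The
#' predecessor is a letter with formal parameter names; the condition is a
#' boolean expression over the formals (operators `&&`, `||`, `==`, `!=`,
#' comparisons), empty for "always"; the successor is a bracketed template
#' whose parameters are arithmetic expressions over the formals. Reserved
#' tokens: `r` (stable age state), `choice(k)` (k-th branch code of the
#' plant's choice string, NA out of range) and `nc` (choice length).
#' Successor fragments may be locally bracket-unbalanced (leaf bifurcation
#' closes and reopens the enclosing branch); balance is enforced on whole
#' strings only.
#'
#' A rule set must be deterministic: if two rules ever hold for the same
#' symbol instance, rewriting raises an ambiguity error.
#'
#' @param x path to a grammar file, or a character vector of rule lines.
#' @return A list of productions of class `lsys_rules`.
#' @export
parse_grammar <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- lapply(lines, parse_production)
  structure(rules, class = "lsys_rules")
}

parse_production <- function(line) {
  m <- regmatches(line, regexec("^\\s*([A-Za-z])\\(([^)]*)\\)\\s*:\\s*(.*?)\\s*->\\s*(.*)$", line))[[1]]
  if (length(m) != 5)
    stopf("tomstem_grammar_error", "cannot parse production: %s", line)
  letter <- m[2]
  formals <- trimws(strsplit(m[3], ",")[[1]])
  if (any(!grepl("^[A-Za-z][A-Za-z0-9_]*$", formals)))
    stopf("tomstem_grammar_error", "bad formal parameters in: %s", line)
  cond <- if (nzchar(m[4]) && m[4] != "*") {
    e <- tryCatch(str2lang(m[4]), error = function(err)
      stopf("tomstem_grammar_error", "bad condition '%s'", m[4]))
    bad <- setdiff(all.vars(e), c(formals, "r", "nc"))
    if (length(bad))
      stopf("tomstem_grammar_error", "condition uses unbound name(s): %s",
            paste(bad, collapse = ","))
    e
  } else NULL
  succ <- parse_succ_template(m[5], formals)
  list(letter = letter, formals = formals, cond = cond, succ = succ,
       text = line)
}

# successor template: like parse_lstring but parameters are expressions
parse_succ_template <- function(text, formals) {
  chars <- strsplit(gsub("−", "-", text), "")[[1]]
  chars <- chars[!chars %in% c(" ", "\t")]
  known <- c(LSYS_ORGANS, LSYS_CONTROLS, LSYS_OPS)
  toks <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (!ch %in% known)
      stopf("tomstem_grammar_error", "unknown symbol '%s' in successor", ch)
    exprs <- list()
    if (i < length(chars) && chars[i + 1L] == "(") {
      j <- i + 2L; depth <- 0L; buf <- character(0); cur <- ""
      while (j <= length(chars) && !(chars[j] == ")" && depth == 0L)) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        if (chars[j] == "," && depth == 0L) { buf <- c(buf, cur); cur <- "" }
        else cur <- paste0(cur, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stopf("tomstem_grammar_error", "unclosed '('")
      buf <- c(buf, cur)
      exprs <- lapply(buf, function(b) {
        e <- tryCatch(str2lang(b), error = function(err)
          stopf("tomstem_grammar_error", "bad parameter expression '%s'", b))
        bad <- setdiff(all.vars(e), c(formals, "r", "nc", "choice"))
        if (length(bad))
          stopf("tomstem_grammar_error", "parameter uses unbound name(s): %s",
                paste(bad, collapse = ","))
        e
      })
      i <- j
    }
    toks[[length(toks) + 1L]] <- list(letter = ch, exprs = exprs)
    i <- i + 1L
  }
  toks
}

#' Load the built-in grammar of a tomato variety
#'
#' Two rule sets ship with the package, one per variety. They differ in
#' where flowers grow: the cherry tomato bears leaves and flowers on the
#' same full-fledged branch, while the ordinary tomato keeps leaves and
#' flowers on separate branches. Both are plain-text files users can copy
#' and edit.
#'
#' @param variety `"ordinary"` or `"cherry"`.
#' @return An `lsys_rules` rule set.
#' @export
default_grammar <- function(variety = c("ordinary", "cherry")) {
  variety <- match.arg(variety)
  parse_grammar(system.file("extdata", "grammars",
                            paste0(variety, ".lsys"), package = "tomstem"))
}

#' Default maturity ages at which an organ's age freezes to `r`
#'
#' Once an organ's age reaches its maturity, its age parameter enters the
#' stable state `r` and its morphology stops changing -- except for side
#' leaves `L`, whose stable state triggers bifurcation into two leaves at
#' the next rewrite (compound-leaf development). Flower stalks and flowers
#' are driven entirely by explicit rules (stalk bears a flower, withered
#' flower is replaced by a fruit), so they carry no default maturity.
#'
#' @return Named numeric vector of maturity ages per organ letter.
#' @export
default_maturity <- function() {
  c(F = 5, S = 5, f = 5, h = 5, L = 4, l = 4, G = 6, Y = 3, y = 3,
    P = Inf, H = Inf)
}

#' Test whether a production holds for a symbol instance
#'
#' A production holds iff, simultaneously: (1) the actual symbol letter
#' equals the predecessor letter; (2) the actual parameter count equals the
#' formal parameter count; (3) the condition evaluates to true with the
#' actual parameters bound to the formals.
#'
#' @param prod one production from [parse_grammar].
#' @param sym a symbol instance (`list(letter, params)`).
#' @param env optional environment supplying `choice`/`nc`.
#' @return `TRUE` or `FALSE`.
#' @export
match_production <- function(prod, sym, env = NULL) {
  if (prod$letter != sym$letter) return(FALSE)
  if (length(prod$formals) != length(sym$params)) return(FALSE)
  if (is.null(prod$cond)) return(TRUE)
  e <- make_rule_env(env)
  for (k in seq_along(prod$formals))
    assign(prod$formals[k], sym$params[k], envir = e)
  isTRUE(tryCatch(eval(prod$cond, e), error = function(err) FALSE))
}

make_rule_env <- function(parent_env = NULL) {
  choice <- attr(parent_env, "choice") %||% integer(0)
  e <- new.env(parent = baseenv())
  assign("r", Inf, envir = e)
  assign("nc", length(choice), envir = e)
  assign("choice", local({
    ch <- as.integer(choice)
    function(k) if (k >= 1 && k <= length(ch)) ch[k] else NA_integer_
  }), envir = e)
  e
}

instantiate_succ <- function(succ, formals, params, env) {
  e <- make_rule_env(env)
  for (k in seq_along(formals)) assign(formals[k], params[k], envir = e)
  lapply(succ, function(tk) {
    vals <- vapply(tk$exprs, function(ex) as.numeric(eval(ex, e)), 0)
    lsys_token(tk$letter, vals)
  })
}

#' One parallel rewriting step
#'
#' Every symbol with a holding production is replaced by the instantiated
#' successor, all in parallel. Organ symbols (single age parameter) with no
#' holding production age in place: the age increases by 1 per stage until
#' the organ's maturity, then enters the stable state `r`. Operators,
#' brackets and parameterless symbols pass through unchanged. If two
#' productions hold for one symbol the grammar is ambiguous and rewriting
#' stops with an error.
#'
#' @param s an `lstring` (bracket-balanced; carries its choice string).
#' @param rules an `lsys_rules` set.
#' @param maturity named maturity ages, see [default_maturity].
#' @return The rewritten `lstring`.
#' @export
lsys_step <- function(s, rules, maturity = default_maturity()) {
  stopifnot(inherits(s, "lstring"))
  out <- list()
  for (tk in s) {
    if (tk$letter %in% LSYS_OPS) { out[[length(out) + 1L]] <- tk; next }
    hold <- Filter(function(p) match_production(p, tk, s), rules)
    if (length(hold) > 1)
      stopf("tomstem_ambiguous_grammar",
            "%d productions hold for %s(%s)", length(hold), tk$letter,
            paste(vapply(tk$params, fmt_param, ""), collapse = ","))
    if (length(hold) == 1) {
      rep_toks <- instantiate_succ(hold[[1]]$succ, hold[[1]]$formals,
                                   tk$params, s)
      out <- c(out, rep_toks)
    } else if (tk$letter %in% LSYS_ORGANS && length(tk$params) == 1 &&
               is.finite(tk$params[1])) {
      age <- tk$params[1] + 1
      m <- maturity[[tk$letter]] %||% Inf
      out[[length(out) + 1L]] <-
        lsys_token(tk$letter, if (age >= m) Inf else age)
    } else {
      out[[length(out) + 1L]] <- tk
    }
  }
  new_lstring(out, choice = attr(s, "choice"), variety = attr(s, "variety"))
}

#' Grow a plant for a number of stages
#'
#' Applies [lsys_step] repeatedly, returning the whole developmental
#' sequence (element 1 is the axiom itself). Rewriting is deterministic:
#' all stochasticity lives in the axiom draw ([random_choice]) and in the
#' geometric interpretation.
#'
#' @param axiom an `lstring` from [make_axiom].
#' @param n_stages number of rewriting steps (>= 0).
#' @param rules rule set; defaults to the axiom's variety grammar.
#' @param maturity see [default_maturity].
#' @return List of `n_stages + 1` lstrings.
#' @export
lsys_grow <- function(axiom, n_stages, rules = NULL,
                      maturity = default_maturity()) {
  stopifnot(n_stages >= 0)
  if (is.null(rules))
    rules <- default_grammar(attr(axiom, "variety") %||% "ordinary")
  out <- vector("list", n_stages + 1L)
  out[[1]] <- axiom
  s <- axiom
  for (k in seq_len(n_stages)) {
    s <- lsys_step(s, rules, maturity)
    out[[k + 1L]] <- s
  }
  out
}

#' Lateral-branch forms present in a string, bottom to top
#'
#' Scans the depth-0 bracketed groups along the main stem and classifies
#' each by its root symbol: short shoot (`S`/`C`) -> 1, leafy full-fledged
#' branch (`f`/`D`) -> 2, flower branch (`h`) -> 3, terminal leaves (`l`)
#' -> 4, terminal flowers (`P`) -> 5; pending branch controls `B(t, .)`
#' report their type parameter. The paired terminal groups atop the stem
#' collapse to a single trailing code.
#'
#' @param s an `lstring`.
#' @return Integer vector of branch codes in bottom-to-top order.
#' @export
branch_types <- function(s) {
  codes <- integer(0)
  depth <- 0L; root <- NA_character_; root_param <- NA_real_
  classify <- function(letter, param) {
    switch(letter,
           S = 1L, C = 1L, f = 2L, D = 2L, h = 3L, l = 4L, P = 5L, H = 5L,
           B = as.integer(param), NA_integer_)
  }
  for (tk in s) {
    if (tk$letter == "[") {
      depth <- depth + 1L
      next
    }
    if (tk$letter == "]") {
      depth <- depth - 1L
      if (depth == 0L && !is.na(root)) {
        cd <- classify(root, root_param)
        if (!is.na(cd)) codes <- c(codes, cd)
        root <- NA_character_
      }
      next
    }
    if (depth >= 1L && is.na(root) &&
        tk$letter %in% c(LSYS_ORGANS, LSYS_CONTROLS)) {
      root <- tk$letter
      root_param <- if (length(tk$params)) tk$params[1] else NA_real_
    }
  }
  # paired terminal groups -> one terminal code
  while (length(codes) >= 2 &&
         codes[length(codes)] %in% 4:5 &&
         codes[length(codes) - 1L] == codes[length(codes)])
    codes <- codes[-length(codes)]
  codes
}

# bracket balance predicate used by property tests
lstring_balanced <- function(s) {
  d <- 0L
  for (tk in s) {
    if (tk$letter == "[") d <- d + 1L
    if (tk$letter == "]") { d <- d - 1L; if (d < 0L) return(FALSE) }
  }
  d == 0L
}
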