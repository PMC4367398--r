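test_that("choice strings are validated and reproducible", {
  expect_s3_class(choice_string(c(2, 2, 1, 2, 1, 2, 3, 1, 5)), "choice_string")
  expect_error(choice_string(c(2, 6)), class = "tomstem_invalid_choice")
  expect_error(choice_string(integer(0)), class = "tomstem_invalid_choice")
  expect_error(choice_string(c(4, 1, 2)), class = "tomstem_invalid_choice")
  expect_error(choice_string(c(1, 4, 5)), class = "tomstem_invalid_choice")
  expect_identical(random_choice(3), random_choice(3))
  expect_error(make_axiom(c(1, 6)), class = "tomstem_invalid_choice")
})

test_that("a production holds only on letter, arity and condition together", {
  rules <- parse_grammar(c("F(age) : age == r -> S(0)"))
  p <- rules[[1]]
  expect_false(match_production(p, tomstem:::lsys_token("L", 2)))   # letter
  expect_false(match_production(p, tomstem:::lsys_token("F", c(2, 1)))) # arity
  expect_false(match_production(p, tomstem:::lsys_token("F", 3)))   # condition
  expect_true(match_production(p, tomstem:::lsys_token("F", Inf)))  # age == r
})

test_that("grammar files reject unbound names and malformed rules at load", {
  expect_error(parse_grammar("F(a) : b == 1 -> F(a)"),
               class = "tomstem_grammar_error")
  expect_error(parse_grammar("F(a) :  -> F(q+1)"),
               class = "tomstem_grammar_error")
  expect_error(parse_grammar("F a : -> F"), class = "tomstem_grammar_error")
})

test_that("two simultaneously holding productions raise an ambiguity error", {
  rules <- parse_grammar(c("F(a) : a == 1 -> F(2)", "F(a) :  -> F(0)"))
  s <- parse_lstring("F(1)")
  expect_error(lsys_step(s, rules), class = "tomstem_ambiguous_grammar")
})

test_that("the mature-leaf bifurcation rewrites verbatim", {
  rules <- default_grammar("ordinary")
  out <- lsys_step(parse_lstring("[+L(r)]"), rules)
  expect_identical(lstring_to_string(out), "[+L(3)][-L(0)]")
})

test_that("organs age in place and freeze to the stable state", {
  rules <- default_grammar("ordinary")
  expect_identical(lstring_to_string(lsys_step(parse_lstring("G(2)"), rules)),
                   "G(3)")
  expect_identical(lstring_to_string(lsys_step(parse_lstring("G(5)"), rules)),
                   "G(r)")                       # fruit maturity 6
  expect_identical(lstring_to_string(lsys_step(parse_lstring("G(r)"), rules)),
                   "G(r)")                       # stable state persists
  expect_identical(length(lsys_step(tomstem:::new_lstring(list()), rules)), 0L)
})

test_that("flower stalks bear flowers that wither into fruit", {
  rules <- default_grammar("ordinary")
  s <- parse_lstring("P(0)")
  trace <- character(0)
  for (k in 1:7) { s <- lsys_step(s, rules); trace <- c(trace, lstring_to_string(s)) }
  expect_identical(trace[1], "P(1)")
  expect_identical(trace[2], "P(r)[H(0)]")
  expect_identical(trace[5], "P(r)[G(0)]")       # flower -> fruit in place
})

test_that("growth follows the choice string bottom to top", {
  choice <- c(2, 2, 1, 2, 1, 2, 3, 1, 5)
  states <- lsys_grow(make_axiom(choice, "ordinary"), 12)
  expect_length(states, 13)
  expect_identical(lstring_to_string(states[[1]]), "F(0)A(0,0)")
  final <- states[[13]]
  expect_identical(branch_types(final), as.integer(choice))
  # terminal flowers only atop the main stem: the trailing y bud closes it
  letters <- vapply(final, `[[`, "", "letter")
  expect_identical(letters[length(letters)], "y")
})

test_that("every stage is bracket-balanced with non-decreasing symbol count", {
  for (seed in c(2, 9, 17)) {
    ax <- make_axiom(random_choice(seed),
                     if (seed %% 2) "ordinary" else "cherry")
    states <- lsys_grow(ax, 10)
    expect_true(all(vapply(states, tomstem:::lstring_balanced, NA)))
    expect_true(all(diff(vapply(states, length, 0L)) >= 0))
  }
})

test_that("growth is deterministic and n_stages = 0 returns only the axiom", {
  ax <- make_axiom(c(1, 2, 5), "cherry")
  expect_identical(lsys_grow(ax, 0), list(ax))
  a <- lsys_grow(make_axiom(random_choice(5), "ordinary"), 8)
  b <- lsys_grow(make_axiom(random_choice(5), "ordinary"), 8)
  expect_identical(vapply(a, lstring_to_string, ""),
                   vapply(b, lstring_to_string, ""))
})

test_that("cherry and ordinary grammars diverge where flowers meet leaves", {
  choice <- c(2, 2, 1, 5)                        # contains a type-2 branch
  so <- lsys_grow(make_axiom(choice, "ordinary"), 8)
  sc <- lsys_grow(make_axiom(choice, "cherry"), 8)
  to <- vapply(so, lstring_to_string, "")
  tc <- vapply(sc, lstring_to_string, "")
  d <- which(to != tc)
  expect_gt(length(d), 0)
  # frozen from running both default grammars: the strings first differ at
  # stage 3, when the type-2 branch control expands
  expect_identical(min(d), 4L)                   # states[[4]] = stage 3
  # the cherry type-2 branch carries flower stalks, the ordinary one not
  has_P_on_f <- function(s) grepl("f\\(0\\)\\[#L\\(0\\)\\]\\[&P\\(0\\)\\]", s)
  expect_true(has_P_on_f(tc[4]))
  expect_false(has_P_on_f(to[4]))
})

test_that("parse and print are inverse on bracketed parametric strings", {
  txt <- "F(2)/[&B(2,0)]S(r)[+L(3)][-L(0)]A(1,1)"
  expect_identical(lstring_to_string(parse_lstring(txt)), txt)
  expect_error(parse_lstring("F(1)]["), class = "tomstem_structure_error")
  expect_error(parse_lstring("Q(1)"), class = "tomstem_parse_error")
  expect_identical(lstring_to_string(parse_lstring("F(1)][", validate = FALSE)),
                   "F(1)][")
})
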