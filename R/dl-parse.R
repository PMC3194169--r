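# Recursive-descent parser for the Manchester-style surface syntax.
# Precedence: not > and > or; restriction fillers are primaries, so
# "has_grain some H-Atom and A" is (has_grain some H-Atom) and A.

.KEYWORDS <- c("and", "or", "not", "some", "only", "exactly", "min", "max")

.tokenize <- function(text) {
  pat <- "\\(|\\)|[0-9]+|[A-Za-z][A-Za-z0-9_'.\\-]*"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  toks <- if (m[1L] == -1L) character() else regmatches(text, list(m))[[1L]]
  pos <- if (m[1L] == -1L) integer() else as.integer(m)
  # everything outside a token must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(toks))
    covered[seq(pos[i], length.out = attr(m, "match.length")[i])] <- TRUE
  chars <- strsplit(text, "")[[1L]]
  bad <- which(!covered & !grepl("^\\s$", chars))
  if (length(bad)) .stopf("syntax error at position %d: unexpected '%s'",
                          bad[1L], chars[bad[1L]])
  list(toks = toks, pos = pos)
}

#' Parse a Manchester-style class expression
#'
#' Grammar: `or`-expressions of `and`-expressions of primaries; a primary
#' is an optionally negated restriction (`ROLE some|only PRIMARY`,
#' `ROLE exactly|min|max N PRIMARY`), a parenthesized expression, or an
#' atomic class name. Keywords are reserved; syntax errors report the
#' character position.
#'
#' @param text the expression, e.g.
#'   `"has_grain some H-Atom and has_grain only H-Atom"`.
#' @return a [ClassExpr-class]
#' @export
parseClassExpr <- function(text) {
  st <- new.env(parent = emptyenv())
  tk <- .tokenize(text)
  st$toks <- tk$toks; st$pos <- tk$pos; st$i <- 1L; st$text <- text
  e <- .pOr(st)
  if (st$i <= length(st$toks))
    .stopf("syntax error at position %d: unexpected '%s'",
           st$pos[st$i], st$toks[st$i])
  e
}

.peek <- function(st) if (st$i <= length(st$toks)) st$toks[st$i] else ""
.advance <- function(st) { t <- .peek(st); st$i <- st$i + 1L; t }
.expect <- function(st, what) {
  t <- .peek(st)
  if (!identical(t, what))
    .stopf("syntax error at position %d: expected '%s', found '%s'",
           if (st$i <= length(st$toks)) st$pos[st$i] else nchar(st$text) + 1L,
           what, if (nzchar(t)) t else "end of input")
  .advance(st)
}

.pOr <- function(st) {
  args <- list(.pAnd(st))
  while (identical(.peek(st), "or")) {
    .advance(st)
    args <- c(args, list(.pAnd(st)))
  }
  if (length(args) == 1L) args[[1L]] else .expr("or", args = args)
}

.pAnd <- function(st) {
  args <- list(.pPrimary(st))
  while (identical(.peek(st), "and")) {
    .advance(st)
    args <- c(args, list(.pPrimary(st)))
  }
  if (length(args) == 1L) args[[1L]] else .expr("and", args = args)
}

.pPrimary <- function(st) {
  t <- .peek(st)
  if (!nzchar(t))
    .stopf("syntax error at position %d: unexpected end of input",
           nchar(st$text) + 1L)
  if (identical(t, "not")) {
    .advance(st)
    return(.expr("not", args = list(.pPrimary(st))))
  }
  if (identical(t, "(")) {
    .advance(st)
    e <- .pOr(st)
    .expect(st, ")")
    return(e)
  }
  if (t %in% .KEYWORDS || grepl("^[0-9]", t))
    .stopf("syntax error at position %d: unexpected '%s'", st$pos[st$i], t)
  nxt <- if (st$i + 1L <= length(st$toks)) st$toks[st$i + 1L] else ""
  if (nxt %in% c("some", "only")) {
    role <- .advance(st); quant <- .advance(st)
    return(.expr(quant, role = role, args = list(.pPrimary(st))))
  }
  if (nxt %in% c("exactly", "min", "max")) {
    role <- .advance(st); quant <- .advance(st)
    numTok <- .peek(st)
    if (!grepl("^[0-9]+$", numTok))
      .stopf("syntax error at position %d: expected a cardinality after '%s'",
             if (st$i <= length(st$toks)) st$pos[st$i] else nchar(st$text) + 1L,
             quant)
    .advance(st)
    n <- as.integer(numTok)
    if (quant %in% c("exactly", "min") && n < 1L)
      .stopf("syntax error at position %d: '%s %d' needs n >= 1",
             st$pos[st$i - 1L], quant, n)
    return(.expr(quant, role = role, n = n, args = list(.pPrimary(st))))
  }
  atomicClass(.advance(st))
}
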