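# Atom-selection mini-language.
#
# Grammar (EBNF):
#   expr     := or_expr
#   or_expr  := and_expr { "or" and_expr }
#   and_expr := unary { "and" unary }
#   unary    := "not" unary | primary
#   primary  := "(" expr ")"
#             | "resid" range { ("," | " ") range }
#             | "name" ident { ident }
#             | "chain" ident { ident }
#             | "backbone" | "sidechain" | "heavy" | "calpha" | "all"
#   range    := INT | INT "-" INT
#
# "backbone" selects atoms named N, CA, C, O; "heavy" all non-hydrogens;
# "sidechain" heavy atoms that are not backbone.  Example:
# "resid 6-165 and backbone".

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

tokenize_selection <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  text <- gsub(",", " ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

#' Parse an atom-selection expression
#'
#' Compiles a selection string such as `"resid 6-165 and backbone"` into a
#' predicate function over an atom table.
#'
#' @param text selection string (see package vignette for the grammar).
#' @return a function taking an atom data frame and returning a logical vector.
#' @export
parse_selection <- function(text) {
  toks <- tokenize_selection(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  expect <- function(t) {
    if (!identical(peek(), t)) stop("selection parse error: expected '", t,
                                    "' near position ", pos, " in: ", text)
    advance()
  }

  parse_expr <- function() {
    fns <- list(parse_and())
    while (identical(peek(), "or")) { advance(); fns <- c(fns, list(parse_and())) }
    if (length(fns) == 1L) return(fns[[1L]])
    function(a) Reduce(`|`, lapply(fns, function(f) f(a)))
  }
  parse_and <- function() {
    fns <- list(parse_unary())
    while (identical(peek(), "and")) { advance(); fns <- c(fns, list(parse_unary())) }
    if (length(fns) == 1L) return(fns[[1L]])
    function(a) Reduce(`&`, lapply(fns, function(f) f(a)))
  }
  parse_unary <- function() {
    if (identical(peek(), "not")) {
      advance(); f <- parse_unary()
      return(function(a) !f(a))
    }
    parse_primary()
  }
  is_value_tok <- function(t) {
    !is.na(t) && !t %in% c("and", "or", "not", "(", ")", "resid", "name",
                           "chain", "backbone", "sidechain", "heavy",
                           "calpha", "all")
  }
  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) stop("selection parse error: unexpected end of input in: ", text)
    if (t == "(") {
      advance(); f <- parse_expr(); expect(")"); return(f)
    }
    advance()
    switch(t,
      resid = {
        ranges <- list()
        while (is_value_tok(peek())) {
          v <- advance()
          if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
            ab <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1L]])
            ranges <- c(ranges, list(seq(ab[1L], ab[2L])))
          } else if (grepl("^-?[0-9]+$", v)) {
            ranges <- c(ranges, list(as.integer(v)))
          } else stop("selection parse error: bad resid token '", v, "'")
        }
        if (!length(ranges)) stop("selection parse error: resid needs values")
        ids <- unique(unlist(ranges))
        function(a) a$resid %in% ids
      },
      name = {
        nm <- character(0)
        while (is_value_tok(peek())) nm <- c(nm, advance())
        if (!length(nm)) stop("selection parse error: name needs values")
        function(a) a$atom %in% nm
      },
      chain = {
        ch <- character(0)
        while (is_value_tok(peek())) ch <- c(ch, advance())
        if (!length(ch)) stop("selection parse error: chain needs values")
        function(a) a$chain %in% ch
      },
      backbone = function(a) a$atom %in% BACKBONE_ATOMS,
      sidechain = function(a) a$element != "H" & !a$atom %in% BACKBONE_ATOMS,
      heavy = function(a) a$element != "H",
      calpha = function(a) a$atom == "CA",
      all = function(a) rep(TRUE, nrow(a)),
      stop("selection parse error: unknown token '", t, "' in: ", text)
    )
  }

  f <- parse_expr()
  if (pos <= length(toks)) stop("selection parse error: trailing tokens in: ", text)
  f
}

#' Select atoms of a model
#'
#' @param model a `structure_model`.
#' @param selection selection string, logical vector, integer index, or a
#'   predicate function from [parse_selection()].
#' @return integer indices of selected atoms (in model order).
#' @export
select_atoms <- function(model, selection) {
  a <- model$atoms
  if (is.character(selection)) selection <- parse_selection(selection)
  if (is.function(selection)) {
    keep <- selection(a)
    stopifnot(is.logical(keep), length(keep) == nrow(a))
    return(which(keep))
  }
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}
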