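#' Select atoms with a small selection language
#'
#' Grammar (case-insensitive keywords):
#' \preformatted{
#'   expr    := term ( "or" term )*
#'   term    := factor ( "and" factor )*
#'   factor  := "not" factor | "(" expr ")" | primary
#'   primary := "chain" <id>... | "resid" <int|a:b>... | "resname" <name>...
#'            | "name" <name>... | "backbone" | "water" | "ion" | "all"
#' }
#' `backbone` matches non-water, non-ion atoms named N, CA, C or O.
#' `resid` accepts integers and `a:b` ranges. Value lists are unions, so
#' `resid 24 32 73` matches any of the three.
#'
#' @param top a `topology`.
#' @param expression selection string.
#' @return An `atom_selection`: sorted unique integer indices into
#'   `top$atoms`, with the originating expression attached. May be empty.
#' @export
#' @examples
#' top <- topology(data.frame(serial = 1:2, name = c("CA", "CB"),
#'                            resname = "ALA", resid = 1, chain = "A"))
#' select_atoms(top, "name CA")
select_atoms <- function(top, expression) {
  stopifnot(inherits(top, "topology"), is.character(expression),
            length(expression) == 1)
  tokens <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  st$expr <- expression
  mask <- parse_sel_expr(st, top)
  if (st$pos <= nrow(st$tokens)) {
    sel_syntax_error(expression, st$tokens$start[st$pos],
                     paste0("unexpected token '", st$tokens$text[st$pos], "'"))
  }
  idx <- which(mask)
  structure(as.integer(idx), expression = expression, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection: %d atoms from '%s'\n",
              length(x), attr(x, "expression")))
  invisible(x)
}

#' Indices of an atom selection
#' @param sel an `atom_selection` or plain integer vector.
#' @return Integer index vector.
#' @export
selection_indices <- function(sel) as.integer(sel)

SEL_KEYWORDS <- c("chain", "resid", "resname", "name", "backbone", "water",
                  "ion", "all", "and", "or", "not", "(", ")")

tokenize_selection <- function(expression) {
  m <- gregexpr("\\(|\\)|[^\\s()]+", expression, perl = TRUE)[[1]]
  if (m[1] == -1) {
    sel_syntax_error(expression, 1L, "empty selection")
  }
  data.frame(text = regmatches(expression, list(m))[[1]],
             start = as.integer(m), stringsAsFactors = FALSE)
}

sel_syntax_error <- function(expression, pos, msg) {
  stop(sprintf("selection syntax error at position %d in '%s': %s",
               pos, expression, msg), call. = FALSE)
}

sel_peek <- function(st) {
  if (st$pos > nrow(st$tokens)) NA_character_ else tolower(st$tokens$text[st$pos])
}

sel_take <- function(st) {
  tok <- st$tokens[st$pos, ]
  st$pos <- st$pos + 1L
  tok
}

parse_sel_expr <- function(st, top) {
  mask <- parse_sel_term(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "or") {
    sel_take(st)
    mask <- mask | parse_sel_term(st, top)
  }
  mask
}

parse_sel_term <- function(st, top) {
  mask <- parse_sel_factor(st, top)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "and") {
    sel_take(st)
    mask <- mask & parse_sel_factor(st, top)
  }
  mask
}

parse_sel_factor <- function(st, top) {
  tok <- sel_peek(st)
  expr_str <- st$expr
  if (is.na(tok)) {
    sel_syntax_error(expr_str, nchar(expr_str) + 1L, "unexpected end of expression")
  }
  if (tok == "not") {
    sel_take(st)
    return(!parse_sel_factor(st, top))
  }
  if (tok == "(") {
    open <- sel_take(st)
    mask <- parse_sel_expr(st, top)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")") {
      sel_syntax_error(expr_str, open$start, "unbalanced parenthesis")
    }
    sel_take(st)
    return(mask)
  }
  parse_sel_primary(st, top)
}

# value tokens following a field keyword: everything up to the next keyword
sel_values <- function(st, keyword_tok) {
  vals <- character(0)
  while (!is.na(sel_peek(st)) && !(sel_peek(st) %in% SEL_KEYWORDS)) {
    vals <- c(vals, sel_take(st)$text)
  }
  if (length(vals) == 0) {
    sel_syntax_error(st$expr,
                     keyword_tok$start,
                     paste0("'", keyword_tok$text, "' requires at least one value"))
  }
  vals
}

parse_sel_primary <- function(st, top) {
  a <- top$atoms
  tok <- sel_peek(st)
  kw <- sel_take(st)
  switch(tok,
    "all" = rep(TRUE, nrow(a)),
    "water" = a$is_water,
    "ion" = a$is_ion,
    "backbone" = !a$is_water & !a$is_ion & a$name %in% c("N", "CA", "C", "O"),
    "chain" = a$chain %in% sel_values(st, kw),
    "name" = toupper(a$name) %in% toupper(sel_values(st, kw)),
    "resname" = toupper(a$resname) %in% toupper(sel_values(st, kw)),
    "resid" = {
      vals <- sel_values(st, kw)
      ids <- integer(0)
      for (v in vals) {
        if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
          rng <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
          ids <- c(ids, seq(rng[1], rng[2]))
        } else if (grepl("^-?[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else {
          sel_syntax_error(st$expr, kw$start,
                           paste0("invalid resid value '", v, "'"))
        }
      }
      a$resid %in% ids
    },
    sel_syntax_error(st$expr, kw$start,
                     paste0("unknown keyword '", kw$text, "'"))
  )
}
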