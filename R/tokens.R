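# Tokenizer / parser for the polymer-extended SMILES dialect.
#
# The grammar is the SMILES organic subset plus four bracketed polymer
# tokens: [>] chain initiation, [<] chain termination, [$] stochastic
# point, [#] cross-link site. Polymer tokens are only legal at top level
# (branch depth 0); inside branches the grammar is plain SMILES.

POLYMER_TOKENS <- c(
  "chain-init"      = "[>]",
  "chain-term"      = "[<]",
  "stochastic-point" = "[$]",
  "crosslink-site"  = "[#]"
)

#' Parse a polymer-extended SMILES string
#'
#' Tokenizes a SMILES string extended with the four polymer tokens
#' `[>]` (chain initiation), `[<]` (chain termination), `[$]`
#' (stochastic point) and `[#]` (cross-link site) into an ordered token
#' sequence. Parsing is purely lexical plus structural checks: branches
#' must balance and ring-closure digits must pair up.
#'
#' @param text A single string. The empty string yields an empty token
#'   sequence.
#' @return A `poly_sequence`: a list with `tokens` (a tibble with
#'   columns `kind`, `text`, `pos`) and `source_text`.
#'   `serialize_sequence()` of the result reproduces `text` exactly.
#' @export
#' @examples
#' seq <- parse_bigsmiles_ext("CC[$]CC")
#' seq$tokens
parse_bigsmiles_ext <- function(text) {
  if (is.null(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single non-NA string", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kinds <- character(0)
  texts <- character(0)
  poss <- integer(0)
  i <- 1L
  depth <- 0L
  push <- function(kind, txt, pos) {
    kinds[[length(kinds) + 1L]] <<- kind
    texts[[length(texts) + 1L]] <<- txt
    poss[[length(poss) + 1L]] <<- pos
  }
  two_letter <- c("Cl", "Br")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic <- c("b", "c", "n", "o", "p", "s")
  bonds <- c("-", "=", "#", "$", ":", "/", "\\", ".")

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(sprintf("unclosed bracket at offset %d", i), call. = FALSE)
      content <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      full <- paste0("[", content, "]")
      if (full %in% POLYMER_TOKENS) {
        if (depth > 0L) {
          stop(sprintf("polymer token %s inside a branch at offset %d", full, i),
               call. = FALSE)
        }
        push(names(POLYMER_TOKENS)[match(full, POLYMER_TOKENS)], full, i)
      } else if (grepl("^[0-9]*[A-Za-z][a-z]?[@]{0,2}H?[0-9]*[+-]{0,3}[0-9]*$", content)) {
        push("atom", full, i)
      } else {
        stop(sprintf("unknown bracket token %s at offset %d", full, i), call. = FALSE)
      }
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      push("atom", paste0(ch, chars[i + 1L]), i)
      i <- i + 2L
    } else if (ch %in% organic || ch %in% aromatic) {
      push("atom", ch, i)
      i <- i + 1L
    } else if (ch %in% bonds) {
      push("bond", ch, i)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      push("ring-closure", ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop(sprintf("malformed %%nn ring closure at offset %d", i), call. = FALSE)
      }
      push("ring-closure", paste0("%", chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == "(") {
      depth <- depth + 1L
      push("branch-open", ch, i)
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("unbalanced ')' at offset %d", i), call. = FALSE)
      push("branch-close", ch, i)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at offset %d", ch, i), call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop(sprintf("unbalanced '(' (%d left open) at end of input", depth), call. = FALSE)
  }
  # ring-closure digits must pair up (reuse after closing is allowed)
  open_rings <- character(0)
  for (k in seq_along(kinds)) {
    if (kinds[k] == "ring-closure") {
      lbl <- texts[k]
      hit <- match(lbl, open_rings)
      if (is.na(hit)) open_rings <- c(open_rings, lbl) else open_rings <- open_rings[-hit]
    }
  }
  if (length(open_rings) > 0L) {
    stop(sprintf("unmatched ring closure(s): %s", paste(open_rings, collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(
      tokens = tibble::tibble(kind = kinds, text = texts, pos = poss),
      source_text = text
    ),
    class = "poly_sequence"
  )
}

#' Serialize a polymer token sequence back to text
#'
#' Inverse of [parse_bigsmiles_ext()]: concatenates token literals in
#' order, so `serialize_sequence(parse_bigsmiles_ext(s)) == s` for any
#' well-formed input.
#'
#' @param seq A `poly_sequence`.
#' @return A single string.
#' @export
serialize_sequence <- function(seq) {
  stopifnot(inherits(seq, "poly_sequence"))
  paste0(seq$tokens$text, collapse = "")
}

#' @export
print.poly_sequence <- function(x, ...) {
  cat("<poly_sequence> ", x$source_text, "\n", sep = "")
  cat("  ", nrow(x$tokens), " tokens (",
      sum(x$tokens$kind == "atom"), " atoms)\n", sep = "")
  invisible(x)
}

# Count tokens of a given kind.
count_tokens <- function(seq, kind) sum(seq$tokens$kind == kind)
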