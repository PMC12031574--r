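#' Split a SMILES string into SMILES-atoms
#'
#' A SMILES-atom is the smallest indivisible unit of a SMILES string: a single
#' character, a two-letter element symbol (`Cl`, `Br`, ...), the chirality
#' marker `@@`, or a two-digit ring closure `%nn`. Multi-character units lose
#' their meaning if split, so they are matched greedily left to right.
#'
#' @param smiles A single non-empty SMILES string without whitespace.
#' @param two_letter Character vector of two-letter element symbols recognised
#'   as single tokens. The default covers the symbols that occur in organic
#'   and organometallic SMILES handled by this framework.
#' @return Character vector of tokens; concatenating them reproduces `smiles`.
#' @examples
#' smiles_tokenize("ClCC")   # "Cl" "C" "C"
#' smiles_tokenize("C%11")   # "C" "%11"
#' @export
smiles_tokenize <- function(smiles,
                            two_letter = c("Cl", "Br", "Si", "Se", "Na", "Li",
                                           "Mg", "Ca", "Al", "As", "Zn", "Sn")) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L)
    stopf("'smiles' must be a single non-empty string")
  if (grepl("[[:space:]]", smiles))
    stopf("SMILES must not contain whitespace: %s", smiles)

  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "%") {
      if (i + 2L > n || !all(grepl("^[0-9]$", chars[(i + 1L):(i + 2L)])))
        stopf("malformed SMILES: '%%' must be followed by two digits in %s",
              smiles)
      tokens <- c(tokens, paste0(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == "@" && i < n && chars[i + 1L] == "@") {
      tokens <- c(tokens, "@@")
      i <- i + 2L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

# -- canonical 12-character attribute codes ---------------------------------

.SLOT_WIDTH <- 4L
.N_SLOTS <- 3L

pad_token <- function(tok) {
  if (nchar(tok) > .SLOT_WIDTH)
    stopf("token '%s' exceeds the %d-character slot width", tok, .SLOT_WIDTH)
  paste0(tok, strrep(".", .SLOT_WIDTH - nchar(tok)))
}

#' Build the canonical 12-character code of one SMILES attribute
#'
#' Attributes come in three families: `Sk` (one token), `SSk` (an adjacent
#' pair) and `SSSk` (an adjacent triple). Each token occupies a 4-character
#' slot padded with `'.'`; unused slots are `"...."`. Codes are canonicalised
#' so that a token sequence and its reverse produce the same code: a pair is
#' written with the byte-wise greater token first, and a triple keeps the
#' orientation whose first token is greater than or equal to its last.
#'
#' @param tokens Character vector of 1, 2 or 3 SMILES-atoms.
#' @return A 12-character code string.
#' @examples
#' attribute_code("Cl")              # "Cl.........."
#' attribute_code(c("C", "N"))       # "N...C......."
#' @export
attribute_code <- function(tokens) {
  k <- length(tokens)
  if (k < 1L || k > .N_SLOTS)
    stopf("an attribute has 1 to %d tokens, got %d", .N_SLOTS, k)
  if (k == 2L && lex_gt(tokens[2L], tokens[1L]))
    tokens <- rev(tokens)
  if (k == 3L && lex_gt(tokens[3L], tokens[1L]))
    tokens <- rev(tokens)
  slots <- vapply(tokens, pad_token, character(1L), USE.NAMES = FALSE)
  paste0(paste0(slots, collapse = ""),
         strrep(".", (.N_SLOTS - k) * .SLOT_WIDTH))
}

#' Family of a canonical attribute code
#'
#' @param code Character vector of 12-character attribute codes.
#' @return Character vector with values `"Sk"`, `"SSk"` or `"SSSk"`.
#' @export
attribute_family <- function(code) {
  slot2 <- substr(code, 5L, 8L)
  slot3 <- substr(code, 9L, 12L)
  ifelse(slot2 == "....", "Sk", ifelse(slot3 == "....", "SSk", "SSSk"))
}

#' Extract all SMILES attributes of a token sequence
#'
#' Returns, with multiplicity, every single token (`Sk`), every adjacent pair
#' (`SSk`) and every adjacent triple (`SSSk`) as canonical codes. For a token
#' list of length L this yields L + max(L-1, 0) + max(L-2, 0) codes. The
#' result is invariant, as a multiset, to reversing the token sequence.
#'
#' @param x Either a SMILES string or a token vector from [smiles_tokenize()].
#' @param family Restrict the output to one family, or `"all"` (default).
#' @return Character vector of canonical 12-character codes.
#' @examples
#' smiles_attributes("ClC")
#' @export
smiles_attributes <- function(x, family = c("all", "Sk", "SSk", "SSSk")) {
  family <- match.arg(family)
  tokens <- if (length(x) == 1L && !inherits(x, "AsIs")) smiles_tokenize(x)
            else as.character(x)
  L <- length(tokens)
  if (any(nchar(tokens) > .SLOT_WIDTH))
    stopf("tokens longer than %d characters are not representable",
          .SLOT_WIDTH)
  pads <- paste0(tokens, strrep(".", .SLOT_WIDTH - nchar(tokens)))
  # byte-order rank of each token, for vectorized canonical orientation
  rk <- match(tokens, lex_sort(unique(tokens)))
  codes <- character(0)
  if (family %in% c("all", "Sk"))
    codes <- c(codes, paste0(pads, "........"))
  if (family %in% c("all", "SSk") && L >= 2L) {
    a <- seq_len(L - 1L); b <- a + 1L
    swap <- rk[b] > rk[a]
    first <- ifelse(swap, pads[b], pads[a])
    second <- ifelse(swap, pads[a], pads[b])
    codes <- c(codes, paste0(first, second, "...."))
  }
  if (family %in% c("all", "SSSk") && L >= 3L) {
    a <- seq_len(L - 2L); m <- a + 1L; z <- a + 2L
    swap <- rk[z] > rk[a]
    first <- ifelse(swap, pads[z], pads[a])
    third <- ifelse(swap, pads[a], pads[z])
    codes <- c(codes, paste0(first, pads[m], third))
  }
  codes
}
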