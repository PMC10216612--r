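# Degenerate (PROSITE-style) motif engine.
#
# A compiled pattern is a list of allowed-residue character vectors, one per
# position: a singleton for a fixed residue, the full 20-letter alphabet for
# the wildcard x/X. An X residue in the *protein* matches only wildcard
# positions.

#' Compile a dash-separated degenerate pattern
#'
#' Syntax: positions separated by `-`; a bare residue fixes that position;
#' `[...]` lists alternatives; `x` or `X` is a wildcard matching any residue.
#'
#' @param pattern_text e.g. `"Q-x-V-x-G"` or
#'   `"[LVI]-[AGT]-[RKE]-[FY]-[AS]-[VI]-X-[EDQV]-[HYFQ]-N"`.
#' @param name Optional pattern name (defaults to the pattern text).
#' @return A `"motif_pattern"`: list with `name` and `positions`.
#' @export
compile_pattern <- function(pattern_text, name = pattern_text) {
  toks <- strsplit(pattern_text, "-", fixed = TRUE)[[1]]
  if (length(toks) < 2L) stop("pattern must have at least 2 positions")
  col <- 1L
  positions <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- toks[i]
    if (!nzchar(tok)) stop(sprintf("empty position at column %d", col))
    if (grepl("^\\[", tok)) {
      if (!grepl("^\\[[A-Z]+\\]$", tok)) {
        stop(sprintf("malformed bracket expression '%s' at column %d", tok, col))
      }
      res <- strsplit(substr(tok, 2L, nchar(tok) - 1L), "", fixed = TRUE)[[1]]
    } else if (tok %in% c("x", "X")) {
      res <- AA_ALPHABET
    } else {
      res <- toupper(tok)
    }
    if (!all(res %in% AA_ALPHABET)) {
      bad <- setdiff(res, AA_ALPHABET)
      stop(sprintf("illegal residue '%s' at column %d", bad[1], col))
    }
    positions[[i]] <- res
    col <- col + nchar(tok) + 1L
  }
  structure(list(name = name, positions = positions), class = "motif_pattern")
}

# Regex form of a compiled pattern. Wildcards become "." (which also matches
# an X residue); restricted positions become character classes that cannot
# match X.
pattern_regex <- function(pattern) {
  paste(vapply(pattern$positions, function(res) {
    if (length(res) == length(AA_ALPHABET)) "." else
      paste0("[", paste(res, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Scan a protein for all (possibly overlapping) matches of a pattern
#'
#' @param prot A [protein_record()] or plain amino-acid string.
#' @param pattern A compiled [compile_pattern()] object.
#' @return A data.frame of hits in left-to-right order: `pattern_name`,
#'   `start`, `end` (0-based half-open on the protein), `matched_text`.
#' @export
scan_motif <- function(prot, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  aa <- if (inherits(prot, "protein_record")) prot$aa_seq else prot
  k <- length(pattern$positions)
  # lookahead makes overlapping matches visible
  rx <- paste0("(?=(", pattern_regex(pattern), "))")
  m <- gregexpr(rx, aa, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(pattern_name = character(), start = integer(),
                      end = integer(), matched_text = character(),
                      stringsAsFactors = FALSE))
  }
  start0 <- as.integer(m) - 1L
  data.frame(pattern_name = pattern$name,
             start = start0, end = start0 + k,
             matched_text = substring(aa, start0 + 1L, start0 + k),
             stringsAsFactors = FALSE)
}
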