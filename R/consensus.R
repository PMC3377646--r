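# Degenerate consensus representation and mismatch arithmetic.
#
# A consensus is a fixed-width DNA pattern in which each position allows a
# non-empty subset of {A,C,G,T}. This is the natural representation for
# LacI-family operator sites written in the literature either as IUPAC
# strings (e.g. TGGGAWCGWTCCCA) or with parenthesized alternates
# (e.g. "TGGGA(A/T)CG(A/T)TCCCA").

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Construct a degenerate consensus
#'
#' @param positions list of character vectors, each a non-empty subset of
#'   A/C/G/T giving the allowed bases at that position (5' to 3').
#' @param consensus_id identifier carried into scan hits.
#' @return an object of class `degenerate_consensus` with fields
#'   `consensus_id`, `positions` and `width`.
#' @seealso [parse_consensus()] for the usual text entry point.
#' @export
degenerate_consensus <- function(positions, consensus_id = "consensus") {
  stopifnot(is.list(positions), length(positions) >= 1)
  positions <- lapply(positions, function(p) {
    p <- sort(unique(toupper(p)))
    if (length(p) == 0 || !all(p %in% DNA_BASES))
      stop("each consensus position must be a non-empty subset of A/C/G/T")
    p
  })
  structure(
    list(consensus_id = as.character(consensus_id),
         positions = positions,
         width = length(positions)),
    class = "degenerate_consensus"
  )
}

#' Parse consensus text into a degenerate consensus
#'
#' Accepts plain bases, IUPAC one-letter degeneracy codes (N, W, S, ...),
#' and parenthesized alternates in the literature's "(A/T)" notation.
#'
#' @param text consensus string, e.g. `"TGGGA(A/T)CG(A/T)TCCCA"`.
#' @param consensus_id identifier for the pattern.
#' @return a [degenerate_consensus()].
#' @examples
#' cns <- parse_consensus("TGGGA(A/T)CG(A/T)TCCCA", "Acel")
#' cns$width            # 14
#' cns$positions[[6]]   # "A" "T"
#' @export
parse_consensus <- function(text, consensus_id = "consensus") {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  chars <- strsplit(toupper(text), "", fixed = TRUE)[[1]]
  positions <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      close <- i
      while (close <= length(chars) && chars[close] != ")") close <- close + 1
      if (close > length(chars))
        stop(sprintf("unterminated '(' at column %d", i))
      inner <- chars[(i + 1):(close - 1)]
      alts <- inner[inner != "/"]
      if (length(alts) == 0)
        stop(sprintf("empty alternate group at column %d", i))
      if (!all(alts %in% DNA_BASES))
        stop(sprintf("illegal base in alternate group at column %d", i))
      positions[[length(positions) + 1]] <- alts
      i <- close + 1
    } else if (!is.null(IUPAC_SETS[[ch]])) {
      positions[[length(positions) + 1]] <- IUPAC_SETS[[ch]]
      i <- i + 1
    } else {
      stop(sprintf("illegal character '%s' at column %d", ch, i))
    }
  }
  degenerate_consensus(positions, consensus_id)
}

#' @export
print.degenerate_consensus <- function(x, ...) {
  cat(sprintf("<degenerate_consensus> %s  width=%d\n  %s\n",
              x$consensus_id, x$width, consensus_to_text(x)))
  invisible(x)
}

#' Render a consensus back to compact text
#'
#' Singleton positions print as the base, the full set as N, and other
#' subsets in "(X/Y)" notation.
#'
#' @param c a [degenerate_consensus()].
#' @return single character string.
#' @export
consensus_to_text <- function(c) {
  stopifnot(inherits(c, "degenerate_consensus"))
  paste(vapply(c$positions, function(p) {
    if (length(p) == 1) p
    else if (length(p) == 4) "N"
    else paste0("(", paste(p, collapse = "/"), ")")
  }, character(1)), collapse = "")
}

# Complement an allowed-base set.
complement_set <- function(p) sort(unname(BASE_COMPLEMENT[p]))

#' Reverse-complement a degenerate consensus
#'
#' @param c a [degenerate_consensus()].
#' @return a [degenerate_consensus()] matching the opposite strand.
#' @export
revcomp_consensus <- function(c) {
  stopifnot(inherits(c, "degenerate_consensus"))
  degenerate_consensus(lapply(rev(c$positions), complement_set), c$consensus_id)
}

#' Test whether a degenerate consensus is palindromic
#'
#' A degenerate pattern is a (biological) palindrome when the allowed set at
#' position i equals the base-complement of the allowed set at the mirrored
#' position width+1-i, for every i — i.e. the pattern equals its own reverse
#' complement, so both strands present the same sequence to a homodimeric
#' repressor.
#'
#' @param c a [degenerate_consensus()].
#' @return logical scalar.
#' @export
is_palindrome <- function(c) {
  stopifnot(inherits(c, "degenerate_consensus"))
  w <- c$width
  for (i in seq_len(w)) {
    if (!identical(c$positions[[i]], complement_set(c$positions[[w + 1 - i]])))
      return(FALSE)
  }
  TRUE
}

#' Count mismatches of a window against a consensus
#'
#' A window base matches a position iff it is a member of the allowed set;
#' there is no partial credit for degenerate positions, and an ambiguous
#' 'N' in the genome never matches (it counts as a mismatch).
#'
#' @param window DNA string of length `c$width` over A/C/G/T/N.
#' @param c a [degenerate_consensus()].
#' @return integer mismatch count.
#' @examples
#' acel <- parse_consensus("TGGGA(A/T)CG(A/T)TCCCA")
#' count_mismatches("TGGGAACGGTCCCA", acel)  # 1
#' @export
count_mismatches <- function(window, c) {
  stopifnot(inherits(c, "degenerate_consensus"))
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(chars) != c$width)
    stop(sprintf("window length %d != consensus width %d",
                 length(chars), c$width))
  sum(!mapply(function(b, p) b %in% p, chars, c$positions))
}

#' Per-half-site mismatch counts
#'
#' Splits an even-width consensus into its 5' and 3' half-sites and counts
#' mismatches in each separately — the unit in which operator degeneracy is
#' usually described for palindromic repressor sites ("one base change per
#' half-site").
#'
#' @inheritParams count_mismatches
#' @return integer vector of length 2: mismatches in positions
#'   `[1, width/2]` and `[width/2+1, width]`.
#' @export
half_site_mismatches <- function(window, c) {
  stopifnot(inherits(c, "degenerate_consensus"))
  if (c$width %% 2 != 0)
    stop("half-site mismatch counts require an even consensus width")
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(chars) != c$width)
    stop(sprintf("window length %d != consensus width %d",
                 length(chars), c$width))
  ok <- mapply(function(b, p) b %in% p, chars, c$positions)
  h <- c$width / 2
  c(sum(!ok[seq_len(h)]), sum(!ok[(h + 1):c$width]))
}

#' Built-in operator site consensi
#'
#' The CelR operator of *Thermobifida fusca* and the related organism-
#' specific cellulase-regulator sites used throughout this package. The
#' 14-bp CelR palindrome shipped here (`TGGGAGCGCTCCCA`) is a
#' reconstruction: it is the unique perfect palindrome consistent with all
#' published mismatch annotations of CelR-site variants (see the package
#' vignette), and it can be overridden anywhere a consensus argument is
#' taken.
#'
#' @param id one of `"CelR"`, `"Acel"`, `"Caci"`, `"Cfla1"`, `"Cfla2"`,
#'   `"Actro"`; with no argument, the full named list is returned.
#' @return a [degenerate_consensus()], or a named list of them.
#' @export
builtin_sites <- function(id = NULL) {
  defs <- c(
    CelR  = "TGGGAGCGCTCCCA",
    Acel  = "TGGGA(A/T)CG(A/T)TCCCA",
    Caci  = "(G/C)(G/A)(T/A)G(A/G)AA(G/C)TTTC(G/A)",
    Cfla1 = "CNAA(T/A)CGNTTANNNA",
    Cfla2 = "CNAA(T/A)CGNTTCNNNG",
    Actro = "TG(A/T)AA(G/T)(C/T)T(G/T)C(A/T)"
  )
  sites <- mapply(parse_consensus, defs, names(defs), SIMPLIFY = FALSE)
  if (is.null(id)) return(sites)
  if (!id %in% names(sites))
    stop("unknown built-in site id: ", id)
  sites[[id]]
}

#' The reconstructed CelR operator consensus
#'
#' @return a [degenerate_consensus()] for the 14-bp CelR palindrome.
#' @export
celr_consensus <- function() builtin_sites("CelR")
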