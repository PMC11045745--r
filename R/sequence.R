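#' RNA sequence handling
#'
#' An `rna_sequence` is a plain 5'->3' string over the alphabet A, U, G, C.
#' Lowercase input is accepted and upper-cased; any other character is an
#' error that names the offending position.
#'
#' @param bases character scalar, the sequence written 5'->3'.
#' @return An object of class `rna_sequence` (a validated character scalar).
#' @export
#' @examples
#' rna_sequence("GUCAGUACUGAC")
rna_sequence <- function(bases) {
  if (inherits(bases, "rna_sequence")) return(bases)
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(bases)
  if (nchar(bases) == 0L) stop("RNA sequence must be non-empty")
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "U", "G", "C"))
  if (length(bad))
    stop(sprintf("invalid RNA base '%s' at position %d (alphabet is AUGC)",
                 chars[bad[1]], bad[1]))
  structure(bases, class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("RNA 5'-%s-3' (%d nt)\n", unclass(x), nchar(x)))
  invisible(x)
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A-U, G-C) of the reversed strand, so the result
#' is again written 5'->3'.
#'
#' @param seq an [rna_sequence()] or string coercible to one.
#' @return An `rna_sequence`.
#' @export
reverse_complement <- function(seq) {
  seq <- rna_sequence(seq)
  rev_seq <- paste(rev(strsplit(unclass(seq), "", fixed = TRUE)[[1]]),
                   collapse = "")
  rna_sequence(chartr("AUGC", "UACG", rev_seq))
}

#' Is a strand self-complementary?
#'
#' A strand is self-complementary when it equals its own reverse complement
#' under Watson-Crick pairing, so two copies can form a blunt duplex.  The
#' dimerization model (2 ssRNA = dsRNA) applies only to such strands.
#'
#' @inheritParams reverse_complement
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_self_complementary("UUUAUUAAUAAA")  # TRUE
#' is_self_complementary("UUUU")          # FALSE
is_self_complementary <- function(seq) {
  seq <- rna_sequence(seq)
  unclass(reverse_complement(seq)) == unclass(seq)
}
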