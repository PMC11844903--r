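AA_CODES <- c("A","R","N","D","C","Q","E","G","H","I",
              "L","K","M","F","P","S","T","W","Y","V")
AROMATIC <- c("F", "W", "Y")

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around seqinr's FASTA reader that enforces canonical
#' one-letter amino-acid codes: lowercase letters are uppercased with a
#' warning, non-amino-acid characters raise an error naming the record and
#' position.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names taken from the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing FASTA file: ", path)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  seqs <- vapply(recs, function(x) as.character(x)[1], character(1))
  names(seqs) <- vapply(recs, function(x) attr(x, "name"), character(1))
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues uppercased")
    seqs <- toupper(seqs)
  }
  for (k in seq_along(seqs)) {
    chars <- strsplit(seqs[[k]], "")[[1]]
    bad <- which(!chars %in% AA_CODES)
    if (length(bad) > 0) {
      stop("non-amino-acid character '", chars[bad[1]], "' at position ",
           bad[1], " of record '", names(seqs)[k], "'")
    }
  }
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

#' Packaged A1-LCD variant sequences (synthetic surrogates)
#'
#' Returns the seven-variant family of A1-LCD sequences shipped with the
#' package.  These are labelled synthetic: they are surrogate sequences
#' constructed to satisfy the documented compositional constraints of the
#' A1-LCD aromatic-variant family (WT+NLS with 8Y + 12F; 19 mutable
#' aromatic sticker positions carrying 7Y + 12F with one additional
#' non-mutable Y in the NLS-like tail; variants allF/allY/allW/YtoW/FtoW/W-
#' with 19F, 19Y, 19W, 7W+12F, 7Y+12W and 13W at the sticker positions,
#' sequence patterning conserved), not the experimental construct.
#'
#' @return named character vector with elements WT+NLS, allF, allY, allW,
#'   YtoW, FtoW, W-.
#' @export
a1lcd_variants <- function() {
  read_fasta(system.file("extdata", "sequences",
                         "a1lcd_variants_synthetic.fasta",
                         package = "cgphase"))
}

#' Sticker positions of the packaged A1-LCD surrogate family
#'
#' The 19 mutable aromatic positions shared by all variants (1-based).
#' The 20th aromatic of WT+NLS (a tyrosine in the NLS-like tail) is not a
#' sticker and is never mutated.
#'
#' @return integer vector of length 19.
#' @export
a1lcd_sticker_positions <- function() seq(4L, by = 7L, length.out = 19L)

#' Construct an aromatic-variant substitution rule
#'
#' A rule names the mutable positions and what each aromatic residue there
#' becomes.  `targets` may be a single code (applied to every position), a
#' named map from current aromatic code to replacement (e.g.
#' `c(Y = "W")`), or a vector with one code per position.
#'
#' @param name rule label.
#' @param positions 1-based mutable positions.
#' @param targets replacement specification (see above).
#' @return object of class `variant_rule`.
#' @export
variant_rule <- function(name, positions, targets) {
  stopifnot(length(positions) > 0, all(positions >= 1))
  structure(list(name = name, positions = as.integer(positions),
                 targets = targets), class = "variant_rule")
}

#' Built-in rules for the A1-LCD aromatic variants
#'
#' @param name one of "allF", "allY", "allW", "YtoW", "FtoW", "W-".
#' @return a [variant_rule()] over the packaged sticker positions.
#' @export
a1lcd_variant_rule <- function(name) {
  pos <- a1lcd_sticker_positions()
  switch(name,
    "allF" = variant_rule("allF", pos, "F"),
    "allY" = variant_rule("allY", pos, "Y"),
    "allW" = variant_rule("allW", pos, "W"),
    "YtoW" = variant_rule("YtoW", pos, c(Y = "W", F = "F")),
    "FtoW" = variant_rule("FtoW", pos, c(F = "W", Y = "Y")),
    "W-"   = variant_rule("W-", pos,
                          ifelse(seq_along(pos) %% 3 == 2, "G", "W")),
    stop("unknown variant rule '", name, "'"))
}

#' Apply a variant rule to a reference sequence
#'
#' Only the rule's positions change; every listed position must carry an
#' aromatic residue (F, W or Y) in the reference.  Length and all other
#' positions are preserved, so sequence patterning is conserved.
#'
#' @param reference single sequence string.
#' @param rule a [variant_rule()].
#' @return mutated sequence string.
#' @export
make_variant <- function(reference, rule) {
  stopifnot(inherits(rule, "variant_rule"), is.character(reference),
            length(reference) == 1)
  chars <- strsplit(reference, "")[[1]]
  if (max(rule$positions) > length(chars)) {
    stop("rule positions exceed sequence length")
  }
  cur <- chars[rule$positions]
  notar <- which(!cur %in% AROMATIC)
  if (length(notar) > 0) {
    stop("rule position ", rule$positions[notar[1]],
         " is not aromatic in the reference (found '", cur[notar[1]], "')")
  }
  tg <- rule$targets
  repl <- if (!is.null(names(tg))) {
    unmapped <- setdiff(unique(cur), names(tg))
    if (length(unmapped) > 0) {
      stop("rule map does not cover residue(s): ",
           paste(unmapped, collapse = ", "))
    }
    tg[cur]
  } else if (length(tg) == 1) {
    rep(tg, length(rule$positions))
  } else if (length(tg) == length(rule$positions)) {
    tg
  } else {
    stop("targets must be length 1, a named map, or one per position")
  }
  chars[rule$positions] <- repl
  paste(chars, collapse = "")
}

#' Residue-type composition of a sequence
#'
#' @param sequence single sequence string.
#' @param positions optional subset of 1-based positions to count over
#'   (e.g. the sticker positions).
#' @return named integer vector of counts over the 20 canonical residues;
#'   counts sum to the number of counted positions.
#' @export
composition <- function(sequence, positions = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            nchar(sequence) > 0)
  chars <- strsplit(sequence, "")[[1]]
  if (!is.null(positions)) chars <- chars[positions]
  counts <- table(factor(chars, levels = AA_CODES))
  setNames(as.integer(counts), AA_CODES)
}
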