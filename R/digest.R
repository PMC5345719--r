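# Genome-wide restriction-site counting for GBS enzyme selection, backed by
# Biostrings pattern matching.

BUILTIN_ENZYMES <- list(PstI = "CTGCAG", KpnI = "GGTACC", MspI = "CCGG")

#' Restriction enzyme specification
#'
#' Built-ins: PstI (CTGCAG), KpnI (GGTACC), MspI (CCGG); any other
#' name requires an explicit IUPAC recognition sequence.
#'
#' @param name enzyme name
#' @param site recognition sequence (IUPAC); defaults to the built-in for
#'   known names
#' @return an \linkS4class{EnzymeSpec}
#' @export
enzyme <- function(name, site = NULL) {
  if (is.null(site)) {
    site <- BUILTIN_ENZYMES[[name]]
    if (is.null(site))
      stop("unknown enzyme '", name, "': supply a recognition sequence")
  }
  new("EnzymeSpec", name = name, site = toupper(site))
}

.isPalindromic <- function(site) {
  s <- Biostrings::DNAString(site)
  as.character(Biostrings::reverseComplement(s)) == as.character(s)
}

# sequences as raw character strings; reading through BStringSet preserves
# the lowercase soft-masking that DNAString containers normalize away
.loadSeqs <- function(fasta) {
  if (is(fasta, "XStringSet")) {
    seqs <- as.character(fasta)
  } else {
    seqs <- as.character(Biostrings::readBStringSet(fasta))
  }
  seqs
}

# site start positions of an enzyme in one DNA sequence (uppercased;
# ambiguous bases in the subject never match a concrete pattern base)
.sitePositions <- function(seqUpper, enz) {
  pat <- Biostrings::DNAString(enz@site)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, seqUpper,
                                                    fixed = "subject"))
  if (.isPalindromic(enz@site)) return(sort(fwd))
  rcp <- Biostrings::reverseComplement(pat)
  rev <- Biostrings::start(Biostrings::matchPattern(rcp, seqUpper,
                                                    fixed = "subject"))
  sort(unique(c(fwd, rev)))
}

#' Count restriction sites in a genome
#'
#' Scans one strand for the recognition sequence with overlapping matches
#' allowed; palindromic sites are therefore counted once per genomic
#' location, and non-palindromic sequences are additionally scanned on the
#' reverse complement. Ambiguous bases (N) in the subject never match. By
#' default soft-masked (lowercase) bases are counted as their uppercase
#' equivalents; \code{respectMask = TRUE} excludes sites overlapping
#' masked bases.
#'
#' @param fasta path to a FASTA file, or a Biostrings XStringSet (note that
#'   DNAStringSet containers normalize case, so masking is only visible when
#'   reading from a file or a BStringSet)
#' @param enz an \linkS4class{EnzymeSpec} (see \code{\link{enzyme}})
#' @param respectMask exclude soft-masked matches, default FALSE
#' @return list: \code{perSequence} named counts, \code{total}
#' @export
countSites <- function(fasta, enz, respectMask = FALSE) {
  stopifnot(is(enz, "EnzymeSpec"))
  seqs <- .loadSeqs(fasta)
  counts <- vapply(seq_along(seqs), function(i) {
    raw <- seqs[[i]]
    up <- Biostrings::DNAString(toupper(raw))
    pos <- .sitePositions(up, enz)
    if (respectMask && length(pos)) {
      w <- nchar(enz@site)
      lower <- which(strsplit(raw, "")[[1]] %in% letters)
      if (length(lower)) {
        masked <- vapply(pos, function(p) any(lower >= p & lower < p + w),
                         logical(1))
        pos <- pos[!masked]
      }
    }
    length(pos)
  }, numeric(1))
  names(counts) <- names(seqs)
  list(perSequence = counts, total = sum(counts))
}

#' Predict GBS fragments from a rare/common double digest
#'
#' Enumerates genomic intervals bounded by one rare-cutter site and one
#' common-cutter site with no internal site of either enzyme (the fragments
#' a two-enzyme GBS library samples), using site start coordinates, and
#' filters them by length.
#'
#' @param fasta FASTA path or DNAStringSet
#' @param rare,common \linkS4class{EnzymeSpec} objects
#' @param sizeRange numeric length-2, keep fragments with
#'   sizeRange[1] <= length <= sizeRange[2]; default c(0, Inf)
#' @return list: \code{n} fragment count, \code{lengths}, \code{histogram}
#' @export
predictGBSFragments <- function(fasta, rare, common, sizeRange = c(0, Inf)) {
  stopifnot(is(rare, "EnzymeSpec"), is(common, "EnzymeSpec"))
  seqs <- .loadSeqs(fasta)
  lens <- numeric(0)
  for (i in seq_along(seqs)) {
    up <- Biostrings::DNAString(toupper(seqs[[i]]))
    pr <- .sitePositions(up, rare)
    pc <- .sitePositions(up, common)
    if (!length(pr) || !length(pc)) next
    pos <- sort(c(pr, pc))
    lab <- c(rep("r", length(pr)), rep("c", length(pc)))[order(c(pr, pc))]
    if (length(pos) < 2) next
    pair <- lab[-length(lab)] != lab[-1]
    lens <- c(lens, (pos[-1] - pos[-length(pos)])[pair])
  }
  keep <- lens >= sizeRange[1] & lens <= sizeRange[2]
  lens <- lens[keep]
  list(n = length(lens), lengths = lens,
       histogram = if (length(lens)) graphics::hist(lens, plot = FALSE)
                   else NULL)
}
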