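#' Oligo-dT anchor combinatorics
#'
#' The oligo-dT primer that initiates reverse transcription at the poly(A)
#' junction is anchored by a terminal dinucleotide written in IUPAC codes:
#' the original design ends in `VN` (V = A/C/G, N = A/C/G/T), giving a
#' 12-primer equimolar mixture. To suppress T/A-ligation artifacts from
#' primers ending in adenosine, the redesigned mixture splits into primers
#' ending `VB` (B = C/G/T, phosphorothioate-protected) and primers ending
#' `VA`, which are later depleted enzymatically.
#'
#' `oligo_dt_anchors()` enumerates the dinucleotides for a pair of IUPAC
#' codes; `oligo_dt_primer_counts()` reports the mixture sizes of the
#' original and redesigned primer pools.
#'
#' @param first,second Single IUPAC nucleotide codes for the two anchor
#'   positions.
#' @return `oligo_dt_anchors()`: character vector of dinucleotides.
#'   `oligo_dt_primer_counts()`: named integer vector with elements `VN`,
#'   `VB`, `VA`.
#' @examples
#' oligo_dt_anchors("V", "N")
#' oligo_dt_primer_counts()
#' @export
oligo_dt_anchors <- function(first = "V", second = "N") {
  combos <- expand.grid(a = iupac_bases(first), b = iupac_bases(second),
                        stringsAsFactors = FALSE)
  sort(paste0(combos$a, combos$b))
}

#' @rdname oligo_dt_anchors
#' @export
oligo_dt_primer_counts <- function() {
  c(VN = length(oligo_dt_anchors("V", "N")),
    VB = length(oligo_dt_anchors("V", "B")),
    VA = length(oligo_dt_anchors("V", "A")))
}

#' Expand an IUPAC nucleotide code to its bases
#'
#' @param code Single IUPAC code character.
#' @return Character vector of A/C/G/T bases the code stands for.
#' @export
iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  stopifnot(code %in% names(map))
  strsplit(map[[code]], "")[[1L]]
}
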