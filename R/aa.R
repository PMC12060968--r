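# Titratable residue vocabulary and channel assignment.

TITRATABLE_AAS <- c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS")
ACID_AAS <- c("ASP", "GLU", "CYS", "TYR")
BASE_AAS <- c("HIS", "LYS")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# one-letter codes of the titratable six
TITRATABLE_LETTERS <- unname(AA_THREE_TO_ONE[TITRATABLE_AAS])

#' Normalize amino-acid codes to three-letter form
#'
#' Accepts one-letter (`"D"`) or three-letter (`"ASP"`, `"asp"`) codes and
#' returns upper-case three-letter codes. Codes that are not standard amino
#' acids are returned upper-cased unchanged so that downstream domain checks
#' can report them.
#'
#' @param aa Character vector of amino-acid codes.
#' @return Character vector of three-letter codes.
#' @export
#' @examples
#' normalize_aa(c("D", "glu", "HIS"))
normalize_aa <- function(aa) {
  aa <- toupper(as.character(aa))
  one <- nchar(aa) == 1L & aa %in% names(AA_ONE_TO_THREE)
  aa[one] <- AA_ONE_TO_THREE[aa[one]]
  aa
}

#' Acid/base channel of a titratable residue
#'
#' Asp, Glu, Cys and Tyr belong to the acidic channel; His and Lys to the
#' basic channel. The two channels partition the six titratable types and are
#' modelled by separately trained ensembles.
#'
#' @param aa Amino-acid codes (one- or three-letter).
#' @return Character vector with values `"acid"` or `"base"`.
#' @export
#' @examples
#' channel_of(c("ASP", "HIS", "K"))
channel_of <- function(aa) {
  aa <- normalize_aa(aa)
  bad <- setdiff(unique(aa), TITRATABLE_AAS)
  if (length(bad) > 0) {
    abort(sprintf(
      "channel_of() is defined only for titratable residues (%s); got: %s",
      paste(TITRATABLE_AAS, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  ifelse(aa %in% ACID_AAS, "acid", "base")
}

#' Titratable residue types
#'
#' @return Character vector of the six titratable three-letter codes.
#' @export
titratable_aas <- function() TITRATABLE_AAS
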