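# Standard genetic code, hard-coded (nuclear code only; '*' marks stop).
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  `*` = "Ter"
)

AA_ONE_FROM_THREE <- stats::setNames(names(AA_THREE), unname(AA_THREE))

#' Translate codons under the standard genetic code
#'
#' @param codons character vector of 3-nt codons over A/C/G/T (case
#'   insensitive; U is accepted and read as T).
#' @return character vector of one-letter amino acids, with `"*"` for stop.
#' @examples
#' translate_codons(c("ATG", "TGG", "TAA"))
#' @export
translate_codons <- function(codons) {
  codons <- toupper(codons)
  codons <- gsub("U", "T", codons, fixed = TRUE)
  bad <- nchar(codons) != 3L | grepl("[^ACGT]", codons)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  }
  unname(GENETIC_CODE_STD[codons])
}

# one-letter validation helpers
is_canonical_aa <- function(aa) aa %in% AA_ONE
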