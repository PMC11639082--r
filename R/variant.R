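#' Parse HGVS-style protein variant notation
#'
#' Parses strings such as `"p.Ile157Thr"`, `"p.I157T"`, `"p.Tyr298*"`,
#' `"p.Tyr298Ter"` or `"p.Leu157="` into a normalized variant table.
#' Three-letter and one-letter amino-acid codes yield identical results;
#' `"Ter"` and `"*"` both denote a stop gain; `"="` (or a repeated
#' reference residue) denotes a synonymous change.
#'
#' @param text character vector of protein variant strings (leading
#'   `"p."` optional).
#' @return a data.frame with one row per input and columns `position`
#'   (1-based residue index), `ref_aa`, `alt_aa` (one-letter, `"*"` for
#'   stop), `vclass` (`"missense"`, `"nonsense"` or `"synonymous"`) and
#'   `hgvs_pro` (normalized three-letter notation).
#' @examples
#' parse_protein_variant(c("p.Ile157Thr", "p.Tyr298*", "p.L157L"))
#' @seealso [format_protein_variant()]
#' @export
parse_protein_variant <- function(text) {
  stopifnot(is.character(text))
  m <- regmatches(text, regexec("^(p\\.)?([A-Za-z]{1,3}|\\*)([0-9]+)([A-Za-z]{1,3}|\\*|=)$", text))
  parse_one <- function(s, mm) {
    if (length(mm) == 0L) {
      stop("malformed protein variant string: '", s, "'", call. = FALSE)
    }
    ref <- aa_token_to_one(mm[3], s)
    pos <- as.integer(mm[4])
    alt_tok <- mm[5]
    alt <- if (identical(alt_tok, "=")) ref else aa_token_to_one(alt_tok, s)
    if (identical(ref, "*")) {
      stop("reference residue may not be a stop in '", s, "'", call. = FALSE)
    }
    if (pos < 1L) stop("position must be >= 1 in '", s, "'", call. = FALSE)
    c(ref, pos, alt)
  }
  parsed <- mapply(parse_one, text, m, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  ref_aa <- vapply(parsed, `[`, "", 1L)
  position <- as.integer(vapply(parsed, `[`, "", 2L))
  alt_aa <- vapply(parsed, `[`, "", 3L)
  vclass <- ifelse(alt_aa == "*", "nonsense",
                   ifelse(ref_aa == alt_aa, "synonymous", "missense"))
  out <- data.frame(position = position, ref_aa = ref_aa, alt_aa = alt_aa,
                    vclass = vclass, stringsAsFactors = FALSE)
  out$hgvs_pro <- format_protein_variant(out)
  out
}

# map a one- or three-letter token to a one-letter code; '*'/'Ter' -> '*'
aa_token_to_one <- function(tok, context) {
  if (tok %in% c("*", "Ter", "ter", "TER")) return("*")
  if (nchar(tok) == 1L) {
    tok <- toupper(tok)
    if (!is_canonical_aa(tok)) {
      stop("non-canonical amino acid '", tok, "' in '", context, "'",
           call. = FALSE)
    }
    return(tok)
  }
  tok3 <- paste0(toupper(substr(tok, 1, 1)), tolower(substr(tok, 2, 3)))
  one <- AA_ONE_FROM_THREE[tok3]
  if (is.na(one)) {
    stop("non-canonical amino acid token '", tok, "' in '", context, "'",
         call. = FALSE)
  }
  unname(one)
}

#' Format variants in HGVS p. notation
#'
#' @param variants data.frame with columns `position`, `ref_aa`, `alt_aa`
#'   (as produced by [parse_protein_variant()]).
#' @param three_letter use three-letter codes (default) or one-letter.
#' @return character vector of variant strings; synonymous changes are
#'   written with a trailing `"="`.
#' @export
format_protein_variant <- function(variants, three_letter = TRUE) {
  ref <- variants$ref_aa
  alt <- variants$alt_aa
  if (three_letter) {
    alt_tok <- ifelse(alt == ref, "=", unname(AA_THREE[alt]))
    paste0("p.", unname(AA_THREE[ref]), variants$position, alt_tok)
  } else {
    alt_tok <- ifelse(alt == ref, "=", alt)
    paste0("p.", ref, variants$position, alt_tok)
  }
}

#' Classify a codon change
#'
#' @param ref_codon,alt_codon 3-nt codons over A/C/G/T. Vectorized.
#' @return `"missense"`, `"nonsense"` or `"synonymous"` per pair. A
#'   reference stop codon is rejected: stop-loss changes are outside the
#'   amino-acid substitution classes the map reports.
#' @examples
#' classify_codon_change("ATG", "ATA")
#' @export
classify_codon_change <- function(ref_codon, alt_codon) {
  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  if (any(ref_aa == "*")) {
    stop("reference codon translates to a stop; stop-loss changes are not classified")
  }
  ifelse(alt_aa == "*", "nonsense",
         ifelse(alt_aa == ref_aa, "synonymous", "missense"))
}

#' Enumerate amino-acid changes reachable by a single-nucleotide variant
#'
#' Every codon of the coding sequence is mutated at each of its three
#' bases to each of the three alternative nucleotides (9 codon neighbours
#' per codon), the mutant codons are translated, and the distinct
#' amino-acid-level changes are returned. Changes at the natural stop
#' codon and stop-loss events are excluded; the initiator Met codon is
#' enumerated like any other.
#'
#' @param cds coding DNA sequence: a single string or character vector of
#'   single bases. Length must be divisible by 3 and the sequence must
#'   start with ATG.
#' @param classes which variant classes to return; defaults to missense
#'   only.
#' @return data.frame of distinct variants (`position`, `ref_aa`,
#'   `alt_aa`, `vclass`, `hgvs_pro`), sorted by position then alternate
#'   residue.
#' @examples
#' nrow(snv_reachable("ATGTGGTAA"))  # Met and Trp codons
#' @export
snv_reachable <- function(cds, classes = "missense") {
  classes <- match.arg(classes, c("missense", "nonsense", "synonymous"),
                       several.ok = TRUE)
  cds <- normalize_cds(cds)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- translate_codons(codons)
  nt <- c("A", "C", "G", "T")
  rows <- vector("list", length(codons))
  for (i in seq_along(codons)) {
    if (aa[i] == "*") next  # natural stop codon: not an amino-acid position
    ref <- strsplit(codons[i], "")[[1]]
    alts <- character(9L)
    k <- 0L
    for (p in 1:3) {
      for (b in setdiff(nt, ref[p])) {
        mut <- ref
        mut[p] <- b
        k <- k + 1L
        alts[k] <- paste(mut, collapse = "")
      }
    }
    alt_aa <- translate_codons(alts)
    keep <- alt_aa != aa[i] | "synonymous" %in% classes
    vclass <- ifelse(alt_aa == "*", "nonsense",
                     ifelse(alt_aa == aa[i], "synonymous", "missense"))
    sel <- vclass %in% classes
    if (!any(sel)) next
    rows[[i]] <- data.frame(position = i, ref_aa = aa[i],
                            alt_aa = alt_aa[sel], vclass = vclass[sel],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character(), vclass = character(),
                      stringsAsFactors = FALSE)
  }
  out <- unique(out)
  out <- out[order(out$position, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out$hgvs_pro <- format_protein_variant(out)
  out
}

# validate and normalize a CDS to a single uppercase string
normalize_cds <- function(cds) {
  if (length(cds) > 1L) cds <- paste(cds, collapse = "")
  cds <- toupper(gsub("\\s", "", cds))
  cds <- gsub("U", "T", cds, fixed = TRUE)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length (", nchar(cds), ") is not divisible by 3")
  }
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT symbols")
  if (substr(cds, 1, 3) != "ATG") stop("CDS does not start with ATG")
  cds
}

#' Read a coding sequence from a single-record FASTA file
#'
#' @param path FASTA file with exactly one record.
#' @return uppercase CDS string, validated by the same rules as
#'   [snv_reachable()].
#' @export
read_cds <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L) stop("expected a single FASTA record in ", path)
    seq <- as.character(set[[1]])
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) != 1L) stop("expected a single FASTA record in ", path)
    seq <- paste(lines[-hdr], collapse = "")
  }
  normalize_cds(seq)
}
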