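#' Filter variant call records by posterior probability
#'
#' Keeps decidable records only. Variant calls must have a posterior
#' strictly above `threshold`; a decidable call failing the threshold is
#' demoted to a wild-type sentinel record (`alt_codon = "="`) so that the
#' read still contributes to effective depth, never to a marginal count.
#'
#' @param calls data.frame with columns `read_id`, `codon_index`,
#'   `alt_codon` (3-nt codon or `"="` for a wild-type call), `posterior`
#'   in `[0, 1]` and logical `decidable`.
#' @param threshold posterior cutoff, strict inequality (default 0.9).
#' @return filtered call records.
#' @export
filter_calls <- function(calls, threshold = 0.9) {
  if (threshold <= 0 || threshold >= 1) {
    stop("config error: posterior threshold must be inside (0, 1)")
  }
  stopifnot(all(c("read_id", "codon_index", "alt_codon", "posterior",
                  "decidable") %in% names(calls)))
  if (any(calls$posterior < 0 | calls$posterior > 1, na.rm = TRUE)) {
    stop("data error: posterior outside [0, 1]")
  }
  out <- calls[calls$decidable, , drop = FALSE]
  fail <- out$alt_codon != "=" & !(out$posterior > threshold)
  out$alt_codon[fail] <- "="
  rownames(out) <- NULL
  out
}

#' Tally marginal counts and effective depths per codon change
#'
#' The marginal count of a codon change is the number of reads carrying
#' that alternate codon, irrespective of co-occurring variants on the
#' same read: a read with calls at two codons contributes to both. The
#' effective depth at a codon is the number of reads whose call at that
#' codon was decidable (wild-type sentinel reads included).
#'
#' @param calls filtered call records from a single
#'   condition/replicate/tile (see [filter_calls()]).
#' @param condition,replicate labels attached to the output rows.
#' @param ref_codons optional named map codon_index -> reference codon.
#' @return data.frame of count records: `condition`, `replicate`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `count`, `depth`. Codons
#'   with zero decidable reads emit no rows.
#' @export
tally_marginal_counts <- function(calls, condition = "pre", replicate = 1L,
                                  ref_codons = NULL) {
  if (nrow(calls) == 0L) {
    return(data.frame(condition = character(), replicate = integer(),
                      codon_index = integer(), ref_codon = character(),
                      alt_codon = character(), count = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(calls$read_id, calls$codon_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(split(calls$alt_codon, key), function(a)
      length(unique(a)) > 1L, TRUE)
    if (any(conflicting)) {
      stop("data error: conflicting calls for the same read and codon: ",
           paste(utils::head(names(conflicting)[conflicting], 3), collapse = "; "))
    }
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  depth <- table(calls$codon_index)
  alt <- calls[calls$alt_codon != "=", , drop = FALSE]
  cnt <- as.data.frame(table(codon_index = alt$codon_index,
                             alt_codon = alt$alt_codon),
                       stringsAsFactors = FALSE)
  cnt <- cnt[cnt$Freq > 0, , drop = FALSE]
  cnt$codon_index <- as.integer(cnt$codon_index)
  out <- data.frame(condition = condition, replicate = as.integer(replicate),
                    codon_index = cnt$codon_index,
                    ref_codon = if (is.null(ref_codons)) NA_character_ else
                      unname(ref_codons[as.character(cnt$codon_index)]),
                    alt_codon = cnt$alt_codon,
                    count = as.integer(cnt$Freq),
                    depth = as.integer(depth[as.character(cnt$codon_index)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$codon_index, out$alt_codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert marginal counts to frequencies
#'
#' @param counts count records with `count` and `depth` columns.
#' @return the input with a `frequency = count / depth` column; rows with
#'   zero depth are dropped with a warning.
#' @export
compute_frequencies <- function(counts) {
  stopifnot(all(c("count", "depth") %in% names(counts)))
  zero <- counts$depth == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero effective depth excluded")
    counts <- counts[!zero, , drop = FALSE]
  }
  counts$frequency <- counts$count / counts$depth
  counts
}
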