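#' The seven BGC product classes
#'
#' Vocabulary of biosynthetic gene cluster classes used throughout:
#' non-ribosomal peptide synthetases, type-I and other polyketide synthases,
#' PKS-NRPS hybrids, terpenes, RiPPs and a catch-all "OTHERS" class.
#' All per-class analyses (distances, clustering, tail fits) partition BGCs
#' by this vocabulary; unknown class labels are rejected at load time.
#'
#' @format Character vector of length 7.
#' @export
BGC_CLASSES <- c("NRPS", "PKSI", "PKSOTHER", "PKS-NRP_HYBRIDS",
                 "TERPENE", "RIPPS", "OTHERS")

#' Default entomopathogenic genus list
#'
#' Genera of the Hypocreales traditionally associated with an
#' insect-pathogenic lifestyle. Used to set the `is_entomopathogen` flag when
#' reading BGC inventories and as the default lifestyle map for exclusivity
#' screening. Supplied as an editable default, not hardcoded truth: every
#' function taking a lifestyle flag accepts records carrying any flag.
#'
#' @return Character vector of genus names.
#' @export
entomopathogen_genera <- function() {
  c("Metarhizium", "Beauveria", "Cordyceps", "Hirsutella",
    "Tolypocladium", "Purpureocillium", "Akanthomyces")
}

#' Construct a list of domain copies
#'
#' A BGC's domain architecture is an ordered list of domain copies, each a
#' domain-family token with an optional residue sequence for copy-level
#' similarity scoring.
#'
#' @param types Character vector of domain-type tokens (ordered, non-empty).
#' @param sequences Optional character vector of per-copy sequences (NA
#'   where absent), recycled length must equal `length(types)`.
#' @return An object of class `domain_copies`: a list with character vectors
#'   `domain_type` and `sequence`.
#' @examples
#' domain_copies(c("KS", "AT", "PP"))
#' @export
domain_copies <- function(types, sequences = NULL) {
  types <- as.character(types)
  if (length(types) == 0L || any(is.na(types)) || any(!nzchar(types)))
    stop("domain types must be a non-empty vector of non-empty tokens")
  if (is.null(sequences)) sequences <- rep(NA_character_, length(types))
  sequences <- as.character(sequences)
  if (length(sequences) != length(types))
    stop("sequences must match types in length")
  structure(list(domain_type = types, sequence = sequences),
            class = "domain_copies")
}

#' @export
print.domain_copies <- function(x, ...) {
  has_seq <- !is.na(x$sequence)
  cat("<domain_copies> ", paste(x$domain_type, collapse = ";"),
      if (any(has_seq)) sprintf("  [%d/%d with sequence]",
                                sum(has_seq), length(has_seq)),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.domain_copies <- function(x) length(x$domain_type)

# Serialize domain copies as "type1;type2:SEQ;type3" (colon-appended
# per-copy sequence, optional).
format_domains <- function(dc) {
  seqs <- dc$sequence
  tok <- ifelse(is.na(seqs) | !nzchar(seqs),
                dc$domain_type,
                paste0(dc$domain_type, ":", seqs))
  paste(tok, collapse = ";")
}

parse_domains <- function(s) {
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(NULL)
  parts <- strsplit(toks, ":", fixed = TRUE)
  types <- vapply(parts, `[[`, character(1), 1L)
  seqs <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else NA_character_,
                 character(1))
  domain_copies(types, seqs)
}
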