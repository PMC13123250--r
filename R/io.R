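#' Build a validated BGC record table
#'
#' The central container of the package: one row per predicted biosynthetic
#' gene cluster, with genome/genus provenance, lifestyle flag, product class
#' and the ordered domain architecture as a list column.
#'
#' @param bgc_id Unique character ids.
#' @param genome_id,genus,species Character provenance columns (`species`
#'   may be omitted).
#' @param bgc_class One of the seven classes in [BGC_CLASSES].
#' @param domains List of [domain_copies()] objects, one per record.
#' @param is_entomopathogen Logical lifestyle flag per record (defaults to
#'   genus membership in [entomopathogen_genera()]).
#' @param has_mibig_hit Logical: does the BGC match a MiBIG entry.
#' @param contig,start,end Optional coordinates (1-based inclusive); carried
#'   through, never computed on.
#' @return A `data.frame` of class `bgc_table` with a `domains` list column.
#' @export
bgc_table <- function(bgc_id, genome_id, genus, bgc_class, domains,
                      species = NA_character_,
                      is_entomopathogen = genus %in% entomopathogen_genera(),
                      has_mibig_hit = FALSE,
                      contig = NA_character_,
                      start = NA_integer_, end = NA_integer_) {
  df <- data.frame(bgc_id = as.character(bgc_id),
                   genome_id = as.character(genome_id),
                   genus = as.character(genus),
                   species = as.character(species),
                   is_entomopathogen = as.logical(is_entomopathogen),
                   bgc_class = as.character(bgc_class),
                   has_mibig_hit = as.logical(has_mibig_hit),
                   contig = as.character(contig),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$domains <- domains
  class(df) <- c("bgc_table", "data.frame")
  validate_bgc_table(df)
}

#' Validate a BGC record table
#'
#' Enforces the record invariants: unique `bgc_id`, non-empty domain lists,
#' class labels from the seven-class vocabulary, `start <= end` where
#' coordinates are present.
#'
#' @param records A `bgc_table`.
#' @return The validated table, invisibly unchanged.
#' @export
validate_bgc_table <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("bgc_id", "genome_id", "genus", "is_entomopathogen",
            "bgc_class", "has_mibig_hit", "domains")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("BGC table is missing required column(s): ",
         paste(miss, collapse = ", "))
  dup <- records$bgc_id[duplicated(records$bgc_id)]
  if (length(dup))
    stop("duplicate bgc_id: ", paste(unique(dup), collapse = ", "))
  bad_class <- setdiff(unique(records$bgc_class), BGC_CLASSES)
  if (length(bad_class))
    stop("unknown bgc_class value(s): ", paste(bad_class, collapse = ", "),
         " (expected one of ", paste(BGC_CLASSES, collapse = ", "), ")")
  empty <- vapply(records$domains, function(d)
    is.null(d) || length(d$domain_type) == 0L, logical(1))
  if (any(empty))
    stop("empty domain list for bgc_id: ",
         paste(records$bgc_id[empty], collapse = ", "))
  if (all(c("start", "end") %in% names(records))) {
    both <- !is.na(records$start) & !is.na(records$end)
    if (any(both & records$start > records$end))
      stop("start > end for bgc_id: ",
           paste(records$bgc_id[both & records$start > records$end],
                 collapse = ", "))
  }
  invisible(records)
}

#' Read a BGC inventory table
#'
#' Tab-separated with a header; one row per BGC. The `domains` column holds
#' the ordered domain tokens joined by `;`, each optionally followed by
#' `:SEQUENCE`. Input order is preserved.
#'
#' @param path Path to the TSV file.
#' @return A validated `bgc_table`.
#' @export
read_bgc_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  need <- c("bgc_id", "genome_id", "genus", "bgc_class", "domains")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("BGC inventory is missing required column(s): ",
         paste(miss, collapse = ", "))
  doms <- lapply(seq_len(nrow(raw)), function(i) {
    d <- parse_domains(raw$domains[i])
    if (is.null(d))
      stop("empty domain field for bgc_id: ", raw$bgc_id[i])
    d
  })
  opt_chr <- function(col, default) {
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  opt_lgl <- function(col, default) {
    if (col %in% names(raw)) as.logical(raw[[col]]) else default
  }
  bgc_table(bgc_id = raw$bgc_id,
            genome_id = raw$genome_id,
            genus = raw$genus,
            species = opt_chr("species", NA_character_),
            bgc_class = raw$bgc_class,
            domains = doms,
            is_entomopathogen =
              if ("is_entomopathogen" %in% names(raw))
                as.logical(raw$is_entomopathogen)
              else raw$genus %in% entomopathogen_genera(),
            has_mibig_hit = opt_lgl("has_mibig_hit", FALSE),
            contig = opt_chr("contig", NA_character_),
            start = suppressWarnings(as.integer(opt_chr("start", NA))),
            end = suppressWarnings(as.integer(opt_chr("end", NA))))
}

#' Write a BGC inventory table
#'
#' Inverse of [read_bgc_table()]: round-trips a validated table to the TSV
#' dialect (domains serialized `type[:SEQ];...`).
#'
#' @param records A `bgc_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bgc_table <- function(records, path) {
  validate_bgc_table(records)
  out <- records[, setdiff(names(records), "domains"), drop = FALSE]
  out$domains <- vapply(records$domains, format_domains, character(1))
  class(out) <- "data.frame"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read genome metadata
#'
#' Tab-separated table with columns `genome_id`, `genus`, `genome_size_mb`
#' and optionally `n_bgcs`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`.
#' @export
read_genome_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("genome_id", "genus", "genome_size_mb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("genome metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$genome_id))
    stop("duplicate genome_id in genome metadata")
  if (any(df$genome_size_mb <= 0))
    stop("genome_size_mb must be positive")
  df
}

#' Read a BiG-SCAPE-style clustering file
#'
#' Two-column tab-separated dialect: BGC name, family number. Comment lines
#' beginning with `#` are tolerated. Rows whose family field is not
#' integer-like are skipped with a warning reporting the count; family
#' labels are kept as opaque strings.
#'
#' @param path Path to the clustering TSV.
#' @return Named character vector mapping `bgc_id` to family label.
#' @export
read_bigscape_clustering <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate a header row naming the columns
  if (length(parts) && !grepl("^-?[0-9]+$", parts[[1]][2]) &&
      grepl("family", parts[[1]][2], ignore.case = TRUE))
    parts <- parts[-1]
  ok <- vapply(parts, function(p)
    length(p) >= 2L && grepl("^-?[0-9]+$", p[2]), logical(1))
  if (any(!ok))
    warning(sum(!ok), " row(s) with non-integer family field skipped")
  parts <- parts[ok]
  setNames(vapply(parts, `[[`, character(1), 2L),
           vapply(parts, `[[`, character(1), 1L))
}

#' Write a clustering mapping in the two-column dialect
#'
#' @param mapping Named character vector (names = bgc ids, values = family
#'   labels), e.g. the per-class mapping of a [assign_gcfs()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bigscape_clustering <- function(mapping, path) {
  # the dialect wants integer family numbers: number distinct labels
  # deterministically (sorted label order); the partition round-trips even
  # though the label strings do not
  lab <- as.integer(factor(unname(mapping), levels = sort(unique(mapping))))
  writeLines(paste(names(mapping), lab, sep = "\t"), path)
  invisible(path)
}
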