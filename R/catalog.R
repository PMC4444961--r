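# Query catalog: mature miRNA sequences -----------------------------------

# Mature miRNAs are ~18-24 nt; bounds padded for edge annotations.
MIRNA_MIN_LEN <- 16L
MIRNA_MAX_LEN <- 30L

#' Load a miRBase-style mature miRNA FASTA file
#'
#' Reads a mature-miRNA FASTA (RNA or DNA alphabet), converts every
#' sequence to uppercase DNA (U is replaced by T), and validates the
#' alphabet and length. The first whitespace-delimited token of each
#' header becomes the record name, so full miRBase headers
#' (`>ame-miR-279c MIMAT0005748 Apis mellifera ...`) are tolerated.
#'
#' Records whose sequence falls outside `[16, 30]` nt are dropped with a
#' warning; the dropped names are attached as `attr(x, "rejected")`.
#' Characters outside the RNA/DNA alphabet are an error, because a
#' malformed query would silently poison every downstream presence call.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with one row per retained mature miRNA and
#'   columns `name`, `species_prefix`, `family`, `sequence`
#'   (uppercase DNA), and `source_ids`.
#' @seealso [dedup_catalog()], [assign_family()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">ame-miR-279c MIMAT0005748", "UGACUAGAUCCACACUCAUCC"), fa)
#' load_mature_fasta(fa)
#' @export
load_mature_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read mature FASTA file: ", path)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    out <- empty_catalog_entries()
    attr(out, "rejected") <- character(0)
    return(out)
  }
  ids <- sub("\\s.*$", "", names(recs))
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty header in ", path)
  }
  seqs <- toupper(as.character(recs))
  bad <- grepl("[^ACGUT]", seqs)
  if (any(bad)) {
    stop("invalid characters (outside A/C/G/U/T) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  seqs <- chartr("U", "T", seqs)
  len <- nchar(seqs)
  keep <- len >= MIRNA_MIN_LEN & len <= MIRNA_MAX_LEN
  rejected <- ids[!keep]
  if (length(rejected)) {
    warning("dropped ", length(rejected), " record(s) with length outside [",
            MIRNA_MIN_LEN, ", ", MIRNA_MAX_LEN, "]: ",
            paste(rejected, collapse = ", "))
  }
  ids <- ids[keep]
  seqs <- seqs[keep]
  out <- data.frame(
    name = ids,
    species_prefix = species_prefix(ids),
    family = vapply(ids, assign_family, character(1), USE.NAMES = FALSE),
    sequence = unname(seqs),
    source_ids = ids,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

empty_catalog_entries <- function() {
  data.frame(name = character(0), species_prefix = character(0),
             family = character(0), sequence = character(0),
             source_ids = character(0), stringsAsFactors = FALSE)
}

species_prefix <- function(name) {
  # miRBase species prefixes are lowercase (ame, nvi, dme, ...)
  pref <- sub("^([a-z]{3,4})-.*$", "\\1", name)
  pref[pref == name] <- NA_character_
  pref
}

#' Derive the miRNA family from a canonical miRNA name
#'
#' Strips the species prefix, the arm suffix (`-5p`/`-3p`), trailing
#' paralog letters, and duplicate-locus numerals, following miRBase
#' naming conventions: `ame-miR-279c` and `ame-miR-279d` both map to
#' family `miR-279`; `dme-miR-13b-3p` maps to `miR-13`; `let-7`-,
#' `lin-4`- and `bantam`-style names pass through with the prefix
#' stripped. Unrecognized name dialects are an error rather than a
#' silent mis-grouping.
#'
#' @param name A single miRNA name, e.g. `"ame-miR-279c"`.
#' @return The family string, e.g. `"miR-279"`.
#' @export
assign_family <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  core <- sub("^[a-z]{3,4}-", "", name)
  if (identical(core, name)) {
    stop("cannot parse miRNA name (missing species prefix): ", name)
  }
  if (grepl("^bantam$", core, ignore.case = TRUE)) {
    return("bantam")
  }
  m <- regmatches(core,
    regexec("^(miR|mir|let|lin)-([0-9]+)([a-z]*)(-[0-9]+)?(-(5p|3p))?$",
            core))[[1]]
  if (length(m) == 0L) {
    stop("unrecognized miRNA name dialect: ", name)
  }
  stem <- m[2]
  if (stem == "mir") stem <- "miR"
  paste0(stem, "-", m[3])
}

#' Collapse identical mature sequences into a deduplicated catalog
#'
#' Entries with byte-identical sequences (e.g. a mature conserved across
#' the source species, or identical matures from paralogous loci) are
#' merged into a single query. The canonical name is taken from the
#' highest-precedence source species; all merged record IDs are kept in
#' `source_ids`. Genomic multiplicity is recovered later from hit
#' counts, not by duplicating queries.
#'
#' @param entries Catalog entries as returned by [load_mature_fasta()]
#'   (possibly concatenated across several source species).
#' @param precedence Ordered character vector of species prefixes; the
#'   first listed prefix wins the canonical name. Every prefix present
#'   in `entries` must be listed.
#' @return A `mirna_catalog`: a data.frame of unique-sequence entries,
#'   ordered by canonical name.
#' @export
dedup_catalog <- function(entries, precedence = c("ame", "nvi", "dme")) {
  stopifnot(is.data.frame(entries))
  if (nrow(entries) == 0L) {
    return(as_mirna_catalog(empty_catalog_entries()))
  }
  prefs <- unique(entries$species_prefix)
  missing <- setdiff(prefs, precedence)
  if (length(missing) || anyNA(prefs)) {
    stop("species prefix(es) absent from precedence list: ",
         paste(missing[!is.na(missing)], collapse = ", "))
  }
  rank <- match(entries$species_prefix, precedence)
  ord <- order(rank, entries$name)
  e <- entries[ord, , drop = FALSE]
  groups <- split(seq_len(nrow(e)), e$sequence)
  rep_idx <- vapply(groups, `[[`, integer(1), 1L)
  merged <- e[rep_idx, , drop = FALSE]
  merged$source_ids <- vapply(groups, function(i) {
    paste(sort(unique(unlist(strsplit(e$source_ids[i], ";", fixed = TRUE)))),
          collapse = ";")
  }, character(1))
  merged <- merged[order(merged$name), , drop = FALSE]
  rownames(merged) <- NULL
  as_mirna_catalog(merged)
}

as_mirna_catalog <- function(df) {
  if (anyDuplicated(df$name)) {
    stop("catalog name collision after deduplication: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  if (anyDuplicated(df$sequence)) {
    stop("catalog contains duplicated sequences; run dedup_catalog()")
  }
  class(df) <- c("mirna_catalog", "data.frame")
  df
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat("miRNA catalog:", nrow(x), "unique mature sequences,",
      length(unique(x$family)), "families\n")
  NextMethod()
}

#' Look up catalog entries by name or family
#'
#' @param catalog A `mirna_catalog`.
#' @param name,family Values to select.
#' @return The matching catalog rows.
#' @export
catalog_by_name <- function(catalog, name) {
  catalog[catalog$name %in% name, , drop = FALSE]
}

#' @rdname catalog_by_name
#' @export
catalog_by_family <- function(catalog, family) {
  catalog[catalog$family %in% family, , drop = FALSE]
}

#' Write a catalog to TSV
#'
#' @param catalog A `mirna_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write catalog sequences as a DNA FASTA file
#'
#' @param catalog A `mirna_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  s <- Biostrings::DNAStringSet(catalog$sequence)
  names(s) <- catalog$name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
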