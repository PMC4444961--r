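# Strand-aware exact multi-pattern genome scan ----------------------------

#' Construct a genome record
#'
#' @param genome_id Species key; must match a tree leaf / panel column.
#' @param contigs Named character vector or `DNAStringSet` of contig
#'   sequences. Soft-masked (lowercase) sequence is uppercased: masking
#'   in assemblies marks repeats, not absence.
#' @param metadata Optional list (species name, panel tag, trait key).
#' @return A `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, metadata = list()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(toupper(contigs))
  }
  if (!inherits(contigs, "DNAStringSet")) {
    stop("contigs must be a named character vector or DNAStringSet")
  }
  if (length(contigs) > 0 &&
      (is.null(names(contigs)) || any(!nzchar(names(contigs))))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig ids in genome ", genome_id)
  }
  structure(list(genome_id = genome_id, contigs = contigs,
                 metadata = metadata),
            class = "genome_record")
}

#' Read a genome assembly FASTA into a genome record
#'
#' Accepts multi-contig, optionally gzip-compressed FASTA. Contig ids
#' are the first whitespace-delimited header token.
#'
#' @inheritParams genome_record
#' @param path Path to the FASTA file.
#' @return A `genome_record`.
#' @export
read_genome_fasta <- function(path, genome_id, metadata = list()) {
  if (!file.exists(path)) stop("cannot read genome FASTA: ", path)
  contigs <- Biostrings::readDNAStringSet(path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  genome_record(genome_id, contigs, metadata)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record", x$genome_id, ":", length(x$contigs), "contig(s),",
      sum(Biostrings::width(x$contigs)), "nt\n")
  invisible(x)
}

#' Scan a genome for all occurrences of every catalog sequence
#'
#' Searches both strands of every contig for every mature-miRNA query,
#' reporting each occurrence (including overlapping and self-overlapping
#' ones). The default `max_mismatches = 0` is the presence criterion of
#' the analysis: a miRNA counts as present only on a full-length exact
#' match. A small mismatch tolerance is available for sensitivity
#' analyses; positions carrying ambiguity codes (N etc.) never
#' participate in a hit, even when nominally compatible.
#'
#' Matching is delegated to `Biostrings::vmatchPattern`, which is exact
#' string search at C speed; minus-strand hits are found by searching
#' the reverse complement of the query and are reported in forward
#' contig coordinates.
#'
#' @param catalog A non-empty `mirna_catalog`.
#' @param genome A `genome_record`.
#' @param max_mismatches Maximum substitutions allowed (default 0).
#' @return A `hit_records` data.frame with columns `mirna_name`,
#'   `genome_id`, `contig_id`, `start` (0-based), `end` (exclusive),
#'   `strand` (`+`/`-`), and `matched_sequence` (forward-strand contig
#'   substring), sorted by (genome_id, contig_id, start, strand, name).
#' @export
scan_genome <- function(catalog, genome, max_mismatches = 0L) {
  stopifnot(inherits(genome, "genome_record"))
  if (!is.data.frame(catalog) || nrow(catalog) == 0L) {
    stop("catalog is empty; nothing to scan for")
  }
  if (length(genome$contigs) == 0L) {
    stop("genome ", genome$genome_id, " has zero contigs")
  }
  max_mismatches <- as.integer(max_mismatches)
  stopifnot(length(max_mismatches) == 1L, max_mismatches >= 0L)
  qlen <- nchar(catalog$sequence)
  if (max_mismatches >= min(qlen)) {
    stop("max_mismatches (", max_mismatches,
         ") must be smaller than the shortest query (", min(qlen), " nt)")
  }
  subjects <- genome$contigs
  contig_chr <- as.character(subjects)
  rows <- list()
  k <- 0L
  emit <- function(i, j, starts, strand, w) {
    if (length(starts) == 0L) return()
    matched <- substring(contig_chr[j], starts, starts + w - 1L)
    if (max_mismatches > 0L) {
      ok <- !grepl("[^ACGT]", matched)
      starts <- starts[ok]
      matched <- matched[ok]
      if (length(starts) == 0L) return()
    }
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      mirna_name = catalog$name[i],
      genome_id = genome$genome_id,
      contig_id = names(subjects)[j],
      start = starts - 1L,
      end = starts - 1L + w,
      strand = strand,
      matched_sequence = matched,
      stringsAsFactors = FALSE
    )
  }
  # a preprocessed pattern dictionary pays off on large catalog x genome
  # workloads; small scans go through plain per-query matching
  work <- as.double(nrow(catalog)) * sum(nchar(contig_chr))
  if (max_mismatches == 0L && work >= 5e5) {
    pd <- catalog_pdict(catalog)
    for (j in seq_along(subjects)) {
      st <- Biostrings::startIndex(Biostrings::matchPDict(pd$pdict,
                                                          subjects[[j]]))
      for (p in which(lengths(st) > 0L)) {
        emit(pd$query[p], j, st[[p]], pd$strand[p], pd$width[p])
      }
    }
  } else {
    for (i in seq_len(nrow(catalog))) {
      q <- catalog$sequence[i]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") q else revcomp_chr(q)
        m <- Biostrings::vmatchPattern(pat, subjects,
                                       max.mismatch = max_mismatches,
                                       fixed = TRUE)
        st <- Biostrings::startIndex(m)
        w <- nchar(pat)
        for (j in seq_along(subjects)) {
          starts <- st[[j]]
          if (is.null(starts)) next
          # vmatchPattern can report out-of-bounds starts at high
          # max.mismatch; keep fully contained matches only.
          starts <- starts[starts >= 1L &
                             starts + w - 1L <= nchar(contig_chr[j])]
          emit(i, j, starts, strand, w)
        }
      }
    }
  }
  hits <- if (k == 0L) empty_hits() else do.call(rbind, rows[seq_len(k)])
  hits <- hits[order(hits$genome_id, hits$contig_id, hits$start,
                     hits$strand, hits$mirna_name), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("hit_records", "data.frame")
  hits
}

# Both-strand Biostrings pattern dictionary for a catalog, cached on
# the catalog object's environment-free attributes via a local memo.
catalog_pdict <- local({
  cache_key <- NULL
  cache_val <- NULL
  function(catalog) {
    key <- paste(catalog$name, catalog$sequence, collapse = "\r")
    if (identical(key, cache_key)) return(cache_val)
    fwd <- Biostrings::DNAStringSet(catalog$sequence)
    rc <- Biostrings::reverseComplement(fwd)
    pats <- c(fwd, rc)
    val <- list(
      pdict = Biostrings::PDict(pats, tb.start = 1,
                                tb.width = min(Biostrings::width(pats))),
      query = rep(seq_len(nrow(catalog)), 2L),
      strand = rep(c("+", "-"), each = nrow(catalog)),
      width = rep(nchar(catalog$sequence), 2L)
    )
    cache_key <<- key
    cache_val <<- val
    val
  }
})

empty_hits <- function() {
  data.frame(mirna_name = character(0), genome_id = character(0),
             contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), matched_sequence = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a panel of genomes
#'
#' @param catalog A `mirna_catalog`.
#' @param panel List of `genome_record` objects.
#' @inheritParams scan_genome
#' @return Combined `hit_records` across the panel.
#' @export
scan_panel <- function(catalog, panel, max_mismatches = 0L) {
  hits <- lapply(panel, function(g) scan_genome(catalog, g, max_mismatches))
  out <- do.call(rbind, c(list(empty_hits()), hits))
  rownames(out) <- NULL
  class(out) <- c("hit_records", "data.frame")
  out
}

#' Reverse-complement a DNA string
#'
#' @param x A character vector of DNA strings.
#' @return The reverse complement of each element.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# plain-character reverse complement (ACGT only), cheaper than round-
# tripping through an XString for short queries
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Binarize hits into a presence/absence matrix
#'
#' A miRNA is scored present in a genome iff it has at least one hit
#' there; per-cell hit counts are retained as provenance.
#'
#' @param hits `hit_records` from [scan_genome()]/[scan_panel()].
#' @param catalog The `mirna_catalog` that produced the hits.
#' @param panel List of `genome_record` objects, or a character vector
#'   of genome ids, defining the matrix columns.
#' @param panel_tag Tag stored on the matrix.
#' @return A [pa_matrix()] over catalog rows and panel columns.
#' @export
call_presence <- function(hits, catalog, panel, panel_tag = "panel") {
  gids <- if (is.character(panel)) panel else
    vapply(panel, function(g) g$genome_id, character(1))
  if (anyDuplicated(gids)) stop("duplicate genome ids in panel")
  unknown_m <- setdiff(unique(hits$mirna_name), catalog$name)
  if (length(unknown_m)) {
    stop("hits reference miRNAs not in the catalog: ",
         paste(unknown_m, collapse = ", "))
  }
  unknown_g <- setdiff(unique(hits$genome_id), gids)
  if (length(unknown_g)) {
    stop("hits reference genomes not in the panel: ",
         paste(unknown_g, collapse = ", "))
  }
  counts <- matrix(0L, nrow = nrow(catalog), ncol = length(gids),
                   dimnames = list(catalog$name, gids))
  if (nrow(hits) > 0L) {
    tab <- table(factor(hits$mirna_name, levels = catalog$name),
                 factor(hits$genome_id, levels = gids))
    counts[] <- as.integer(tab)
  }
  pa_matrix((counts > 0L) * 1L, counts = counts, panel_tag = panel_tag)
}

#' Write hits as BED6 plus a detail TSV
#'
#' BED columns: contig, start, end, miRNA name, score 0, strand. The
#' companion TSV additionally carries `genome_id` and
#' `matched_sequence`.
#'
#' @param hits `hit_records`.
#' @param bed_path Output BED path.
#' @param tsv_path Optional detail TSV path.
#' @return `bed_path`, invisibly.
#' @export
write_hits_bed <- function(hits, bed_path, tsv_path = NULL) {
  bed <- data.frame(hits$contig_id, hits$start, hits$end,
                    hits$mirna_name, 0L, hits$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(hits), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(bed_path)
}

#' Write a genome record to FASTA
#'
#' @param genome A `genome_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$contigs, path)
  invisible(path)
}
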