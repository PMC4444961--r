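# Trait-association and clade-specificity screens -------------------------

#' Canonical trait labels for a genome panel
#'
#' Maps the field vocabulary (`eusocial` / `solitary` / `facultative`)
#' onto the canonical screen labels `positive` / `negative` /
#' `neutral`. A facultatively social species is deliberately neutral:
#' its presences neither qualify nor disqualify a candidate, because a
#' gene retained in a species with both social and solitary
#' populations is informative about neither state.
#'
#' @param x Named character vector (names = genome ids) with values in
#'   `eusocial`/`solitary`/`facultative` or already-canonical
#'   `positive`/`negative`/`neutral`.
#' @return Named character vector of canonical labels.
#' @export
trait_labels <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)), all(nzchar(names(x))))
  map <- c(eusocial = "positive", solitary = "negative",
           facultative = "neutral",
           positive = "positive", negative = "negative", neutral = "neutral")
  out <- map[tolower(x)]
  if (anyNA(out)) {
    stop("unrecognized trait label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  names(out) <- names(x)
  out
}

#' Read a trait-label TSV
#'
#' Expected columns: `genome_id`, `label` (eusocial/solitary/
#' facultative).
#'
#' @param path TSV path.
#' @return Canonical named label vector (see [trait_labels()]).
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("genome_id", "label") %in% names(df)))
  trait_labels(stats::setNames(df$label, df$genome_id))
}

check_labels_cover <- function(m, labels) {
  unlabeled <- setdiff(colnames(m$values), names(labels))
  if (length(unlabeled)) {
    stop("matrix column(s) without a trait label: ",
         paste(unlabeled, collapse = ", "))
  }
  labels[colnames(m$values)]
}

candidate_report <- function(m, keep, category) {
  nms <- rownames(m$values)[keep]
  data.frame(
    mirna_name = nms,
    category = rep(category, length(nms)),
    n_present = unname(rowSums(m$values[keep, , drop = FALSE])),
    present_in = vapply(nms, function(nm) {
      paste(colnames(m$values)[m$values[nm, ] == 1L], collapse = ";")
    }, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Screen for trait-exclusive miRNAs
#'
#' Returns rows present in at least `min_positive` trait-positive
#' genomes and in zero trait-negative genomes. Presence in
#' neutral-labeled (facultative) genomes neither qualifies nor
#' disqualifies.
#'
#' @param m A `pa_matrix`.
#' @param labels Canonical labels covering every column (see
#'   [trait_labels()]).
#' @param min_positive Minimum presences among positive genomes.
#' @return A candidate-report data.frame (`mirna_name`, `category`,
#'   `n_present`, `present_in`).
#' @export
trait_exclusive <- function(m, labels, min_positive = 1L) {
  stopifnot(inherits(m, "pa_matrix"))
  lab <- check_labels_cover(m, labels)
  v <- m$values
  pos <- names(lab)[lab == "positive"]
  neg <- names(lab)[lab == "negative"]
  keep <- rowSums(v[, neg, drop = FALSE]) == 0L &
    rowSums(v[, pos, drop = FALSE]) >= min_positive
  candidate_report(m, which(keep), "trait_exclusive")
}

#' Screen for clade-exclusive miRNAs
#'
#' Rows absent from every genome outside the clade and present in at
#' least `min_inside` genomes inside it.
#'
#' @param m A `pa_matrix`.
#' @param tree Tree with the clade bound via [bind_clades()].
#' @param clade Clade handle name.
#' @param min_inside Minimum presences inside the clade.
#' @return A candidate-report data.frame.
#' @export
clade_exclusive <- function(m, tree, clade, min_inside = 1L) {
  stopifnot(inherits(m, "pa_matrix"))
  members <- clade_leaves(tree, clade)
  outside_panel <- setdiff(members, colnames(m$values))
  if (length(outside_panel)) {
    stop("clade ", clade, " member(s) missing from the matrix: ",
         paste(outside_panel, collapse = ", "))
  }
  v <- m$values
  outside <- setdiff(colnames(v), members)
  keep <- rowSums(v[, outside, drop = FALSE]) == 0L &
    rowSums(v[, members, drop = FALSE]) >= min_inside
  candidate_report(m, which(keep), paste0("clade_exclusive(", clade, ")"))
}

#' Screen for clade-universal miRNAs
#'
#' Rows present in at least `|clade| - tolerance` clade genomes and
#' absent from every genome outside the clade — the criterion for a
#' gene already fixed in the clade's common ancestor. `tolerance`
#' forgives assembly false negatives in up to that many members.
#'
#' @inheritParams clade_exclusive
#' @param tolerance Number of clade members allowed to lack the gene.
#' @return A candidate-report data.frame.
#' @export
clade_universal <- function(m, tree, clade, tolerance = 0L) {
  stopifnot(inherits(m, "pa_matrix"))
  members <- clade_leaves(tree, clade)
  if (tolerance >= length(members)) {
    stop("tolerance (", tolerance, ") must be smaller than the clade size (",
         length(members), ")")
  }
  outside_panel <- setdiff(members, colnames(m$values))
  if (length(outside_panel)) {
    stop("clade ", clade, " member(s) missing from the matrix: ",
         paste(outside_panel, collapse = ", "))
  }
  v <- m$values
  outside <- setdiff(colnames(v), members)
  keep <- rowSums(v[, outside, drop = FALSE]) == 0L &
    rowSums(v[, members, drop = FALSE]) >= length(members) - tolerance
  candidate_report(m, which(keep), paste0("clade_universal(", clade, ")"))
}

#' Parsimony convergence summary per miRNA
#'
#' For every matrix row, reports the minimum number of independent
#' gains (weighted parsimony, root prior absent), how many inferred
#' gain branches lead to subtrees whose labeled leaves are all
#' positive-or-neutral (gains "in positive lineages"), and the loss
#' count — a descriptive summary of phylogeny-independent association
#' with the trait, not a significance test.
#'
#' Gain branches are taken from the Fitch reconstruction's event list
#' (delayed-transformation tie-breaking), while `independent_gains` is
#' the tie-break-independent minimum.
#'
#' @param m A `pa_matrix`.
#' @param tree Rooted tree over the matrix columns.
#' @param labels Canonical trait labels covering every column.
#' @return A data.frame (`mirna_name`, `independent_gains`,
#'   `gains_in_positive_lineages`, `losses`), sorted by
#'   `gains_in_positive_lineages` decreasing.
#' @export
convergence_summary <- function(m, tree, labels) {
  stopifnot(inherits(m, "pa_matrix"))
  lab <- check_labels_cover(m, labels)
  rows <- lapply(rownames(m$values), function(nm) {
    ch <- m$values[nm, ]
    fit <- fitch_min_changes(tree, ch, mirna_name = nm)
    gains_ev <- fit$events[fit$events$type == "gain", , drop = FALSE]
    gip <- 0L
    if (nrow(gains_ev)) {
      gip <- sum(vapply(gains_ev$child_leaves, function(ls) {
        leaves <- strsplit(ls, ";", fixed = TRUE)[[1]]
        all(lab[leaves] %in% c("positive", "neutral"))
      }, logical(1)))
    }
    data.frame(mirna_name = nm,
               independent_gains = count_independent_gains(tree, ch),
               gains_in_positive_lineages = gip,
               losses = fit$n_losses,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$gains_in_positive_lineages, out$mirna_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
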