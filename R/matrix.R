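# Presence/absence profile matrix -----------------------------------------

#' Construct a presence/absence matrix
#'
#' The central object of the analysis: a complete binary miRNA-by-genome
#' grid, optionally carrying per-cell hit counts as provenance.
#'
#' @param values Integer/logical matrix with miRNA row names and genome
#'   column names; entries coerced to 0/1, no missing cells allowed.
#' @param counts Optional hit-count matrix with identical dimnames.
#' @param panel_tag Free-text tag identifying the panel.
#' @return A `pa_matrix` object.
#' @export
pa_matrix <- function(values, counts = NULL, panel_tag = "panel") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("presence matrix has missing cells")
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L))) stop("presence values must be 0 or 1")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("presence matrix needs miRNA row names and genome column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate miRNA row names")
  if (anyDuplicated(colnames(values))) stop("duplicate genome column names")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (!identical(dimnames(counts), dimnames(values))) {
      stop("counts dimnames must match values")
    }
    if (!all((counts > 0L) == (values == 1L))) {
      stop("counts provenance inconsistent with presence values")
    }
  }
  structure(list(values = values, counts = counts, panel_tag = panel_tag),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("pa_matrix [%s]: %d miRNAs x %d genomes, %.1f%% present\n",
              x$panel_tag, nrow(v), ncol(v), 100 * mean(v)))
  invisible(x)
}

#' @export
dim.pa_matrix <- function(x) dim(x$values)

#' Row and column names of a pa_matrix
#' @param m A `pa_matrix`.
#' @return Character vector of names.
#' @export
pa_mirnas <- function(m) rownames(m$values)

#' @rdname pa_mirnas
#' @export
pa_genomes <- function(m) colnames(m$values)

subset_pa <- function(m, rows = NULL, cols = NULL) {
  v <- m$values
  ct <- m$counts
  if (!is.null(rows)) {
    v <- v[rows, , drop = FALSE]
    if (!is.null(ct)) ct <- ct[rows, , drop = FALSE]
  }
  if (!is.null(cols)) {
    v <- v[, cols, drop = FALSE]
    if (!is.null(ct)) ct <- ct[, cols, drop = FALSE]
  }
  pa_matrix(v, counts = ct, panel_tag = m$panel_tag)
}

#' Drop phylogenetically uninformative rows
#'
#' Removes miRNAs present in every genome of the panel and miRNAs
#' present in at most one genome; neither pattern can distinguish
#' hypotheses about where on the tree the gene came or went. Retained
#' rows keep their original relative order, and the column set is
#' unchanged. Applied per panel: a row uninformative on one panel may
#' be informative on another.
#'
#' @param m A `pa_matrix` with at least two columns.
#' @return The filtered `pa_matrix` (possibly with zero rows).
#' @export
filter_informative <- function(m) {
  stopifnot(inherits(m, "pa_matrix"))
  if (ncol(m$values) < 2L) stop("informativeness filter needs >= 2 genomes")
  rs <- rowSums(m$values)
  keep <- rs >= 2L & rs < ncol(m$values)
  subset_pa(m, rows = which(keep))
}

#' Order a matrix along the species tree
#'
#' Columns are permuted to the tree's left-to-right leaf order; rows are
#' then sorted lexicographically by their presence pattern read in that
#' column order (ties broken by miRNA name). This is the deterministic
#' stand-in for "clustering by phylogeny": the species axis is fixed to
#' the tree rather than produced by a distance method.
#'
#' @param m A `pa_matrix` whose columns are exactly the tree's leaves.
#' @param tree A rooted `phylo` tree.
#' @return The reordered `pa_matrix`.
#' @export
order_by_tree <- function(m, tree) {
  stopifnot(inherits(m, "pa_matrix"), inherits(tree, "phylo"))
  leaves <- tree_leaf_order(tree)
  extra_cols <- setdiff(colnames(m$values), leaves)
  extra_leaves <- setdiff(leaves, colnames(m$values))
  if (length(extra_cols) || length(extra_leaves)) {
    stop("matrix columns and tree leaves differ; only in matrix: {",
         paste(extra_cols, collapse = ", "), "}; only in tree: {",
         paste(extra_leaves, collapse = ", "), "}")
  }
  out <- subset_pa(m, cols = leaves)
  pattern <- apply(out$values, 1L, paste, collapse = "")
  ord <- order(pattern, rownames(out$values), method = "radix")
  subset_pa(out, rows = ord)
}

#' Restrict a matrix to a sub-panel of genomes
#'
#' @param m A `pa_matrix`.
#' @param genome_ids Columns to keep (must all exist).
#' @param panel_tag Optional new panel tag.
#' @return The column-subset `pa_matrix`; rows unchanged.
#' @export
restrict_panel <- function(m, genome_ids, panel_tag = NULL) {
  stopifnot(inherits(m, "pa_matrix"))
  unknown <- setdiff(genome_ids, colnames(m$values))
  if (length(unknown)) {
    stop("unknown genome id(s): ", paste(unknown, collapse = ", "))
  }
  out <- subset_pa(m, cols = genome_ids)
  if (!is.null(panel_tag)) out$panel_tag <- panel_tag
  out
}

#' Read/write a presence matrix as TSV
#'
#' Rows are miRNAs, columns genomes, values 0/1; the first column
#' (`mirna`) holds row names.
#'
#' @param m A `pa_matrix`.
#' @param path File path.
#' @param panel_tag Tag for the matrix read back.
#' @return `write_pa_tsv`: `path`, invisibly. `read_pa_tsv`: a
#'   `pa_matrix`.
#' @export
write_pa_tsv <- function(m, path) {
  df <- data.frame(mirna = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pa_tsv
#' @export
read_pa_tsv <- function(path, panel_tag = "panel") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  pa_matrix(v, panel_tag = panel_tag)
}

#' Render a presence/absence heatmap
#'
#' Present cells are drawn yellow, absent cells blue; genome labels of
#' trait-positive species are colored red and framed row groups can
#' highlight candidate sets (black frames for trait-exclusive rows, red
#' for clade-specific rows).
#'
#' @param m A `pa_matrix` (typically tree-ordered).
#' @param labels Optional canonical trait labels (see [trait_labels()]);
#'   positive genomes get red column labels.
#' @param frame_black,frame_red Optional character vectors of miRNA row
#'   names to frame.
#' @param file Optional PNG or SVG path; if `NULL`, draws on the active
#'   device.
#' @param main Plot title.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_pa_heatmap <- function(m, labels = NULL, frame_black = character(0),
                            frame_red = character(0), file = NULL,
                            main = m$panel_tag) {
  v <- m$values
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 200 + 26 * ncol(v),
                                height = 200 + 16 * nrow(v), res = 96),
           svg = grDevices::svg(file, width = 2 + 0.28 * ncol(v),
                                height = 2 + 0.18 * nrow(v)),
           stop("unsupported heatmap format: ", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(9, 7, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  nr <- nrow(v)
  # image() draws row 1 at the bottom; flip so matrix row 1 is on top
  z <- t(v[rev(seq_len(nr)), , drop = FALSE])
  graphics::image(x = seq_len(ncol(v)), y = seq_len(nr), z = z,
                  col = c("#27408B", "#FFD700"), zlim = c(0, 1),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  col_cols <- rep("black", ncol(v))
  if (!is.null(labels)) {
    col_cols[labels[colnames(v)] == "positive"] <- "red"
  }
  graphics::mtext(colnames(v), side = 1, at = seq_len(ncol(v)), las = 2,
                  cex = 0.6, col = col_cols, line = 0.4)
  graphics::mtext(rev(rownames(v)), side = 2, at = seq_len(nr), las = 2,
                  cex = 0.6, line = 0.4)
  frame_rows <- function(nms, border) {
    for (nm in intersect(nms, rownames(v))) {
      y <- nr - match(nm, rownames(v)) + 1L
      graphics::rect(0.5, y - 0.5, ncol(v) + 0.5, y + 0.5,
                     border = border, lwd = 2)
    }
  }
  frame_rows(frame_black, "black")
  frame_rows(frame_red, "red")
  invisible(file)
}
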