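# Synthetic data: presence evolution, catalogs, genomes -------------------

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic panel
#' generator. Rates are per unit branch length of the supplied tree;
#' `fn_rate` models the assembly-gap false negative: the probability
#' that a truly encoded miRNA is omitted from a genome (applied per
#' miRNA-genome cell, the level at which incomplete assemblies bite).
#'
#' @param tree Rooted `phylo` with branch lengths (required whenever a
#'   rate is positive).
#' @param n_mirnas Number of simulated miRNA characters.
#' @param gain_rate,loss_rate Per-unit-length gain (0 to 1) and loss
#'   (1 to 0) rates of the two-state Markov process.
#' @param root_presence_prob Probability a character is present at the
#'   root.
#' @param genome_length Background genome length in nt (>= 10x the
#'   longest query).
#' @param gc_content Background GC fraction.
#' @param fn_rate Per-cell false-negative probability.
#' @param seed Integer seed; mandatory, no hidden global randomness.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(tree, n_mirnas = 50L, gain_rate = 0.1,
                              loss_rate = 0.3, root_presence_prob = 0.5,
                              genome_length = 200000L, gc_content = 0.35,
                              fn_rate = 0, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (missing(seed)) stop("a seed is mandatory in the simulation config")
  stopifnot(gain_rate >= 0, loss_rate >= 0,
            root_presence_prob >= 0, root_presence_prob <= 1,
            fn_rate >= 0, fn_rate <= 1,
            gc_content > 0, gc_content < 1,
            n_mirnas >= 1L, genome_length >= 10L * MIRNA_MAX_LEN)
  if ((gain_rate > 0 || loss_rate > 0) && is.null(tree$edge.length)) {
    stop("tree has no branch lengths but rates are positive")
  }
  structure(list(tree = tree, n_mirnas = as.integer(n_mirnas),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 root_presence_prob = root_presence_prob,
                 genome_length = as.integer(genome_length),
                 gc_content = gc_content, fn_rate = fn_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Closed-form transition probabilities of the 2-state CTMC over time t.
two_state_transition <- function(gain_rate, loss_rate, t) {
  tot <- gain_rate + loss_rate
  if (tot == 0) {
    return(list(p01 = rep(0, length(t)), p10 = rep(0, length(t))))
  }
  decay <- exp(-tot * t)
  list(p01 = (gain_rate / tot) * (1 - decay),
       p10 = (loss_rate / tot) * (1 - decay))
}

#' Simulate presence/absence evolution on the tree
#'
#' For each miRNA character the root state is drawn with
#' `root_presence_prob`, then a two-state continuous-time gain/loss
#' Markov process runs down every branch, with transition
#' probabilities from the closed form of the 2-state chain at the
#' branch length. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A `sim_truth` list: `true_matrix` (a [pa_matrix()] over
#'   simulated miRNAs x tree leaves), `event_log` (one row per branch
#'   state change), `node_states`, and the `config`.
#' @export
simulate_presence_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  cl <- stats::reorder(tree, "cladewise")  # parents before children
  elen <- if (is.null(cl$edge.length)) rep(0, nrow(cl$edge)) else cl$edge.length
  mirnas <- sprintf("sim-miR-%03d", seq_len(config$n_mirnas))
  states <- matrix(0L, n, config$n_mirnas)
  states[root, ] <- stats::rbinom(config$n_mirnas, 1L,
                                  config$root_presence_prob)
  events <- vector("list", nrow(cl$edge))
  for (e in seq_len(nrow(cl$edge))) {
    p <- cl$edge[e, 1]; ch <- cl$edge[e, 2]
    tp <- two_state_transition(config$gain_rate, config$loss_rate, elen[e])
    ps <- states[p, ]
    flip_prob <- ifelse(ps == 0L, tp$p01, tp$p10)
    flip <- stats::runif(config$n_mirnas) < flip_prob
    states[ch, ] <- ifelse(flip, 1L - ps, ps)
    if (any(flip)) {
      events[[e]] <- data.frame(
        mirna = mirnas[flip],
        parent = node_label(tree, p),
        child = node_label(tree, ch),
        type = ifelse(ps[flip] == 0L, "gain", "loss"),
        stringsAsFactors = FALSE
      )
    }
  }
  event_log <- do.call(rbind, c(list(data.frame(mirna = character(0),
                                                parent = character(0),
                                                child = character(0),
                                                type = character(0),
                                                stringsAsFactors = FALSE)),
                                events[!vapply(events, is.null, logical(1))]))
  tip_states <- t(states[seq_len(ntip), , drop = FALSE])
  dimnames(tip_states) <- list(mirnas, tree$tip.label)
  rownames(event_log) <- NULL
  structure(list(true_matrix = pa_matrix(tip_states, panel_tag = "simulated"),
                 event_log = event_log,
                 node_states = states, config = config),
            class = "sim_truth")
}

#' Generate a random (collision-checked) mature miRNA catalog
#'
#' One fixed random DNA sequence (20-24 nt, uniform base composition)
#' per simulated miRNA. Sequences are resampled until none equals, or
#' is contained in, another sequence or its reverse complement, so
#' that planted occurrences can never cross-match between queries.
#'
#' @param n_mirnas Number of queries.
#' @param seed Integer seed.
#' @return A `mirna_catalog` with names `sim-miR-001` ...
#' @export
simulate_catalog <- function(n_mirnas, seed) {
  set.seed(as.integer(seed))
  n <- as.integer(n_mirnas)
  draw <- function() {
    len <- sample(20:24, 1L)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  seqs <- character(0)
  guard <- 0L
  while (length(seqs) < n) {
    guard <- guard + 1L
    if (guard > 100L * n) stop("could not sample a collision-free catalog")
    cand <- draw()
    pool <- c(seqs, revcomp(seqs))
    clash <- any(vapply(pool, function(s) {
      grepl(cand, s, fixed = TRUE) || grepl(s, cand, fixed = TRUE)
    }, logical(1))) || grepl(revcomp(cand), cand, fixed = TRUE)
    if (!clash) seqs <- c(seqs, cand)
  }
  nms <- sprintf("sim-miR-%03d", seq_len(n))
  as_mirna_catalog(data.frame(
    name = nms, species_prefix = "sim",
    family = sub("-[0-9]+$", "", sub("^sim-", "", nms)),
    sequence = seqs, source_ids = nms, stringsAsFactors = FALSE))
}

#' Generate background genomes with planted miRNA occurrences
#'
#' Each genome is an i.i.d. background sequence at `gc_content` with
#' every truly-present miRNA planted exactly once at a uniform
#' position and strand (non-overlapping), except for cells vetoed by
#' `fn_rate`, which are recorded in `dropped`. After planting, the
#' genome is verified by a full scan: if a catalog sequence occurs by
#' chance (or a planting junction creates one), the genome is
#' resampled, so scanning a generated panel at `fn_rate = 0`
#' reproduces the true matrix exactly by construction.
#'
#' @param truth A `sim_truth` from [simulate_presence_evolution()].
#' @param catalog A `mirna_catalog` whose names match the truth rows
#'   (defaults to [simulate_catalog()] on the config seed).
#' @param config The same [simulation_config()] used for the truth.
#' @return A `sim_panel` list: `genomes` (list of `genome_record`),
#'   `planted` (mirna, genome, contig, start, strand), `dropped`
#'   (mirna, genome), and `catalog`.
#' @export
generate_genomes <- function(truth, catalog = NULL, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (is.null(catalog)) {
    catalog <- simulate_catalog(config$n_mirnas, config$seed)
  }
  tm <- truth$true_matrix
  if (!setequal(rownames(tm$values), catalog$name)) {
    stop("catalog names do not match the simulated miRNAs")
  }
  set.seed(config$seed + 1L)
  L <- config$genome_length
  gc <- config$gc_content
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genomes <- list()
  planted_all <- list()
  dropped_all <- list()
  for (g in colnames(tm$values)) {
    truly <- rownames(tm$values)[tm$values[, g] == 1L]
    veto <- truly[stats::runif(length(truly)) < config$fn_rate]
    plant <- setdiff(truly, veto)
    if (length(veto)) {
      dropped_all[[g]] <- data.frame(mirna = veto, genome = g,
                                     stringsAsFactors = FALSE)
    }
    plant_cat <- catalog[match(plant, catalog$name), , drop = FALSE]
    for (attempt in 1:50) {
      bg <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
      placement <- plant_patterns(bg, plant_cat)
      if (is.null(placement)) next
      rec <- genome_record(g, c(contig1 = placement$genome))
      got <- scan_genome(catalog, rec)
      if (setequal(unique(got$mirna_name), plant)) {
        genomes[[g]] <- rec
        if (nrow(placement$planted)) {
          placement$planted$genome <- g
          planted_all[[g]] <- placement$planted
        }
        break
      }
    }
    if (is.null(genomes[[g]])) {
      stop("could not generate a collision-free genome for ", g)
    }
  }
  empty_planted <- data.frame(mirna = character(0), contig = character(0),
                              start = integer(0), strand = character(0),
                              genome = character(0), stringsAsFactors = FALSE)
  empty_dropped <- data.frame(mirna = character(0), genome = character(0),
                              stringsAsFactors = FALSE)
  structure(list(
    genomes = genomes,
    planted = do.call(rbind, c(list(empty_planted), unname(planted_all))),
    dropped = do.call(rbind, c(list(empty_dropped), unname(dropped_all))),
    catalog = catalog
  ), class = "sim_panel")
}

# Place each pattern once, non-overlapping, uniform position/strand.
# bg is a character vector of single bases; returns the final string.
plant_patterns <- function(bg, plant_cat) {
  L <- length(bg)
  taken <- logical(L)
  n <- nrow(plant_cat)
  starts <- integer(n)
  strands <- character(n)
  for (i in seq_len(n)) {
    w <- nchar(plant_cat$sequence[i])
    ok <- FALSE
    for (try in 1:200) {
      s <- sample.int(L - w + 1L, 1L)
      if (!any(taken[s:(s + w - 1L)])) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)  # caller resamples the background
    taken[s:(s + w - 1L)] <- TRUE
    strand <- sample(c("+", "-"), 1L)
    ins <- strsplit(plant_cat$sequence[i], "")[[1]]
    if (strand == "-") ins <- rev(chartr("ACGT", "TGCA", ins))
    bg[s:(s + w - 1L)] <- ins
    starts[i] <- s - 1L
    strands[i] <- strand
  }
  list(genome = paste(bg, collapse = ""),
       planted = data.frame(mirna = plant_cat$name,
                            contig = rep("contig1", n), start = starts,
                            strand = strands, stringsAsFactors = FALSE))
}

#' Write a simulated panel to an output directory
#'
#' Emits one FASTA per genome, the catalog FASTA, the truth matrix
#' TSV, the event-log TSV and the Newick tree.
#'
#' @param truth A `sim_truth`.
#' @param panel A `sim_panel` from [generate_genomes()].
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_sim_panel <- function(truth, panel, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (g in names(panel$genomes)) {
    p <- file.path(outdir, paste0(g, ".fa"))
    write_genome_fasta(panel$genomes[[g]], p)
    paths[[paste0("genome_", g)]] <- p
  }
  paths$catalog <- write_catalog_fasta(panel$catalog,
                                       file.path(outdir, "catalog.fa"))
  paths$truth <- write_pa_tsv(truth$true_matrix,
                              file.path(outdir, "truth_matrix.tsv"))
  paths$events <- file.path(outdir, "event_log.tsv")
  utils::write.table(truth$event_log, paths$events, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$tree <- file.path(outdir, "tree.nwk")
  ape::write.tree(truth$config$tree, paths$tree)
  invisible(paths)
}
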