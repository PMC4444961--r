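two_leaf_tree <- function(t1 = 0.6, t2 = 1.1) {
  parse_newick(sprintf("(L1:%g,L2:%g);", t1, t2))
}

ten_leaf_tree <- function() {
  ape::compute.brlen(parse_newick(
    "(((t1,t2),(t3,(t4,t5))),((t6,t7),(t8,(t9,t10))));"), method = "Grafen")
}

test_that("frozen process: zero rates pin the matrix to the root state", {
  tr <- two_leaf_tree()
  cfg1 <- simulation_config(tr, n_mirnas = 20, gain_rate = 0, loss_rate = 0,
                            root_presence_prob = 1, seed = 1)
  truth1 <- simulate_presence_evolution(cfg1)
  expect_true(all(truth1$true_matrix$values == 1L))
  expect_equal(nrow(truth1$event_log), 0L)
  cfg0 <- simulation_config(tr, n_mirnas = 20, gain_rate = 0, loss_rate = 0,
                            root_presence_prob = 0, seed = 1)
  expect_true(all(simulate_presence_evolution(cfg0)$true_matrix$values == 0L))
})

test_that("config validation catches bad parameters", {
  tr <- two_leaf_tree()
  expect_error(simulation_config(tr, seed = 1, fn_rate = 1.5))
  expect_error(simulation_config(tr, n_mirnas = 10, gain_rate = 0.1,
                                 loss_rate = 0.1, seed = 1,
                                 genome_length = 50))
  expect_error(simulation_config(tr, n_mirnas = 10, seed = 1,
                                 gain_rate = -1))
  expect_error(simulation_config(tr), "seed")
  no_len <- parse_newick("(L1,L2);")
  expect_error(simulation_config(no_len, seed = 1), "branch lengths")
})

test_that("leaf-state frequencies match the closed-form 2-state chain", {
  t1 <- 0.4; t2 <- 1.3
  g <- 0.5; l <- 1.2; p0 <- 0.3
  cfg <- simulation_config(two_leaf_tree(t1, t2), n_mirnas = 10000,
                           gain_rate = g, loss_rate = l,
                           root_presence_prob = p0, seed = 202)
  truth <- simulate_presence_evolution(cfg)
  for (leaf_t in list(c("L1", t1), c("L2", t2))) {
    t <- as.numeric(leaf_t[2])
    expected <- p0 * oracle_p1(1, g, l, t) + (1 - p0) * oracle_p1(0, g, l, t)
    observed <- mean(truth$true_matrix$values[, leaf_t[1]])
    se <- sqrt(expected * (1 - expected) / cfg$n_mirnas)
    expect_lt(abs(observed - expected), 3 * se)
  }
})

test_that("event log and matrix are mutually consistent", {
  cfg <- simulation_config(ten_leaf_tree(), n_mirnas = 40, gain_rate = 0.4,
                           loss_rate = 0.8, root_presence_prob = 0.4,
                           seed = 7)
  truth <- simulate_presence_evolution(cfg)
  # replay events down the tree and compare leaf states to the matrix
  tr <- cfg$tree
  lab <- socmir:::node_label(tr, seq_len(ape::Ntip(tr) + tr$Nnode))
  cl <- stats::reorder(tr, "cladewise")
  for (mir in rownames(truth$true_matrix$values)) {
    st <- stats::setNames(integer(length(lab)), lab)
    st[lab[ape::Ntip(tr) + 1L]] <- truth$node_states[ape::Ntip(tr) + 1L,
                                                     match(mir, rownames(truth$true_matrix$values))]
    ev <- truth$event_log[truth$event_log$mirna == mir, ]
    for (e in seq_len(nrow(cl$edge))) {
      p <- lab[cl$edge[e, 1]]; ch <- lab[cl$edge[e, 2]]
      st[ch] <- st[p]
      hit <- ev$parent == p & ev$child == ch
      if (any(hit)) st[ch] <- if (ev$type[which(hit)] == "gain") 1L else 0L
    }
    expect_equal(st[colnames(truth$true_matrix$values)],
                 truth$true_matrix$values[mir, ],
                 label = mir)
  }
})

test_that("identical seeds give identical truths and panels", {
  cfg <- simulation_config(ten_leaf_tree(), n_mirnas = 10,
                           genome_length = 2000, seed = 33)
  t1 <- simulate_presence_evolution(cfg)
  t2 <- simulate_presence_evolution(cfg)
  expect_identical(t1$true_matrix$values, t2$true_matrix$values)
  expect_identical(t1$event_log, t2$event_log)
  p1 <- generate_genomes(t1)
  p2 <- generate_genomes(t2)
  for (g in names(p1$genomes)) {
    expect_identical(as.character(p1$genomes[[g]]$contigs),
                     as.character(p2$genomes[[g]]$contigs))
  }
})

test_that("random catalogs are collision-free across strands", {
  cat <- simulate_catalog(40, seed = 12)
  expect_equal(nrow(cat), 40L)
  seqs <- cat$sequence
  for (i in seq_along(seqs)) {
    others <- c(seqs[-i], revcomp(seqs[-i]))
    expect_false(any(vapply(others, function(s)
      grepl(seqs[i], s, fixed = TRUE) || grepl(s, seqs[i], fixed = TRUE),
      logical(1))))
  }
})

test_that("scanning a generated panel recovers the truth exactly at fn 0", {
  cfg <- simulation_config(ten_leaf_tree(), n_mirnas = 15,
                           genome_length = 5000, fn_rate = 0, seed = 91)
  truth <- simulate_presence_evolution(cfg)
  panel <- generate_genomes(truth)
  hits <- scan_panel(panel$catalog, panel$genomes)
  got <- call_presence(hits, panel$catalog, names(panel$genomes))
  tm <- truth$true_matrix$values
  expect_identical(got$values[rownames(tm), colnames(tm)], tm)
  expect_equal(nrow(panel$dropped), 0L)
})

test_that("fn_rate = 1 erases every planted occurrence", {
  cfg <- simulation_config(ten_leaf_tree(), n_mirnas = 8,
                           genome_length = 3000, fn_rate = 1,
                           root_presence_prob = 1, gain_rate = 0,
                           loss_rate = 0, seed = 14)
  truth <- simulate_presence_evolution(cfg)
  panel <- generate_genomes(truth)
  hits <- scan_panel(panel$catalog, panel$genomes)
  expect_equal(nrow(hits), 0L)
  expect_equal(nrow(panel$dropped), sum(truth$true_matrix$values))
})

test_that("dropped cells are a subset of truly-present cells", {
  cfg <- simulation_config(ten_leaf_tree(), n_mirnas = 20,
                           genome_length = 4000, fn_rate = 0.3, seed = 61)
  truth <- simulate_presence_evolution(cfg)
  panel <- generate_genomes(truth)
  if (nrow(panel$dropped)) {
    tm <- truth$true_matrix$values
    expect_true(all(tm[cbind(panel$dropped$mirna, panel$dropped$genome)] == 1L))
  }
})

test_that("panel export writes loadable FASTA/TSV/Newick", {
  cfg <- simulation_config(ten_leaf_tree(), n_mirnas = 6,
                           genome_length = 2000, seed = 3)
  truth <- simulate_presence_evolution(cfg)
  panel <- generate_genomes(truth)
  outdir <- tempfile()
  paths <- write_sim_panel(truth, panel, outdir)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_pa_tsv(paths$truth)
  expect_identical(back$values, truth$true_matrix$values)
  g1 <- names(panel$genomes)[1]
  rec <- read_genome_fasta(paths[[paste0("genome_", g1)]], g1)
  expect_identical(as.character(rec$contigs),
                   as.character(panel$genomes[[g1]]$contigs))
})
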