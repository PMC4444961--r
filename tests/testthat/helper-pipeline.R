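# End-to-end pipeline inputs: a small simulated panel written to disk.
pipeline_inputs <- function(dir, seed = 77, fn_rate = 0) {
  tr <- ape::compute.brlen(
    parse_newick("(((s1,s2),(s3,s4)),((s5,s6),(s7,s8)));"),
    method = "Grafen")
  cfg <- simulation_config(tr, n_mirnas = 12, genome_length = 3000,
                           fn_rate = fn_rate, seed = seed)
  truth <- simulate_presence_evolution(cfg)
  panel <- generate_genomes(truth)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_sim_panel(truth, panel, dir)
  labels <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(genome_id = tr$tip.label,
               label = rep(c("eusocial", "solitary"), each = 4)),
    labels, sep = "\t", quote = FALSE, row.names = FALSE)
  genomes <- stats::setNames(
    file.path(dir, paste0(tr$tip.label, ".fa")), tr$tip.label)
  run_config(catalog = paths$catalog, genomes = as.list(genomes),
             tree = paths$tree, labels = labels,
             clades = list(left = paste0("s", 1:4)),
             outdir = file.path(dir, "out"),
             precedence = "sim", seed = seed)
}
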