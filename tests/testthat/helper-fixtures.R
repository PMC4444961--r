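# Shared in-code fixtures for the tests.

write_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(n) {
    c(paste0(">", n), records[[n]])
  })), path)
  path
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# catalog built directly from named DNA sequences
toy_catalog <- function(seqs) {
  entries <- data.frame(
    name = names(seqs),
    species_prefix = socmir:::species_prefix(names(seqs)),
    family = vapply(names(seqs), assign_family, character(1)),
    sequence = unname(unlist(seqs)),
    source_ids = names(seqs), stringsAsFactors = FALSE)
  dedup_catalog(entries, precedence = unique(entries$species_prefix))
}

# A fixed 8-leaf tree with one polytomy, used by the parsimony oracles.
tree8 <- function() {
  parse_newick("(((A,B),(C,D,E)),((F,G),H));")
}

# Random rooted tree with polytomies, n leaves labelled t1..tn.
random_tree <- function(n) {
  labs <- paste0("t", seq_len(n))
  # random recursive partition into 2-3 children
  build <- function(lv) {
    if (length(lv) == 1) return(lv)
    k <- sample(2:min(3, length(lv)), 1)
    groups <- split(lv, sort(sample(seq_len(k), length(lv), replace = TRUE)))
    groups <- groups[lengths(groups) > 0]
    if (length(groups) == 1) return(build(groups[[1]]))
    paste0("(", paste(vapply(groups, build, character(1)), collapse = ","),
           ")")
  }
  parse_newick(paste0(build(sample(labs)), ";"))
}

random_states <- function(tree, p = 0.5, nonconstant = FALSE) {
  repeat {
    st <- stats::setNames(rbinom(ape::Ntip(tree), 1, p), tree$tip.label)
    if (!nonconstant || (any(st == 1) && any(st == 0))) return(st)
  }
}
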