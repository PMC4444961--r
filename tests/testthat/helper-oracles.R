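# Independent oracles, deliberately naive and separate from the package
# implementation paths.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Character-by-character scanner: every occurrence of every query on
# either strand with <= max_mm substitutions; windows containing any
# non-ACGT character never match. Returns 0-based starts.
oracle_scan <- function(queries, contig, max_mm = 0L) {
  contig <- toupper(contig)
  chars <- strsplit(contig, "")[[1]]
  L <- length(chars)
  non_acgt <- !chars %in% c("A", "C", "G", "T")
  out <- list()
  for (nm in names(queries)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") queries[[nm]] else oracle_revcomp(queries[[nm]])
      pv <- strsplit(pat, "")[[1]]
      k <- length(pv)
      if (k > L) next
      n_win <- L - k + 1L
      mism <- integer(n_win)
      amb <- logical(n_win)
      for (j in seq_len(k)) {
        idx <- seq_len(n_win) + j - 1L
        mism <- mism + (chars[idx] != pv[j])
        amb <- amb | non_acgt[idx]
      }
      hit <- which(mism <= max_mm & !amb)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_name = nm, start = hit - 1L, end = hit - 1L + k,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, c(list(data.frame(mirna_name = character(0),
                                          start = integer(0),
                                          end = integer(0),
                                          strand = character(0))), out))
  res[order(res$mirna_name, res$start, res$strand), , drop = FALSE]
}

# Exhaustive parsimony over all 2^n internal-node state assignments.
# Returns min total cost and, among min-cost assignments, the minimum
# number of gains. stem = TRUE charges/counts a root-stem gain when the
# root is assigned present (prior state absent).
oracle_parsimony <- function(tree, tip_states, gain_cost = 1,
                             loss_cost = 1, stem = FALSE) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  tips <- as.integer(tip_states[tree$tip.label])
  best_cost <- Inf
  best_gains <- Inf
  for (mask in 0:(2^nint - 1L)) {
    st <- c(tips, as.integer(intToBits(mask))[seq_len(nint)])
    p <- st[edge[, 1]]
    ch <- st[edge[, 2]]
    g <- sum(p == 0L & ch == 1L) + if (stem) (st[root] == 1L) else 0L
    l <- sum(p == 1L & ch == 0L)
    cost <- gain_cost * g + loss_cost * l
    if (cost < best_cost || (cost == best_cost && g < best_gains)) {
      best_cost <- cost
      best_gains <- g
    }
  }
  list(cost = best_cost, min_gains = best_gains)
}

# Exhaustive Dollo: among assignments with exactly one gain (root-stem
# gain allowed), the minimum loss count.
oracle_dollo <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  tips <- as.integer(tip_states[tree$tip.label])
  best_losses <- Inf
  for (mask in 0:(2^nint - 1L)) {
    st <- c(tips, as.integer(intToBits(mask))[seq_len(nint)])
    p <- st[edge[, 1]]
    ch <- st[edge[, 2]]
    g <- sum(p == 0L & ch == 1L) + (st[root] == 1L)
    if (g != 1L) next
    best_losses <- min(best_losses, sum(p == 1L & ch == 0L))
  }
  best_losses
}

# Closed-form two-state chain: P(state 1 at time t | start state)
oracle_p1 <- function(start, gain, loss, t) {
  tot <- gain + loss
  if (tot == 0) return(as.numeric(start))
  stat <- gain / tot
  stat + (as.numeric(start) - stat) * exp(-tot * t)
}
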