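# Species trees and parsimony gain/loss reconstruction --------------------

#' Parse a rooted Newick tree
#'
#' Thin validating wrapper around `ape::read.tree`: the string must
#' parse, leaf labels must be unique, and child order is preserved.
#' Polytomies (including a basal polytomy) are allowed and treated as
#' rooted at the basal node.
#'
#' @param text A Newick string.
#' @return An `ape` `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick string: ", substr(text, 1, 60))
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s) in Newick: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  }
  tr
}

#' Left-to-right leaf order of a rooted tree
#'
#' @param tree A `phylo` object.
#' @return Tip labels in the order they appear when the tree is drawn
#'   with its stored child order.
#' @export
tree_leaf_order <- function(tree) {
  tr <- stats::reorder(tree, "cladewise")
  tips <- tr$edge[, 2][tr$edge[, 2] <= ape::Ntip(tr)]
  if (ape::Ntip(tr) == 1L) return(tr$tip.label)
  tr$tip.label[tips]
}

#' Bind named clade handles to a tree
#'
#' Each clade is given as its member leaf set; the handle resolves to
#' the node whose descendant leaf set equals the members exactly
#' (monophyly is required). Single-member clades resolve to the tip
#' itself, which covers panels where a clade is represented by one
#' genome.
#'
#' @param tree A `phylo` object.
#' @param clades Named list of character vectors of leaf labels.
#' @return The tree with a `clades` attribute (named list of resolved
#'   leaf sets).
#' @seealso [clade_leaves()]
#' @export
bind_clades <- function(tree, clades) {
  stopifnot(inherits(tree, "phylo"), is.list(clades),
            !is.null(names(clades)), all(nzchar(names(clades))))
  resolved <- list()
  for (nm in names(clades)) {
    members <- clades[[nm]]
    missing <- setdiff(members, tree$tip.label)
    if (length(missing)) {
      stop("clade ", nm, " references unknown leaves: ",
           paste(missing, collapse = ", "))
    }
    if (length(members) == 0L) stop("clade ", nm, " has no members")
    if (length(members) == 1L) {
      resolved[[nm]] <- members
      next
    }
    node <- ape::getMRCA(tree, members)
    desc <- ape::extract.clade(tree, node)$tip.label
    if (!setequal(desc, members)) {
      stop("clade ", nm, " is not monophyletic on this tree; its MRCA also ",
           "contains: ", paste(setdiff(desc, members), collapse = ", "))
    }
    resolved[[nm]] <- sort(members)
  }
  attr(tree, "clades") <- resolved
  tree
}

#' Leaf set of a bound clade handle
#'
#' @param tree A tree produced by [bind_clades()].
#' @param clade Clade handle name.
#' @return Character vector of member leaves.
#' @export
clade_leaves <- function(tree, clade) {
  cl <- attr(tree, "clades")
  if (is.null(cl) || is.null(cl[[clade]])) {
    stop("clade handle not bound on this tree: ", clade)
  }
  cl[[clade]]
}

#' Restrict a tree (keeping bound clades) to a sub-panel
#'
#' @param tree A `phylo`, optionally with bound clades.
#' @param leaves Leaves to keep.
#' @return The pruned tree; bound clades are re-resolved on the
#'   intersection and dropped when empty.
#' @export
restrict_tree <- function(tree, leaves) {
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing)) {
    stop("unknown leaves: ", paste(missing, collapse = ", "))
  }
  out <- ape::keep.tip(tree, leaves)
  cl <- attr(tree, "clades")
  if (!is.null(cl)) {
    cl <- lapply(cl, intersect, leaves)
    cl <- cl[vapply(cl, length, integer(1)) > 0L]
    if (length(cl)) out <- bind_clades(out, cl) else attr(out, "clades") <- NULL
  }
  out
}

# -- internal tree plumbing -------------------------------------------------

# Postorder edge matrix plus bookkeeping shared by the DP routines.
tree_dp_frame <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  stopifnot(ntip >= 2L)
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing)) {
    stop("tip state missing for leaf/leaves: ",
         paste(missing, collapse = ", "))
  }
  st <- as.integer(tip_states[tree$tip.label])
  if (anyNA(st) || !all(st %in% c(0L, 1L))) {
    stop("tip states must be 0/1 for every leaf")
  }
  po <- stats::reorder(tree, "postorder")
  nnode <- tree$Nnode
  root <- ntip + 1L
  list(tree = tree, ntip = ntip, nnode = nnode, n = ntip + nnode,
       root = root, edge = po$edge, tip_states = st)
}

node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  ifelse(node <= ntip, tree$tip.label[node], paste0("node", node))
}

# Leaf labels descending from each node (list indexed by node id).
node_leafsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  po <- stats::reorder(tree, "postorder")
  sets <- vector("list", n)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

# Leaf set of a single node, by targeted descent (cheap when only a few
# event branches need labelling).
node_leafset_one <- function(tree, node, edge) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    kids <- edge[edge[, 1] == nd, 2]
    acc <- c(acc, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(tree$tip.label[acc])
}

fast_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = if (length(cols[[1]])) seq_along(cols[[1]]) else
              integer(0))
}

events_from_states <- function(tree, node_states, stem_gain = FALSE) {
  po <- stats::reorder(tree, "postorder")
  p <- po$edge[, 1]; ch <- po$edge[, 2]
  type <- character(nrow(po$edge))
  type[node_states[p] == 0L & node_states[ch] == 1L] <- "gain"
  type[node_states[p] == 1L & node_states[ch] == 0L] <- "loss"
  keep <- which(nzchar(type))
  ev <- fast_df(
    parent = node_label(tree, p[keep]),
    child = node_label(tree, ch[keep]),
    type = type[keep],
    child_leaves = vapply(ch[keep], function(nd) {
      paste(node_leafset_one(tree, nd, po$edge), collapse = ";")
    }, character(1))
  )
  root <- ape::Ntip(tree) + 1L
  if (stem_gain && node_states[root] == 1L) {
    ev <- rbind(fast_df(parent = "<root-stem>",
                        child = node_label(tree, root), type = "gain",
                        child_leaves = paste(sort(tree$tip.label),
                                             collapse = ";")),
                ev)
  }
  ord <- order(ev$type, ev$child)
  rownames(ev) <- NULL
  ev[ord, , drop = FALSE]
}

new_reconstruction <- function(method, tree, node_states, events,
                               total_cost, ambiguous = integer(0),
                               mirna_name = NULL) {
  ns <- node_states
  names(ns) <- node_label(tree, seq_along(ns))
  structure(list(method = method, mirna_name = mirna_name,
                 node_states = ns, events = events,
                 total_cost = total_cost,
                 n_gains = sum(events$type == "gain"),
                 n_losses = sum(events$type == "loss"),
                 ambiguous_nodes = node_label(tree, ambiguous)),
            class = "gainloss_reconstruction")
}

#' @export
print.gainloss_reconstruction <- function(x, ...) {
  cat(sprintf("%s reconstruction%s: cost %g, %d gain(s), %d loss(es)\n",
              x$method,
              if (is.null(x$mirna_name)) "" else paste0(" [", x$mirna_name, "]"),
              x$total_cost, x$n_gains, x$n_losses))
  invisible(x)
}

#' Minimum-change (Fitch) reconstruction of a binary character
#'
#' Computes the minimum number of state changes needed to explain the
#' tip presence/absence pattern, allowing both gain (0 to 1) and loss
#' (1 to 0) anywhere on the tree, i.e. regain after loss is permitted.
#' Polytomies are handled natively by a unit-cost dynamic program over
#' node states (no binarization). One minimum-change assignment is
#' returned; among ties, the child keeps the parent's state so that
#' events are pushed toward the tips (delayed-transformation
#' convention), and nodes whose state is not forced are flagged in
#' `ambiguous_nodes`. No cost is charged for the root state itself, so
#' a constant character has cost 0 and no events.
#'
#' @param tree A rooted `phylo` tree (>= 2 leaves).
#' @param tip_states Named 0/1 vector covering every leaf.
#' @param mirna_name Optional character name carried into the result.
#' @return A `gainloss_reconstruction` with fields `method`,
#'   `node_states`, `events` (one row per branch with a state change),
#'   `total_cost`, and `ambiguous_nodes`.
#' @export
fitch_min_changes <- function(tree, tip_states, mirna_name = NULL) {
  fr <- tree_dp_frame(tree, tip_states)
  cost <- matrix(0, fr$n, 2L)
  cost[seq_len(fr$ntip), 1L] <- ifelse(fr$tip_states == 0L, 0, Inf)
  cost[seq_len(fr$ntip), 2L] <- ifelse(fr$tip_states == 1L, 0, Inf)
  for (e in seq_len(nrow(fr$edge))) {
    p <- fr$edge[e, 1]; ch <- fr$edge[e, 2]
    cost[p, 1L] <- cost[p, 1L] + min(cost[ch, 1L], cost[ch, 2L] + 1)
    cost[p, 2L] <- cost[p, 2L] + min(cost[ch, 2L], cost[ch, 1L] + 1)
  }
  total <- min(cost[fr$root, ])
  states <- integer(fr$n)
  states[seq_len(fr$ntip)] <- fr$tip_states
  ambiguous <- integer(0)
  root_opts <- cost[fr$root, ]
  states[fr$root] <- if (root_opts[1L] <= root_opts[2L]) 0L else 1L
  if (root_opts[1L] == root_opts[2L]) ambiguous <- fr$root
  # preorder = reverse postorder over edges
  for (e in rev(seq_len(nrow(fr$edge)))) {
    p <- fr$edge[e, 1]; ch <- fr$edge[e, 2]
    if (ch <= fr$ntip) next
    ps <- states[p]
    c0 <- cost[ch, 1L] + as.numeric(ps != 0L)
    c1 <- cost[ch, 2L] + as.numeric(ps != 1L)
    if (c0 == c1) {
      states[ch] <- ps
      ambiguous <- c(ambiguous, ch)
    } else {
      states[ch] <- if (c0 < c1) 0L else 1L
    }
  }
  ev <- events_from_states(tree, states, stem_gain = FALSE)
  new_reconstruction("fitch", tree, states, ev, total,
                     ambiguous = unique(ambiguous), mirna_name = mirna_name)
}

#' Dollo reconstruction: single gain, minimal losses
#'
#' Places exactly one gain on the branch entering the most recent
#' common ancestor of all present leaves (the root stem if every leaf
#' is present, the terminal branch if only one leaf is), then the
#' minimal set of loss branches below it that covers all absent
#' descendants. Total cost is `1 + number of losses`.
#'
#' @inheritParams fitch_min_changes
#' @return A `gainloss_reconstruction` with `method = "dollo"`.
#' @export
dollo_reconstruct <- function(tree, tip_states, mirna_name = NULL) {
  fr <- tree_dp_frame(tree, tip_states)
  present <- which(fr$tip_states == 1L)
  if (length(present) == 0L) {
    stop("Dollo reconstruction undefined for an all-absent character")
  }
  mrca <- if (length(present) == 1L) present else
    ape::getMRCA(tree, tree$tip.label[present])
  # inside the MRCA clade a node is kept present iff it still has a
  # present descendant; everything outside the clade is absent
  has_present <- logical(fr$n)
  has_present[present] <- TRUE
  for (e in seq_len(nrow(fr$edge))) {
    p <- fr$edge[e, 1]; ch <- fr$edge[e, 2]
    has_present[p] <- has_present[p] || has_present[ch]
  }
  in_clade <- logical(fr$n)
  in_clade[mrca] <- TRUE
  for (e in rev(seq_len(nrow(fr$edge)))) {
    p <- fr$edge[e, 1]; ch <- fr$edge[e, 2]
    if (in_clade[p]) in_clade[ch] <- TRUE
  }
  states <- as.integer(in_clade & has_present)
  ev <- events_from_states(tree, states, stem_gain = mrca == fr$root)
  total <- 1 + sum(ev$type == "loss")
  stopifnot(sum(ev$type == "gain") == 1L)
  new_reconstruction("dollo", tree, states, ev, total,
                     mirna_name = mirna_name)
}

#' Minimum number of independent gains under weighted parsimony
#'
#' Over all ancestral assignments with minimum total cost
#' (`gain_cost` per 0-to-1 change, `loss_cost` per 1-to-0 change),
#' returns the smallest number of gain events. The state prior to the
#' root is absent: the queries are lineage-annotated miRNAs, so
#' presence at the panel root is itself a (root-stem) gain event — an
#' all-present character therefore counts one gain. Independent of the
#' tie-breaking used for reported event lists.
#'
#' @inheritParams fitch_min_changes
#' @param gain_cost,loss_cost Positive per-event costs (default 1).
#' @return Integer minimum gain count.
#' @export
count_independent_gains <- function(tree, tip_states, gain_cost = 1,
                                    loss_cost = 1) {
  if (!(is.numeric(gain_cost) && gain_cost > 0 &&
        is.numeric(loss_cost) && loss_cost > 0)) {
    stop("gain_cost and loss_cost must be positive")
  }
  fr <- tree_dp_frame(tree, tip_states)
  # per node/state pair: (min subtree cost, min gains among min-cost)
  cost <- matrix(0, fr$n, 2L)
  gains <- matrix(0, fr$n, 2L)
  cost[seq_len(fr$ntip), 1L] <- ifelse(fr$tip_states == 0L, 0, Inf)
  cost[seq_len(fr$ntip), 2L] <- ifelse(fr$tip_states == 1L, 0, Inf)
  lex_min <- function(c0, g0, c1, g1) {
    if (c0 < c1 || (c0 == c1 && g0 <= g1)) c(c0, g0) else c(c1, g1)
  }
  for (e in seq_len(nrow(fr$edge))) {
    p <- fr$edge[e, 1]; ch <- fr$edge[e, 2]
    # parent state 0: child stays 0, or gain into state 1
    b0 <- lex_min(cost[ch, 1L], gains[ch, 1L],
                  cost[ch, 2L] + gain_cost, gains[ch, 2L] + 1)
    # parent state 1: child stays 1, or loss into state 0
    b1 <- lex_min(cost[ch, 2L], gains[ch, 2L],
                  cost[ch, 1L] + loss_cost, gains[ch, 1L])
    cost[p, 1L] <- cost[p, 1L] + b0[1L]; gains[p, 1L] <- gains[p, 1L] + b0[2L]
    cost[p, 2L] <- cost[p, 2L] + b1[1L]; gains[p, 2L] <- gains[p, 2L] + b1[2L]
  }
  # root stem from prior state 0
  best <- lex_min(cost[fr$root, 1L], gains[fr$root, 1L],
                  cost[fr$root, 2L] + gain_cost, gains[fr$root, 2L] + 1)
  as.integer(best[2L])
}

#' Reconstruction report for every row of a presence matrix
#'
#' @param m A `pa_matrix`.
#' @param tree A rooted tree whose leaves are the matrix columns.
#' @param methods Which reconstructions to run.
#' @return A data.frame with one row per miRNA and per requested
#'   method: cost, gains, losses, and min independent gains.
#' @export
reconstruct_matrix <- function(m, tree, methods = c("fitch", "dollo")) {
  stopifnot(inherits(m, "pa_matrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(rownames(m$values), function(nm) {
    ch <- m$values[nm, ]
    out <- list()
    if ("fitch" %in% methods) {
      f <- fitch_min_changes(tree, ch, mirna_name = nm)
      out$fitch_cost <- f$total_cost
      out$fitch_gains <- f$n_gains
      out$fitch_losses <- f$n_losses
    }
    if ("dollo" %in% methods) {
      if (sum(ch) >= 1L) {
        d <- dollo_reconstruct(tree, ch, mirna_name = nm)
        out$dollo_cost <- d$total_cost
        out$dollo_losses <- d$n_losses
      } else {
        out$dollo_cost <- NA_real_
        out$dollo_losses <- NA_integer_
      }
    }
    out$min_independent_gains <- count_independent_gains(tree, ch)
    data.frame(mirna_name = nm, out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Serialize a reconstruction to a JSON-ready list
#'
#' @param rec A `gainloss_reconstruction`.
#' @return A plain list (method, cost, gains, losses, events).
#' @export
reconstruction_report <- function(rec) {
  list(mirna = rec$mirna_name, method = rec$method,
       total_cost = rec$total_cost, gains = rec$n_gains,
       losses = rec$n_losses,
       events = rec$events, ambiguous_nodes = rec$ambiguous_nodes)
}
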