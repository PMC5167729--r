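# internal helpers shared across modules

# round half away from zero (R's round() is round-half-even); published
# taxonomic G+C values are conventionally rounded half-up
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical key for an unrooted split: the lexicographically smaller of the
# two sorted, "|"-joined sides
split_key <- function(side, all_tips) {
  a <- paste(sort(side), collapse = "|")
  b <- paste(sort(setdiff(all_tips, side)), collapse = "|")
  if (a <= b) a else b
}

# numeric supports from a phylo object's node labels; NA where absent or
# non-numeric (string node names are allowed and simply carry no support)
node_supports <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  suppressWarnings(as.numeric(tree$node.label))
}

stopifnot_phylo <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("expected a 'phylo' tree object", call. = FALSE)
}

# list of tips (labels) below each node, indexed 1..(Ntip+Nnode);
# computed by one postorder sweep
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
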