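#' Encode alignment columns for likelihood computation
#'
#' @param chars character matrix, rows = species (rownames required),
#'   columns = alignment sites, over {A,C,G,T,N,-}. `N` and `-` are
#'   missing data: their partial likelihoods are 1 for every base.
#' @param weights optional per-column multiplicities.
#' @param collapse collapse identical columns into weighted patterns.
#' @return a `site_columns` object (`states` 1..4/NA matrix, `weights`).
#' @export
site_columns <- function(chars, weights = NULL, collapse = FALSE) {
  stopifnot(is.matrix(chars), !is.null(rownames(chars)))
  states <- matrix(match(chars, BASES), nrow = nrow(chars),
                   dimnames = list(rownames(chars), NULL))
  if (is.null(weights)) weights <- rep(1, ncol(states))
  if (collapse && ncol(states) > 0L) {
    key <- apply(states, 2, paste, collapse = ".")
    first <- !duplicated(key)
    w <- tapply(weights, key, sum)
    states <- states[, first, drop = FALSE]
    weights <- as.numeric(w[key[first]])
  }
  structure(list(states = states, weights = weights), class = "site_columns")
}

#' @export
print.site_columns <- function(x, ...) {
  cat("site_columns:", ncol(x$states), "pattern(s) over", nrow(x$states),
      "species, total weight", sum(x$weights), "\n")
  invisible(x)
}

## postorder edge list of an ape tree, plus tip index lookup
tree_index <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, lengths = po$edge.length, ntip = length(po$tip.label),
       tips = po$tip.label, nnode = po$Nnode, root = length(po$tip.label) + 1L)
}

#' Per-column log-likelihood by Felsenstein pruning
#'
#' Vectorized over columns: partial-likelihood matrices (4 x L) are pushed
#' from the tips to the root, with per-column rescaling to avoid
#' underflow. Leaves present in the columns but absent from the tree are
#' an error; tree tips absent from the columns are treated as all-missing.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param model a [gtr_model()].
#' @param columns a [site_columns()] object (or character matrix).
#' @param rho optional scaling of all branch lengths (conserved state).
#' @return numeric vector of per-column log-likelihoods.
#' @export
column_log_likelihood <- function(tree, model, columns, rho = 1) {
  if (is.matrix(columns) && is.character(columns))
    columns <- site_columns(columns)
  ti <- tree_index(tree)
  unknown <- setdiff(rownames(columns$states), ti$tips)
  if (length(unknown))
    stop("leaf in columns absent from tree: ", paste(unknown, collapse = ", "))
  L <- ncol(columns$states)
  if (L == 0L) return(numeric(0))
  nn <- ti$ntip + ti$nnode
  partials <- vector("list", nn)
  logscale <- numeric(L)
  tip_partial <- function(label) {
    M <- matrix(1, 4, L)
    if (label %in% rownames(columns$states)) {
      st <- columns$states[label, ]
      obs <- !is.na(st)
      M[, obs] <- 0
      M[cbind(st[obs], which(obs))] <- 1
    }
    M
  }
  for (k in seq_along(ti$lengths)) {
    p <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    P <- transition_matrix(model, ti$lengths[k] * rho)
    cp <- if (ch <= ti$ntip) tip_partial(ti$tips[ch]) else partials[[ch]]
    up <- P %*% cp
    if (is.null(partials[[p]])) partials[[p]] <- up
    else partials[[p]] <- partials[[p]] * up
    pp <- partials[[p]]
    mx <- pmax(pp[1, ], pp[2, ], pp[3, ], pp[4, ])
    mx[mx == 0] <- 1
    partials[[p]] <- sweep(partials[[p]], 2, mx, "/")
    logscale <- logscale + log(mx)
  }
  log(colSums(model$pi * partials[[ti$root]])) + logscale
}

## total weighted log-likelihood of a site_columns set
total_log_likelihood <- function(tree, model, columns, rho = 1) {
  sum(column_log_likelihood(tree, model, columns, rho) * columns$weights)
}

#' Scale every branch length of a tree by rho
#'
#' The conserved-state model of the phylo-HMM is the neutral model with
#' all branch lengths multiplied by `rho` (0 < rho <= 1).
#'
#' @param tree `ape::phylo`.
#' @param rho positive scale factor.
#' @return the scaled tree.
#' @export
scale_tree <- function(tree, rho) {
  if (rho <= 0) stop("rho must be > 0")
  tree$edge.length <- tree$edge.length * rho
  tree
}

#' Simulate alignment columns along a phylogeny
#'
#' Draws the root from the model's equilibrium frequencies and evolves
#' every site independently down the tree under `P(t) = exp(Qt)`, with
#' branch lengths optionally scaled by `rho` (conserved sites).
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param model a [gtr_model()].
#' @param n number of sites.
#' @param rho branch-length scaling.
#' @param root optional integer vector (1..4) of fixed root states.
#' @return character matrix (tips x n) of evolved states.
#' @export
simulate_columns <- function(tree, model, n, rho = 1, root = NULL) {
  ti <- tree_index(tree)
  nn <- ti$ntip + ti$nnode
  states <- matrix(NA_integer_, nrow = nn, ncol = n)
  if (is.null(root)) root <- sample.int(4L, n, replace = TRUE, prob = model$pi)
  states[ti$root, ] <- root
  # preorder = reversed postorder edge list
  for (k in rev(seq_along(ti$lengths))) {
    p <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    P <- transition_matrix(model, ti$lengths[k] * rho)
    ps <- states[p, ]
    cs <- integer(n)
    for (b in 1:4) {
      idx <- which(ps == b)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
    states[ch, ] <- cs
  }
  out <- matrix(BASES[states[seq_len(ti$ntip), , drop = FALSE]],
                nrow = ti$ntip, dimnames = list(ti$tips, NULL))
  out
}

#' Path-length distances from every leaf to an outgroup leaf
#'
#' Sum of branch lengths along the unique leaf-to-leaf path, as used for
#' comparing neutral substitution rates between lineages; the full
#' symmetric cophenetic matrix is attached as an attribute.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param outgroup leaf label.
#' @return named numeric vector of distances (outgroup excluded), with
#'   attribute `"cophenetic"` holding the full matrix.
#' @export
distance_to_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("unknown leaf: ", outgroup)
  cm <- ape::cophenetic.phylo(tree)
  d <- cm[outgroup, setdiff(tree$tip.label, outgroup)]
  attr(d, "cophenetic") <- cm
  d
}
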