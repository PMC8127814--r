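# Shared fixtures and independent brute-force oracles. Oracles here never
# call the code paths they check.

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

mutate_dna <- function(s, n_mut) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- sample(length(ch), n_mut)
  for (i in idx) ch[i] <- sample(setdiff(BASES4, ch[i]), 1)
  paste(ch, collapse = "")
}

rand_gtr <- function() {
  pi <- stats::runif(4, 0.1, 1); pi <- pi / sum(pi)
  gtr_model(pi, stats::runif(6, 0.2, 5))
}

back_translate <- function(prot) {
  ct <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(prot, "", fixed = TRUE)[[1]],
               function(a) sample(names(ct)[ct == a], 1), ""), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]],
               n, replace = TRUE), collapse = "")
}

## ---- pruning oracle: enumerate all internal-state assignments -----------
brute_column_loglik <- function(tree, model, column, rho = 1) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1L
  Pm <- lapply(seq_len(nrow(tree$edge)), function(k)
    transition_matrix(model, tree$edge.length[k] * rho))
  tipstate <- match(column[tree$tip.label], c("A", "C", "G", "T"))
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= ntip) tipstate[node] else grid[g, node - ntip]
    }
    p <- model$pi[grid[g, 1]]          # root = ntip + 1 is first internal
    for (k in seq_len(nrow(tree$edge))) {
      a <- assign_state(tree$edge[k, 1])
      b <- assign_state(tree$edge[k, 2])
      if (is.na(b)) { # missing tip: sum over states = 1
        next
      }
      p <- p * Pm[[k]][a, b]
    }
    total <- total + p
  }
  log(unname(total))
}

## ---- HMM oracles: enumerate all 2^L state paths --------------------------
brute_hmm <- function(E, params) {
  L <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(1:2), L)))
  tot <- -Inf
  best <- -Inf
  for (i in seq_len(nrow(paths))) {
    st <- paths[i, ]
    lp <- log(params$init[st[1]]) + E[1, st[1]]
    if (L > 1) for (t in 2:L)
      lp <- lp + log(params$trans[st[t - 1], st[t]]) + E[t, st[t]]
    tot <- max(tot, lp) + log1p(exp(min(tot, lp) - max(tot, lp)))
    best <- max(best, lp)
  }
  list(loglik = tot, viterbi = best)
}

## ---- chaining oracle: exhaustive ordered collinear subsets ---------------
brute_chain_score <- function(h, max_gap = 5000) {
  n <- nrow(h)
  o <- order(h$qstart, h$tstart)
  h <- h[o, , drop = FALSE]
  dens <- h$score / (h$qend - h$qstart)
  best <- 0
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  for (i in seq_len(nrow(subsets))) {
    idx <- which(subsets[i, ])
    if (length(idx) == 0L) next
    ok <- TRUE
    sc <- h$score[idx[1]]
    if (length(idx) > 1L) for (k in 2:length(idx)) {
      a <- idx[k - 1L]; b <- idx[k]
      if (h$qstart[b] <= h$qstart[a] || h$tstart[b] <= h$tstart[a] ||
          h$qstart[b] - h$qend[a] > max_gap ||
          h$tstart[b] - h$tend[a] > max_gap) { ok <- FALSE; break }
      ov <- max(0, h$qend[a] - h$qstart[b], h$tend[a] - h$tstart[b])
      sc <- sc + h$score[b] - ov * min(dens[a], dens[b])
    }
    if (ok && sc > best) best <- sc
  }
  best
}

## ---- cophenetic oracle: explicit path enumeration ------------------------
brute_leaf_distance <- function(tree, a, b) {
  ntip <- length(tree$tip.label)
  parent <- function(x) tree$edge[tree$edge[, 2] == x, 1]
  elen <- function(x) tree$edge.length[tree$edge[, 2] == x]
  path_up <- function(x) {
    nodes <- x; d <- 0
    while (length(parent(x)) == 1L) {
      d <- c(d, d[length(d)] + elen(x))
      x <- parent(x)
      nodes <- c(nodes, x)
    }
    list(nodes = nodes, dist = d)
  }
  pa <- path_up(match(a, tree$tip.label))
  pb <- path_up(match(b, tree$tip.label))
  common <- intersect(pa$nodes, pb$nodes)[1]
  pa$dist[match(common, pa$nodes)] + pb$dist[match(common, pb$nodes)]
}

## ---- shared medium fixture (built once per test run) ----------------------
fixture_env <- new.env()
small_sim <- function() {
  if (is.null(fixture_env$sim)) {
    cfg <- sim_config(n_elements = 100L, background_length = 60000L,
                      loss_plan = c(hipCom0 = 10L),
                      gap_plan = c(hipCom0 = 5L),
                      gene_plan = list(n = 10L, cds_length = 300L),
                      seed = 5L)
    fixture_env$sim <- evolve_alignment(cfg)
  }
  fixture_env$sim
}

truth_matrix <- function(sim) {
  sp <- unique(sim$status$species)
  m <- matrix(sim$status$status, nrow = nrow(sim$elements),
              dimnames = list(sim$elements$name, sp))
  m
}
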