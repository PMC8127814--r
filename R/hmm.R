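#' Two-state phylo-HMM transition parameters
#'
#' The two tuning knobs are the target coverage `gamma` (stationary
#' fraction of columns in the conserved state) and the expected conserved
#' element length `omega` in columns. They map to transition rates
#' `mu = 1/omega` (conserved -> neutral) and `nu = mu * gamma / (1 -
#' gamma)` (neutral -> conserved), which makes `gamma` the exact
#' stationary occupancy and `omega` the exact mean conserved run length.
#' Defaults follow common practice for teleost whole-genome screens:
#' coverage 0.3, expected length 45 bp.
#'
#' @param gamma target coverage in (0,1).
#' @param omega expected element length in columns (> 1).
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(gamma = 0.3, omega = 45) {
  stopifnot(gamma > 0, gamma < 1, omega > 1)
  mu <- 1 / omega
  nu <- mu * gamma / (1 - gamma)
  structure(list(gamma = gamma, omega = omega, mu = mu, nu = nu,
                 init = c(conserved = gamma, neutral = 1 - gamma),
                 # rows = from, cols = to; state 1 = conserved, 2 = neutral
                 trans = matrix(c(1 - mu, mu, nu, 1 - nu), 2, 2,
                                byrow = TRUE)),
            class = "hmm_params")
}

## normalize emissions input to an L x 2 matrix of log-likelihoods
as_log_emissions <- function(log_emis_conserved, log_emis_neutral = NULL) {
  if (is.null(log_emis_neutral)) {
    stopifnot(is.matrix(log_emis_conserved), ncol(log_emis_conserved) == 2L)
    return(log_emis_conserved)
  }
  cbind(conserved = log_emis_conserved, neutral = log_emis_neutral)
}

#' Forward-backward posterior decoding of the conservation HMM
#'
#' Scaled forward-backward over the two states. Emissions are per-column
#' log-likelihoods of the alignment column under the conserved
#' (rho-scaled) and neutral phylogenetic models.
#'
#' @param log_emis_conserved,log_emis_neutral numeric vectors of
#'   per-column log emission likelihoods (or a single L x 2 matrix as the
#'   first argument).
#' @param params an [hmm_params()] object.
#' @return list with `posterior` (P(conserved | data) per column),
#'   `loglik` (forward total), `loglik_backward` (same quantity computed
#'   from the backward pass, for verification).
#' @export
forward_backward <- function(log_emis_conserved, log_emis_neutral = NULL,
                             params = hmm_params()) {
  E <- as_log_emissions(log_emis_conserved, log_emis_neutral)
  L <- nrow(E)
  if (L == 0L) stop("zero-length emission sequence")
  shift <- pmax(E[, 1], E[, 2])
  e <- exp(E - shift)
  A <- params$trans
  alpha <- matrix(0, L, 2)
  cvec <- numeric(L)
  a <- params$init * e[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:L) {
    a <- (alpha[t - 1, ] %*% A) * e[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  loglik <- sum(log(cvec)) + sum(shift)
  beta <- matrix(0, L, 2)
  beta[L, ] <- 1
  for (t in (L - 1):1) {
    b <- A %*% (e[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  if (L == 1L) beta[1, ] <- 1
  post <- alpha * beta
  post <- post / rowSums(post)
  ll_b <- log(sum(params$init * e[1, ] * beta[1, ])) +
    sum(log(cvec[-1])) + sum(shift)
  list(posterior = post[, 1], loglik = loglik, loglik_backward = ll_b)
}

#' Viterbi segmentation into conserved runs
#'
#' Most probable state path; ties are broken toward the neutral state so
#' ambiguous columns never extend an element.
#'
#' @inheritParams forward_backward
#' @return list with `path` (1 = conserved, 2 = neutral), `score` (log
#'   probability of the best path) and `runs` (matrix of half-open column
#'   ranges `[start, end)`, 1-based starts, of conserved runs).
#' @export
viterbi_segments <- function(log_emis_conserved, log_emis_neutral = NULL,
                             params = hmm_params()) {
  E <- as_log_emissions(log_emis_conserved, log_emis_neutral)
  L <- nrow(E)
  if (L == 0L) stop("zero-length emission sequence")
  lA <- log(params$trans)
  lI <- log(params$init)
  delta <- matrix(-Inf, L, 2)
  back <- matrix(1L, L, 2)
  delta[1, ] <- lI + E[1, ]
  for (t in 2:L) {
    for (s in 1:2) {
      cand <- delta[t - 1, ] + lA[, s]
      # tie toward neutral predecessor (state 2)
      best <- if (cand[2] >= cand[1]) 2L else 1L
      back[t, s] <- best
      delta[t, s] <- cand[best] + E[t, s]
    }
  }
  path <- integer(L)
  path[L] <- if (delta[L, 2] >= delta[L, 1]) 2L else 1L
  score <- delta[L, path[L]]
  if (L > 1) for (t in (L - 1):1) path[t] <- back[t + 1, path[t + 1]]
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  list(path = path, score = score,
       runs = cbind(start = starts[keep], end = ends[keep] + 1L))
}

## pattern-collapsing cache: unique patterns + back-map to column order
pattern_cache <- function(sc) {
  key <- apply(sc$states, 2, paste, collapse = ".")
  uniq <- which(!duplicated(key))
  list(u = structure(list(states = sc$states[, uniq, drop = FALSE],
                          weights = rep(1, length(uniq))),
                     class = "site_columns"),
       map = match(key, key[uniq]))
}

emission_from_cache <- function(tree, model, cache, rho = 1) {
  column_log_likelihood(tree, model, cache$u, rho = rho)[cache$map]
}

## per-column log-likelihoods with internal pattern collapsing
emission_loglik <- function(tree, model, sc, rho = 1) {
  emission_from_cache(tree, model, pattern_cache(sc), rho)
}

#' Estimate the conserved-model scaling factor rho
#'
#' Maximizes the total phylo-HMM log-likelihood over `rho`, the factor by
#' which all neutral branch lengths are shrunk to form the conserved
#' model. Accepts one column set or a list (one per chromosome); per-set
#' estimates are averaged arithmetically into the final model, with a
#' length-weighted mean available.
#'
#' @param columns a [site_columns()] object in genomic order, or a list
#'   of them (one per chromosome).
#' @param model neutral `gtr_model`.
#' @param tree neutral tree with fitted branch lengths.
#' @param params [hmm_params()].
#' @param bounds search interval for rho.
#' @param weighted use a length-weighted mean across chromosomes.
#' @return list with `rho` (averaged), `rho_per_chrom`, `boundary`
#'   (logical: any per-chromosome estimate at a search bound).
#' @export
estimate_rho <- function(columns, model, tree, params = hmm_params(),
                         bounds = c(0.01, 1), weighted = FALSE) {
  if (inherits(columns, "site_columns")) columns <- list(columns)
  sizes <- vapply(columns, function(s) ncol(s$states), 1L)
  if (sum(sizes) < 500)
    warning("fewer than 500 columns; rho estimate will be unstable")
  rhos <- numeric(length(columns))
  boundary <- FALSE
  for (i in seq_along(columns)) {
    cache <- pattern_cache(columns[[i]])
    e_neut <- emission_from_cache(tree, model, cache, rho = 1)
    f <- function(r) {
      e_cons <- emission_from_cache(tree, model, cache, rho = r)
      -forward_backward(e_cons, e_neut, params)$loglik
    }
    opt <- stats::optimize(f, interval = bounds, tol = 1e-4)
    rhos[i] <- opt$minimum
    if (min(rhos[i] - bounds[1], bounds[2] - rhos[i]) < 0.02) {
      boundary <- TRUE
      warning("rho estimate at search boundary (", signif(rhos[i], 3), ")")
    }
  }
  rho <- if (weighted) sum(rhos * sizes) / sum(sizes) else mean(rhos)
  list(rho = rho, rho_per_chrom = rhos, boundary = boundary)
}

#' Call conserved elements from reference-anchored alignment blocks
#'
#' Computes per-column emissions under the neutral and rho-scaled
#' conserved models, runs the Viterbi segmentation per reference
#' sequence (blocks concatenated in reference order), and maps conserved
#' runs back to reference coordinates. Columns where the reference row is
#' gapped carry no coordinate: runs are bridged across up to
#' `bridge_gap` such columns, otherwise split. Elements shorter than
#' `min_length` reference bp are dropped.
#'
#' @param blocks list of `AlignmentBlock`s (reference row first).
#' @param model neutral `gtr_model`.
#' @param tree neutral tree.
#' @param rho conserved-model scaling factor.
#' @param params [hmm_params()].
#' @param min_length minimum element length (reference bp).
#' @param bridge_gap max reference-gap columns bridged inside a run.
#' @return an `intervals` table of elements with summed log-odds scores.
#' @export
call_elements <- function(blocks, model, tree, rho, params = hmm_params(),
                          min_length = 15L, bridge_gap = 10L) {
  idx <- ref_block_index(blocks)
  ref <- idx$species
  species <- unique(unlist(lapply(blocks, function(b) b$species)))
  out <- list()
  for (sq in names(idx$tab)) {
    tab <- idx$tab[[sq]]
    mats <- list(); refpos <- list()
    for (j in seq_len(nrow(tab))) {
      b <- blocks[[tab$block[j]]]
      cm <- block_char_matrix(b)
      full <- matrix("N", nrow = length(species), ncol = ncol(cm),
                     dimnames = list(species, NULL))
      full[b$species, ] <- cm
      mats[[j]] <- full
      refpos[[j]] <- block_pos_map(b)[1, ]
    }
    chars <- do.call(cbind, mats)
    rpos <- unlist(refpos)
    cache <- pattern_cache(site_columns(chars))
    e_neut <- emission_from_cache(tree, model, cache, rho = 1)
    e_cons <- emission_from_cache(tree, model, cache, rho = rho)
    vit <- viterbi_segments(e_cons, e_neut, params)
    lodds <- e_cons - e_neut
    for (r in seq_len(nrow(vit$runs))) {
      cols <- vit$runs[r, "start"]:(vit$runs[r, "end"] - 1L)
      pieces <- split_run_at_ref_gaps(cols, rpos, bridge_gap)
      for (pc in pieces) {
        ps <- rpos[pc]
        ps <- ps[!is.na(ps)]
        if (length(ps) == 0L) next
        if (max(ps) - min(ps) + 1L < min_length) next
        out[[length(out) + 1L]] <- data.frame(
          seqname = sq, start = min(ps), end = max(ps) + 1L,
          score = sum(lodds[pc]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(intervals(character(), integer(), integer()))
  df <- do.call(rbind, out)
  df <- df[order(df$seqname, df$start), , drop = FALSE]
  intervals(df$seqname, df$start, df$end,
            name = sprintf("el%05d", seq_len(nrow(df))), score = df$score)
}

## split a Viterbi run's columns where > bridge_gap consecutive columns
## have no reference coordinate
split_run_at_ref_gaps <- function(cols, rpos, bridge_gap) {
  has <- !is.na(rpos[cols])
  if (all(has)) return(list(cols))
  if (!any(has)) return(list())
  r <- rle(has)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pieces <- list()
  cur <- integer()
  for (i in seq_along(r$values)) {
    seg <- cols[starts[i]:ends[i]]
    if (r$values[i]) {
      cur <- c(cur, seg)
    } else if (length(cur) && r$lengths[i] > bridge_gap) {
      pieces[[length(pieces) + 1L]] <- cur
      cur <- integer()
    } else if (length(cur)) {
      cur <- c(cur, seg)
    }
  }
  if (length(cur)) pieces[[length(pieces) + 1L]] <- cur
  pieces
}

#' Sensitivity of called elements on coding exons
#'
#' Fraction of coding exons overlapped by a called element at coverage at
#' least `min_cov` — a standard sanity check that the screen finds known
#' functional sequence.
#'
#' @param elements `intervals` of called elements.
#' @param ann annotation table (exon or CDS records used).
#' @param min_cov minimum per-exon coverage fraction (boundary inclusive).
#' @return fraction in \[0,1\]; attribute `"n"` holds the exon count.
#' @export
exon_sensitivity <- function(elements, ann, min_cov = 0.10) {
  ex <- ann[ann$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) ex <- ann[ann$type == "CDS", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon or CDS records in annotation")
  cov <- vapply(seq_len(nrow(ex)), function(i) {
    hits <- elements[overlapping_idx(elements, ex$seqname[i], ex$start[i],
                                     ex$end[i]), , drop = FALSE]
    coverage_fraction(list(seqname = ex$seqname[i], start = ex$start[i],
                           end = ex$end[i]), hits)
  }, 0)
  structure(mean(cov >= min_cov), n = nrow(ex))
}

#' Define conserved noncoding elements (CNEs)
#'
#' A called element qualifies as a CNE when it has zero overlap with any
#' annotated CDS or exon (strictly noncoding) and is present — by the
#' 30% alignment-coverage rule or by homology rescue — in at least
#' `min_species` non-reference species.
#'
#' @param elements `intervals` of called elements.
#' @param ann annotation table with CDS/exon records.
#' @param presence presence-state matrix from [classify_presence()] for
#'   these elements (rownames = element names).
#' @param min_species minimum number of non-reference species in which the
#'   element must be present.
#' @return the retained subset of `elements`.
#' @export
define_cnes <- function(elements, ann, presence, min_species = 1L) {
  cod <- ann[ann$type %in% c("CDS", "exon"), , drop = FALSE]
  noncoding <- vapply(seq_len(nrow(elements)), function(i) {
    length(overlapping_idx(cod, elements$seqname[i], elements$start[i],
                           elements$end[i])) == 0L
  }, TRUE)
  st <- presence[elements$name, , drop = FALSE]
  npresent <- rowSums(st == "present_by_alignment" | st == "present_by_rescue")
  elements[noncoding & npresent >= min_species, , drop = FALSE]
}
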