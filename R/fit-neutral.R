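#' Fit a neutral GTR model and branch lengths from 4D-site columns
#'
#' Equilibrium frequencies are set to the (weighted) empirical base
#' frequencies of the columns. Exchangeabilities and branch lengths are
#' then estimated by maximizing the pruning log-likelihood on the fixed
#' topology: coordinate ascent alternating Brent line searches on each
#' branch (bounds `[1e-6, 10]`) with a bounded quasi-Newton step on the
#' log exchangeabilities (GT fixed at 1), until the improvement per sweep
#' falls below `tol`.
#'
#' When the topology is rooted with a two-child root, only the sum of the
#' two root-adjacent branch lengths is identifiable under a reversible
#' model; one of them is pinned near zero so its sibling carries the sum.
#'
#' @param columns a [site_columns()] object (e.g. from
#'   [extract_4d_columns()]).
#' @param topology `ape::phylo`; its branch lengths (if any) are ignored.
#' @param init_branch starting branch length.
#' @param tol convergence tolerance on the total log-likelihood.
#' @param max_sweeps cap on coordinate-ascent sweeps.
#' @return list with `model` (a `gtr_model`), `tree` (branch lengths
#'   fitted), `loglik` and `init_loglik`.
#' @export
fit_neutral_model <- function(columns, topology, init_branch = 0.1,
                              tol = 1e-6, max_sweeps = 30L) {
  stopifnot(inherits(columns, "site_columns"))
  keep <- colSums(!is.na(columns$states)) > 0L
  columns$states <- columns$states[, keep, drop = FALSE]
  columns$weights <- columns$weights[keep]
  if (ncol(columns$states) == 0L) stop("all columns are gap/missing-only")
  variable <- apply(columns$states, 2, function(s) {
    u <- unique(s[!is.na(s)]); length(u) > 1L
  })
  if (!any(variable))
    stop("no variable 4D columns: more data are needed to fit a model")

  obs <- columns$states[!is.na(columns$states)]
  w <- matrix(columns$weights, nrow = nrow(columns$states),
              ncol = ncol(columns$states), byrow = TRUE)[!is.na(columns$states)]
  cnt <- vapply(1:4, function(b) sum(w[obs == b]), 0) + 1e-8
  pi_hat <- cnt / sum(cnt)

  tree <- topology
  ne <- nrow(tree$edge)
  tree$edge.length <- rep(init_branch, ne)
  root <- length(tree$tip.label) + 1L
  root_children <- which(tree$edge[, 1] == root)
  fixed_edge <- integer(0)
  if (length(root_children) == 2L) {
    fixed_edge <- root_children[2]
    tree$edge.length[fixed_edge] <- 1e-8
  }
  free_edges <- setdiff(seq_len(ne), fixed_edge)

  rates <- rep(1, 6)
  model <- gtr_model(pi_hat, rates)
  ll <- total_log_likelihood(tree, model, columns)
  init_ll <- ll

  for (sweep in seq_len(max_sweeps)) {
    ll_before <- ll
    for (k in free_edges) {
      f <- function(t) {
        tree$edge.length[k] <- t
        -total_log_likelihood(tree, model, columns)
      }
      opt <- stats::optimize(f, interval = c(1e-6, 10), tol = 1e-5)
      # Brent never lands on the boundary; saturated data should
      tree$edge.length[k] <- if (f(1e-6) <= opt$objective) 1e-6
                             else opt$minimum
    }
    g <- function(lr) {
      m <- gtr_model(pi_hat, c(exp(lr), 1))
      -total_log_likelihood(tree, m, columns)
    }
    opt <- stats::optim(log(rates[1:5]), g, method = "L-BFGS-B",
                        lower = log(1e-3), upper = log(1e3),
                        control = list(maxit = 25))
    rates <- c(exp(opt$par), 1)
    model <- gtr_model(pi_hat, rates)
    ll <- total_log_likelihood(tree, model, columns)
    if (ll - ll_before < tol) break
  }
  if (ll < init_ll) stop("optimizer decreased the likelihood (internal error)")
  list(model = model, tree = tree, loglik = ll, init_loglik = init_ll)
}

#' Relative (lineage) rate test
#'
#' Counts substitutions unique to each of two ingroup sequences relative
#' to an outgroup: `m1` = sites where a differs from the outgroup while b
#' matches it, `m2` the mirror image. Under equal rates m1 and m2 have
#' equal expectation, giving the chi-square statistic
#' `(m1 - m2)^2 / (m1 + m2)` on 1 df (0 when both counts are 0). Columns
#' containing `N` or `-` are excluded and counted.
#'
#' @param a,b,outgroup equal-length DNA strings or character vectors.
#' @return object of class `rate_test`: `m1`, `m2`, `chisq`, `p_value`,
#'   `n_used`, `n_excluded`.
#' @export
relative_rate_test <- function(a, b, outgroup) {
  tochar <- function(x) if (length(x) == 1L && nchar(x[1]) > 1L)
    strsplit(toupper(x), "", fixed = TRUE)[[1]] else toupper(x)
  a <- tochar(a); b <- tochar(b); o <- tochar(outgroup)
  if (length(a) != length(b) || length(a) != length(o))
    stop("sequences must have equal length")
  ok <- a %in% BASES & b %in% BASES & o %in% BASES
  m1 <- sum(a[ok] != o[ok] & b[ok] == o[ok])
  m2 <- sum(b[ok] != o[ok] & a[ok] == o[ok])
  chisq <- if (m1 + m2 > 0) (m1 - m2)^2 / (m1 + m2) else 0
  res <- list(m1 = m1, m2 = m2, chisq = chisq,
              p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
              n_used = sum(ok), n_excluded = sum(!ok))
  class(res) <- "rate_test"
  res
}

#' @export
print.rate_test <- function(x, ...) {
  cat(sprintf("relative rate test: m1=%d m2=%d chisq=%.4g p=%.4g (%d sites, %d excluded)\n",
              x$m1, x$m2, x$chisq, x$p_value, x$n_used, x$n_excluded))
  invisible(x)
}
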