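BASES <- c("A", "C", "G", "T")
RATE_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' General time-reversible (GTR) substitution model
#'
#' Builds the normalized GTR rate matrix from equilibrium frequencies and
#' the six symmetric exchangeabilities. `Q[i,j] = s[ij] * pi[j]` off the
#' diagonal; the diagonal makes rows sum to zero and the whole matrix is
#' scaled so the expected substitution rate at stationarity,
#' `-sum(pi * diag(Q))`, equals 1 — branch lengths are then in expected
#' substitutions per site.
#'
#' @param pi equilibrium base frequencies (A,C,G,T); normalized to sum 1.
#' @param rates the six exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @return object of class `gtr_model` with elements `pi`, `rates`, `Q`
#'   and the eigendecomposition used for matrix exponentials.
#' @export
gtr_model <- function(pi = rep(0.25, 4), rates = rep(1, 6)) {
  stopifnot(length(pi) == 4L, length(rates) == 6L, all(pi > 0), all(rates > 0))
  pi <- pi / sum(pi)
  names(pi) <- BASES
  names(rates) <- RATE_NAMES
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S["A", "C"] <- S["C", "A"] <- rates["AC"]
  S["A", "G"] <- S["G", "A"] <- rates["AG"]
  S["A", "T"] <- S["T", "A"] <- rates["AT"]
  S["C", "G"] <- S["G", "C"] <- rates["CG"]
  S["C", "T"] <- S["T", "C"] <- rates["CT"]
  S["G", "T"] <- S["T", "G"] <- rates["GT"]
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-pi * diag(Q))          # mean rate 1
  dimnames(Q) <- list(BASES, BASES)
  # reversible Q is similar to the symmetric B = D^{1/2} Q D^{-1/2}
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  obj <- list(pi = pi, rates = rates / rates["GT"], Q = Q,
              evec = diag(1 / d) %*% eig$vectors,
              ivec = t(eig$vectors) %*% diag(d),
              eval = eig$values)
  class(obj) <- "gtr_model"
  obj
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR model\n  pi:", sprintf("%s=%.4f", BASES, x$pi), "\n  rates:",
      sprintf("%s=%.4g", RATE_NAMES, x$rates), "\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed through the eigendecomposition of the symmetrized rate matrix,
#' which guarantees a valid stochastic matrix for any `t >= 0`.
#'
#' @param model a `gtr_model`.
#' @param t branch length (expected substitutions/site), scalar `>= 0`.
#' @return 4x4 matrix with rows summing to 1.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$evec %*% (exp(model$eval * t) * model$ivec)
  P[P < 0] <- 0                        # clip fp noise
  P / rowSums(P)
}

## JSON-serializable neutral model (model + tree)
#' Write / read a fitted model (pi, exchangeabilities, tree) as JSON
#' @param model a `gtr_model`.
#' @param tree an `ape::phylo` with branch lengths.
#' @param path output path.
#' @export
write_model_json <- function(model, tree, path) {
  obj <- list(pi = as.list(model$pi), rates = as.list(model$rates),
              tree = ape::write.tree(tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns `list(model =, tree =)`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  list(model = gtr_model(unlist(obj$pi), unlist(obj$rates)),
       tree = ape::read.tree(text = obj$tree))
}
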