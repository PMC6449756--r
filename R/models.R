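# Empirical amino-acid substitution models.

#' Empirical amino-acid substitution model
#'
#' Builds the instantaneous rate matrix and stationary frequencies of an
#' empirical reversible model (default LG). The rate matrix is normalized
#' to a mean rate of one substitution per site, so branch lengths are in
#' expected substitutions/site.
#'
#' @param name Model name understood by phangorn (e.g. `"LG"`, `"WAG"`,
#'   `"JTT"`).
#' @return An object of class `aa_model`: list with `name`, `Q` (20x20
#'   rate matrix, rows summing to zero), `pi` (stationary frequencies,
#'   summing to one) and `exchangeabilities` (the symmetric factor).
#' @examples
#' m <- aa_model("LG")
#' range(rowSums(m$Q))  # ~0
#' @export
aa_model <- function(name = "LG") {
  obj <- tryCatch(utils::getFromNamespace(paste0(".", name), "phangorn"),
                  error = function(e) stop("unknown amino-acid model: ", name))
  s <- matrix(0, 20L, 20L, dimnames = list(AA_LEVELS, AA_LEVELS))
  s[lower.tri(s)] <- obj$Q
  s <- s + t(s)
  pi <- obj$bf
  names(pi) <- AA_LEVELS
  Q <- s * rep(pi, each = 20L)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  stopifnot(all(abs(rowSums(Q)) < 1e-10), all(pi > 0),
            abs(sum(pi) - 1) < 1e-8)
  # detailed balance: pi_i Q_ij == pi_j Q_ji
  db <- pi * Q - t(pi * Q)
  stopifnot(max(abs(db)) < 1e-10)
  structure(list(name = name, Q = Q, pi = pi, exchangeabilities = s),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino-acid substitution model", x$name,
      "(20x20 rate matrix, mean rate 1 subst/site)\n")
  invisible(x)
}
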