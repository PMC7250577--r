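#' Construct a substitution model
#'
#' @param exchangeabilities symmetric 20x20 non-negative matrix (diagonal
#'   ignored), in the canonical residue order [AA_ALPHABET20].
#' @param equilibriumFreqs positive length-20 vector; renormalized to sum
#'   to 1.
#' @param gammaShape positive gamma shape for among-site rate variation.
#' @param nRateCategories number of discrete gamma categories; 1 turns rate
#'   heterogeneity off.
#' @param name label for printing.
#' @return a [SubstitutionModel-class] object.
#' @export
substitutionModel <- function(exchangeabilities, equilibriumFreqs,
                              gammaShape = 1, nRateCategories = 4L,
                              name = "custom") {
  fr <- equilibriumFreqs / sum(equilibriumFreqs)
  ex <- (exchangeabilities + t(exchangeabilities)) / 2
  diag(ex) <- 0
  dimnames(ex) <- list(AA_ALPHABET20, AA_ALPHABET20)
  names(fr) <- AA_ALPHABET20
  new("SubstitutionModel", exchangeabilities = ex, equilibriumFreqs = fr,
      gammaShape = as.numeric(gammaShape),
      nRateCategories = as.integer(nRateCategories), name = name)
}

#' Equal-rates (Poisson) amino-acid model
#'
#' All exchangeabilities equal and uniform frequencies. Under this model the
#' probability that a site differs between two sequences at total distance t
#' has the closed form (19/20)(1 - exp(-20 t / 19)), which the test suite
#' uses as an independent oracle.
#'
#' @inheritParams substitutionModel
#' @return a [SubstitutionModel-class].
#' @export
poissonModel <- function(gammaShape = 1, nRateCategories = 1L) {
  substitutionModel(matrix(1, 20, 20), rep(1 / 20, 20), gammaShape,
                    nRateCategories, name = "Poisson")
}

#' LG amino-acid model, optionally with observed frequencies ("+F")
#'
#' Uses the Le & Gascuel (2008) exchangeabilities as shipped with phangorn.
#'
#' @param equilibriumFreqs optional frequency vector (e.g. observed
#'   frequencies of the data alignment, the "+F" convention); defaults to
#'   the LG model frequencies.
#' @inheritParams substitutionModel
#' @return a [SubstitutionModel-class].
#' @export
lgModel <- function(equilibriumFreqs = NULL, gammaShape = 1,
                    nRateCategories = 4L) {
  lg <- utils::getFromNamespace(".LG", "phangorn")
  ex <- matrix(0, 20, 20)
  ex[lower.tri(ex)] <- lg$Q
  ex <- ex + t(ex)
  # phangorn stores amino acids in the same ARND... order used here
  fr <- if (is.null(equilibriumFreqs)) unname(lg$bf) else equilibriumFreqs
  substitutionModel(ex, fr, gammaShape, nRateCategories,
                    name = if (is.null(equilibriumFreqs)) "LG" else "LG+F")
}

#' Observed amino-acid frequencies of an alignment
#'
#' Gaps and X are ignored; a background pseudocount avoids zero frequencies.
#'
#' @param alignment a [SeqAlignment-class].
#' @param pseudo pseudocount added to each residue.
#' @return length-20 frequency vector in canonical order.
#' @export
observedFreqs <- function(alignment, pseudo = 0.5) {
  codes <- aaCodes(paste(alignment@rows, collapse = ""))
  cnt <- tabulate(codes[!is.na(codes)], nbins = 20) + pseudo
  stats::setNames(cnt / sum(cnt), AA_ALPHABET20)
}

# discrete gamma category rates, mean 1
gammaCategoryRates <- function(shape, ncat) {
  if (ncat == 1L) return(1)
  r <- phangorn::discrete.gamma(shape, ncat)
  r / mean(r) # guard the mean-1 contract against quadrature error
}

# normalized rate matrix Q (expected substitutions per unit time = 1)
modelQ <- function(model) {
  ex <- model@exchangeabilities
  pi <- model@equilibriumFreqs
  Q <- ex * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# spectral decomposition of Q via the symmetrized form, plus the rate mixture;
# the list feeds both the C++ engine and the R simulator. Memoized: the
# decomposition is requested for the same model thousands of times inside
# parametric-bootstrap loops.
.eigCache <- new.env(parent = emptyenv())

modelEigen <- function(model) {
  key <- rlang::hash(list(model@exchangeabilities, model@equilibriumFreqs,
                          model@gammaShape, model@nRateCategories))
  hit <- .eigCache[[key]]
  if (!is.null(hit)) return(hit)
  out <- modelEigenCompute(model)
  .eigCache[[key]] <- out
  out
}

modelEigenCompute <- function(model) {
  Q <- modelQ(model)
  pi <- model@equilibriumFreqs
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  U <- es$vectors / d
  Uinv <- t(es$vectors) * rep(d, each = 20)
  rates <- gammaCategoryRates(model@gammaShape, model@nRateCategories)
  list(U = U, Uinv = Uinv, lambda = es$values, pi = unname(pi),
       rates = as.numeric(rates),
       rweights = rep(1 / length(rates), length(rates)))
}

# transition matrix P(t) for one eigen system (no rate scaling applied)
transitionMatrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
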