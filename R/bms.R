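# Random-effects Bayesian model selection over curve families. Model
# frequencies in the population get a Dirichlet posterior via the standard
# variational update; the exceedance probability (probability that a family
# is the most frequent) is estimated by seeded Monte-Carlo sampling of that
# Dirichlet; the Bayes omnibus risk (probability that all families are
# equally frequent and the evidence differences are chance) comes from the
# free-energy comparison of the null and random-effects models, and protects
# the exceedance probability: PXP = EP * (1 - BOR) + BOR / K.

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet-multinomial update over a subjects-by-families
#' log-evidence matrix, iterated to convergence from a flat Dirichlet
#' (`alpha0 = 1` per family by default). Expected model frequencies are
#' `alpha / sum(alpha)`; exceedance probabilities are estimated by
#' Monte-Carlo sampling of the Dirichlet posterior.
#'
#' @param log_evidences numeric matrix, subjects x families (>= 2 of each);
#'   column names are the family labels.
#' @param alpha0 prior Dirichlet concentration per family.
#' @param n_samples Monte-Carlo samples for the exceedance probability.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return List of class `"bms_result"`: `families`, `alpha`,
#'   `expected_freq`, `ep`, `attributions` (subjects x families posterior
#'   model probabilities), plus the settings used. [protected_ep()] adds
#'   `bor` and `pxp`.
#' @references Stephan et al. (2009) NeuroImage 46:1004-1017; Rigoux et al.
#'   (2014) NeuroImage 84:971-985.
#' @export
rfx_bms <- function(log_evidences, alpha0 = 1, n_samples = 1e6, seed = 1L) {
  L <- as.matrix(log_evidences)
  if (nrow(L) < 2L || ncol(L) < 2L)
    stop("need >= 2 subjects and >= 2 families")
  if (any(!is.finite(L))) {
    bad <- which(!is.finite(L), arr.ind = TRUE)[1, ]
    stop("non-finite log evidence for subject ",
         rownames(L)[bad[1]] %||% bad[1], ", family ",
         colnames(L)[bad[2]] %||% bad[2])
  }
  K <- ncol(L)
  n <- nrow(L)
  if (is.null(colnames(L))) colnames(L) <- paste0("family", seq_len(K))
  fam <- colnames(L)
  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  u <- matrix(1 / K, n, K)
  for (it in seq_len(500L)) {
    ln_u <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    ln_u <- ln_u - apply(ln_u, 1, .logsumexp)
    u <- exp(ln_u)
    alpha_new <- a0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-10) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  names(alpha) <- fam
  ep <- .ep_dirichlet_mc(alpha, n_samples, seed)
  dimnames(u) <- list(rownames(L), fam)
  structure(list(families = fam, alpha = alpha,
                 expected_freq = alpha / sum(alpha), ep = ep,
                 attributions = u, log_evidences = L, alpha0 = alpha0,
                 n_samples = n_samples, seed = seed),
            class = "bms_result")
}

# Monte-Carlo exceedance probability of a Dirichlet(alpha) vector.
.ep_dirichlet_mc <- function(alpha, n_samples, seed) {
  K <- length(alpha)
  .with_seed(seed, {
    G <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    wins <- max.col(G, ties.method = "first")
    ep <- tabulate(wins, nbins = K) / n_samples
    names(ep) <- names(alpha)
    ep
  })
}

# Free energy of the fitted RFX model (variational lower bound).
.bms_free_energy <- function(L, alpha, a0, u) {
  Elogr <- digamma(alpha) - digamma(sum(alpha))
  elj <- lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * Elogr) +
    sum(u * (L + matrix(Elogr, nrow(L), length(alpha), byrow = TRUE)))
  ent_r <- sum(lgamma(alpha)) - lgamma(sum(alpha)) -
    sum((alpha - 1) * Elogr)
  lu <- log(u)
  lu[u == 0] <- 0
  ent_z <- -sum(u * lu)
  elj + ent_r + ent_z
}

#' Bayes omnibus risk and protected exceedance probability
#'
#' The null model fixes all family frequencies at 1/K; its evidence is the
#' sum over subjects of the log average model likelihood. The Bayes omnibus
#' risk (BOR) is the posterior probability of that null against the
#' random-effects model, from their free energies; the protected exceedance
#' probability is `PXP = EP * (1 - BOR) + BOR / K`.
#'
#' @param bms a [rfx_bms()] result.
#' @return The same object with `f_rfx`, `f_null`, `bor` and `pxp` added.
#' @export
protected_ep <- function(bms) {
  stopifnot(inherits(bms, "bms_result"))
  L <- bms$log_evidences
  K <- length(bms$families)
  f_rfx <- .bms_free_energy(L, bms$alpha, rep(bms$alpha0, K),
                            bms$attributions)
  f_null <- sum(apply(L, 1, .logsumexp) - log(K))
  bor <- 1 / (1 + exp(f_rfx - f_null))
  bms$f_rfx <- f_rfx
  bms$f_null <- f_null
  bms$bor <- bor
  bms$pxp <- bms$ep * (1 - bor) + bor / K
  bms
}

#' Per-subject model attributions
#'
#' Posterior model probabilities per subject with the argmax family; exact
#' ties are broken by the fixed family order of the evidence matrix columns
#' and reported in the `tie` column.
#'
#' @param bms a [rfx_bms()] result.
#' @return data.frame: `subject_id`, one probability column per family,
#'   `best_family`, `tie`.
#' @export
attribute_models <- function(bms) {
  stopifnot(inherits(bms, "bms_result"))
  u <- bms$attributions
  best <- apply(u, 1, function(p) which(p >= max(p) - 1e-12)[1])
  tie <- apply(u, 1, function(p) sum(p >= max(p) - 1e-12) > 1L)
  out <- data.frame(subject_id = rownames(u) %||%
                      as.character(seq_len(nrow(u))),
                    u, best_family = bms$families[best], tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq_len(ncol(u)) + 1L] <- bms$families
  out
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$families), "families,",
      nrow(x$attributions), "subjects\n")
  tab <- rbind(`expected freq` = x$expected_freq, EP = x$ep)
  if (!is.null(x$pxp)) tab <- rbind(tab, PXP = x$pxp)
  print(round(tab, 4))
  if (!is.null(x$bor)) cat("BOR:", signif(x$bor, 4), "\n")
  invisible(x)
}
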