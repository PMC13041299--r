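# Independent adaptive Gauss-Hermite quadrature evaluation of the marginal
# likelihood, built on the pure-R structural model. Serves as the accuracy
# oracle for the Laplace approximation used in estimation; it shares no code
# with the C++ objective.

# Golub-Welsch nodes/weights for the physicists' Hermite weight exp(-x^2)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Adaptive Gauss-Hermite quadrature marginal objective (oracle)
#'
#' Evaluates the same -2 log marginal likelihood as [qtc_objective()] by
#' adaptive Gauss-Hermite quadrature over the active random-effect
#' dimensions: per subject the integrand's mode and curvature are located
#' numerically and the tensor Gauss-Hermite rule is centred and scaled
#' there. Implemented entirely in R on top of [predict_qtcf()], so it is an
#' independent accuracy oracle for the C++ Laplace approximation on small
#' problems; the tensor grid limits it to at most two active
#' random-effect dimensions.
#'
#' @inheritParams qtc_objective
#' @param nodes quadrature nodes per dimension.
#' @return scalar objective (-2 log marginal likelihood + prior penalty).
#' @export
qtc_objective_gh <- function(data, params, priors = NULL,
                             random = "base", nodes = 64) {
  data <- prepare_qtc_data(data)
  validate_qtc_params(params)
  if (length(random) > 2L)
    stop("quadrature oracle supports at most 2 random-effect dimensions")
  random <- match.arg(random, QTC_ETA_NAMES, several.ok = TRUE)
  om_all <- c(base = params$omega_base, ss = params$omega_ss,
              ec50_cfz = params$omega_ec50_cfz,
              ec50_m2 = params$omega_ec50_m2, eps = params$omega_eps)
  om <- om_all[random]
  if (any(om <= 0)) stop("active random effects need positive omegas")
  d <- length(random)
  gh <- gauss_hermite(nodes)
  if (d == 1L) {
    X <- matrix(gh$nodes, ncol = 1)
    lw <- log(gh$weights)
  } else {
    X <- as.matrix(expand.grid(gh$nodes, gh$nodes))
    # expand.grid varies its first factor fastest
    lw <- log(gh$weights[rep(seq_len(nodes), times = nodes)]) +
      log(gh$weights[rep(seq_len(nodes), each = nodes)])
  }

  total <- 0
  for (id in unique(data$ID)) {
    rec <- data[data$ID == id, , drop = FALSE]
    # joint negative log density of (data, eta) as a function of the
    # active eta dimensions
    njoint <- function(ev) {
      eta <- setNames(numeric(5), QTC_ETA_NAMES)
      eta[random] <- ev
      em <- matrix(eta, 1, 5, dimnames = list(id, QTC_ETA_NAMES))
      pred <- predict_qtcf(rec, params, em)
      sdv <- params$sigma_add * exp(eta["eps"]) / sqrt(rec$NREP)
      -sum(dnorm(rec$QTCF_MS, pred, sdv, log = TRUE)) -
        sum(dnorm(ev, 0, om, log = TRUE))
    }
    opt <- nlminb(numeric(d), njoint)
    H <- stats::optimHess(opt$par, njoint)
    Sig <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (is.null(Sig) || any(!is.finite(Sig)) ||
        any(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values <= 0))
      Sig <- diag(om^2, d)                       # fallback: prior scale
    L <- chol(Sig)                               # upper: Sig = t(L) %*% L
    Z <- sweep(X %*% (sqrt(2) * L), 2, opt$par, `+`)
    lg <- -apply(Z, 1, njoint)
    # log integral of exp(-njoint) over eta (adaptive GH)
    ls <- d / 2 * log(2) + sum(log(diag(L))) +
      log_sum_exp(lw + rowSums(X^2) + lg)
    total <- total + ls
  }
  pen <- 0
  if (!is.null(priors)) {
    natv <- qtc_params_to_natural(params)
    for (nm in names(priors)) {
      if (!nm %in% names(natv))
        stop("prior on unknown parameter: ", nm)
      pen <- pen + ((natv[[nm]] - priors[[nm]]["mean"]) /
                      priors[[nm]]["sd"])^2
    }
  }
  -2 * total + unname(pen)
}
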