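#' Broad-sense heritability from panel vs parental variance
#'
#' H2 = (sigma_R^2 - sigma_P^2) / sigma_R^2, where sigma_R^2 is the variance
#' among the recombinant-panel phenotypic values and sigma_P^2 the variance
#' among the parental phenotypic values. The panel strains differ both
#' genetically and by measurement noise, the (two) parents essentially only
#' by noise, so the excess panel variance is attributed to genetics. The
#' literal pooled-parental reading conflates the between-parent genetic
#' difference with noise, so a within-strain-pooled alternative is available
#' via `pool_within`.
#'
#' @param riail_values numeric vector of panel phenotype values.
#' @param parental_values numeric vector of pooled parental values, or (when
#'   `pool_within = TRUE`) a list of per-parent replicate vectors whose
#'   within-strain variances are pooled.
#' @param pool_within pool within-parent variances instead of taking the
#'   variance of all parental values together. Default `FALSE` (literal
#'   definition).
#' @return H2 clamped to [0, 1]; attribute `raw` keeps the unclamped value,
#'   `sigma_R2` and `sigma_P2` the two variances.
#' @examples
#' broad_sense_h2(c(0, 1, 2, 3), c(1, 2))  # sR2 = 5/3, sP2 = 0.5
#' @export
broad_sense_h2 <- function(riail_values, parental_values, pool_within = FALSE) {
  riail_values <- riail_values[!is.na(riail_values)]
  if (length(riail_values) < 2) stop("need at least 2 panel values")
  s_r2 <- stats::var(riail_values)
  if (s_r2 == 0) stop("panel variance is zero; H2 undefined")
  if (pool_within) {
    stopifnot(is.list(parental_values))
    vs <- lapply(parental_values, function(v) v[!is.na(v)])
    if (any(lengths(vs) < 2)) stop("need at least 2 values per parent")
    df <- lengths(vs) - 1L
    s_p2 <- sum(df * vapply(vs, stats::var, numeric(1))) / sum(df)
  } else {
    pv <- unlist(parental_values)
    pv <- pv[!is.na(pv)]
    if (length(pv) < 2) stop("need at least 2 parental values")
    s_p2 <- stats::var(pv)
  }
  raw <- (s_r2 - s_p2) / s_r2
  out <- min(max(raw, 0), 1)
  attr(out, "raw") <- raw
  attr(out, "sigma_R2") <- s_r2
  attr(out, "sigma_P2") <- s_p2
  out
}

#' Additive relatedness kernel from genotypes
#'
#' Entry (s, t) is the Pearson correlation of the two strains' marker
#' vectors. A strain with zero genotype variance (all markers from one
#' parent) has no defined correlation; its entries fall back to the
#' match-based similarity 2 * (fraction of agreeing markers) - 1, which
#' coincides with the correlation convention for parental vectors, and the
#' strain is flagged with a warning.
#'
#' @param geno a `geno_matrix` (>= 2 markers).
#' @return Strains x strains symmetric matrix of class `relatedness`
#'   (`kind` attribute "additive"), diagonal 1.
#' @export
additive_kernel <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  G <- geno$calls
  if (ncol(G) < 2) stop("need at least 2 markers")
  A <- suppressWarnings(stats::cor(t(G), use = "pairwise.complete.obs"))
  sds <- apply(G, 1, stats::sd, na.rm = TRUE)
  flat <- which(sds == 0)
  if (length(flat)) {
    warning(length(flat), " strain(s) with zero genotype variance; ",
            "using match-based similarity for them")
    for (s in flat) {
      agree <- colMeans(t(G) == G[s, ], na.rm = TRUE)  # per-strain agreement
      A[s, ] <- 2 * agree - 1
      A[, s] <- A[s, ]
    }
  }
  diag(A) <- 1
  structure(A, kind = "additive", class = c("relatedness", "matrix", "array"))
}

#' Pairwise-interaction kernel (Hadamard product)
#'
#' The elementwise (Hadamard) square of the additive relatedness matrix:
#' the covariance kernel of pairwise marker-product effects. By the Schur
#' product theorem it is positive semidefinite whenever the additive kernel
#' is.
#'
#' @param A an additive [additive_kernel()] matrix.
#' @return Symmetric matrix of class `relatedness` (`kind` "interaction").
#' @export
interaction_kernel <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  structure(unclass(A) * unclass(A), kind = "interaction",
            class = c("relatedness", "matrix", "array"))
}

# Negative restricted log-likelihood of y = mu + sum_k u_k + e with
# cov(u_k) = s2_k K_k. theta = log variances (last entry is the residual).
neg_reml <- function(theta, y, kernels) {
  s2 <- exp(theta)
  n <- length(y)
  V <- diag(s2[length(s2)], n)
  for (k in seq_along(kernels)) V <- V + s2[k] * kernels[[k]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  xvx <- sum(Vi_1)
  if (xvx <= 0) return(1e10)
  beta <- sum(Vi_y) / xvx
  yPy <- sum(y * Vi_y) - xvx * beta^2
  0.5 * (logdetV + log(xvx) + yPy)
}

#' Variance-component heritability by restricted maximum likelihood
#'
#' Fits y = mu + a + (i) + e with cov(a) = s2_A * A, cov(i) = s2_I *
#' (A o A) (Hadamard interaction kernel; two-component model only), and
#' cov(e) = s2_E * I, by direct optimization of the restricted
#' log-likelihood over log-variances. Narrow-sense heritability is
#' s2_A / (s2_A + s2_I + s2_E); the interaction fraction is defined
#' analogously. The two-component fit is initialized at the one-component
#' solution (with a tiny interaction variance), so its likelihood can never
#' fall below the nested model's.
#'
#' @param y numeric phenotype vector over the kernel's strains.
#' @param A additive relatedness matrix from [additive_kernel()].
#' @param with_interaction add the Hadamard interaction component?
#'   Default `FALSE`.
#' @param jitter diagonal jitter added to a kernel that fails a Cholesky
#'   check. Default 1e-6.
#' @return Object of class `vc_fit`: variance components `sigma2` (named),
#'   `h2_additive`, `interaction_fraction`, `residual_fraction`, `loglik`
#'   (restricted, up to a constant), `model` ("one-component" or
#'   "two-component"), `convergence`.
#' @export
fit_variance_components <- function(y, A, with_interaction = FALSE,
                                    jitter = 1e-6) {
  ok <- !is.na(y)
  y <- y[ok]
  A <- unclass(A)[ok, ok, drop = FALSE]
  n <- length(y)
  if (n < 10) stop("need at least 10 strains")
  if (stats::sd(y) == 0) stop("phenotype has zero variance")
  psd_fix <- function(K) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      warning("kernel not positive semidefinite; adding diagonal jitter")
      K <- K + diag(jitter, nrow(K))
    }
    K
  }
  kernels <- list(additive = psd_fix(A))
  if (with_interaction) kernels$interaction <- psd_fix(A * A)
  vy <- stats::var(y)
  nk <- length(kernels)
  # one-component start: equal split
  start1 <- log(rep(vy / 2, 2))
  opt1 <- stats::optim(start1, neg_reml, y = y, kernels = kernels["additive"],
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
  if (!with_interaction) {
    s2 <- stats::setNames(exp(opt1$par), c("additive", "residual"))
    conv <- opt1$convergence
    ll <- -opt1$value
  } else {
    start2 <- c(opt1$par[1L], log(vy * 1e-4), opt1$par[2L])
    opt2 <- stats::optim(start2, neg_reml, y = y, kernels = kernels,
                         method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-10))
    # also try an equal split start; keep the better optimum
    opt2b <- stats::optim(log(rep(vy / 3, 3)), neg_reml, y = y,
                          kernels = kernels, method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-10))
    if (opt2b$value < opt2$value) opt2 <- opt2b
    if (opt2$value > opt1$value) {   # guard: nested model can't beat full
      opt2$par <- c(opt1$par[1L], -30, opt1$par[2L])
      opt2$value <- opt1$value
    }
    s2 <- stats::setNames(exp(opt2$par), c("additive", "interaction", "residual"))
    conv <- opt2$convergence
    ll <- -opt2$value
  }
  tot <- sum(s2)
  structure(list(sigma2 = s2,
                 h2_additive = unname(s2["additive"] / tot),
                 interaction_fraction =
                   if (with_interaction) unname(s2["interaction"] / tot) else 0,
                 residual_fraction = unname(s2["residual"] / tot),
                 loglik = ll,
                 model = if (with_interaction) "two-component" else "one-component",
                 convergence = conv, n = n),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Variance-component fit (", x$model, ", REML, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  additive fraction (h2):    %.3f\n", x$h2_additive))
  if (x$model == "two-component")
    cat(sprintf("  interaction fraction:      %.3f\n", x$interaction_fraction))
  cat(sprintf("  residual fraction:         %.3f\n", x$residual_fraction))
  cat(sprintf("  restricted log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' @export
coef.vc_fit <- function(object, ...) {
  c(h2_additive = object$h2_additive,
    interaction_fraction = object$interaction_fraction,
    residual_fraction = object$residual_fraction)
}

#' @export
logLik.vc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2) + 1L, class = "logLik")
}

#' @export
summary.vc_fit <- function(object, ...) {
  out <- c(coef(object), loglik = object$loglik, n = object$n)
  class(out) <- "summary.vc_fit"
  out
}

#' @export
print.summary.vc_fit <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Simulate a trait from the variance-component model
#'
#' Draws y = a + i + e with cov(a) = `h2_additive` * A, cov(i) =
#' `interaction` * (A o A), cov(e) = residual * I (residual = 1 - additive
#' - interaction), via eigendecomposition of the (PSD) kernels -- the
#' generative counterpart of [fit_variance_components()], used for
#' parameter-recovery checks.
#'
#' @param A additive relatedness matrix.
#' @param h2_additive,interaction variance fractions (sum <= 1).
#' @param seed integer seed.
#' @return Numeric trait vector of length `nrow(A)`.
#' @export
simulate_vc_trait <- function(A, h2_additive, interaction = 0, seed) {
  if (h2_additive + interaction > 1) stop("variance fractions exceed 1")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  A <- unclass(A)
  n <- nrow(A)
  draw <- function(K, s2) {
    e <- eigen(K, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    as.numeric(e$vectors %*% (sqrt(s2 * ev) * stats::rnorm(n)))
  }
  y <- draw(A, h2_additive)
  if (interaction > 0) y <- y + draw(A * A, interaction)
  y + stats::rnorm(n, 0, sqrt(1 - h2_additive - interaction))
}
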