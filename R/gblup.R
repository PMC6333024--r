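#' Impute missing dosages by the rounded marker mean
#'
#' Deterministic: each missing call is replaced by the marker's mean dosage
#' over non-missing calls, rounded to the nearest of 0/1/2 (ties round
#' half up, so a mean of exactly 0.5 becomes 1).
#'
#' @param W Dosage matrix (individuals x markers) with possible NAs.
#' @return The matrix with no missing values.
#' @export
impute_missing <- function(W) {
  nas <- which(colSums(is.na(W)) > 0)
  for (j in nas) {
    x <- W[, j]
    if (all(is.na(x)))
      stop("all-missing marker (should have been removed by QC): ",
           colnames(W)[j], call. = FALSE)
    W[is.na(x), j] <- min(2, max(0, floor(mean(x, na.rm = TRUE) + 0.5)))
  }
  W
}

#' Build the genomic mixed-model equations
#'
#' The ridge system for marker effects,
#' \deqn{[X'X, X'W; W'X, W'W + I \lambda] [b; m] = [X'y; W'y]}
#' with shrinkage \code{lambda = sigma_e2 / (sigma_g2 / nQ)} added to the
#' marker block diagonal: the genetic variance is split evenly over the
#' \code{nQ} loci assumed to carry it.
#'
#' @param y Response (corrected phenotypes), one value per individual.
#' @param X Fixed-effect design (default intercept).
#' @param W Marker dosage matrix 0/1/2, no missing values.
#' @param sigma_g2,sigma_e2 Genetic and residual variances.
#' @param nQ Assumed number of loci; defaults to \code{ncol(W)} (the
#'   standard ridge-BLUP equivalence).
#' @return List with \code{C} (coefficient matrix), \code{rhs},
#'   \code{lambda}, \code{p} (number of fixed effects) and dimensions.
#' @export
build_mme <- function(y, X = matrix(1, length(y), 1), W,
                      sigma_g2, sigma_e2, nQ = ncol(W)) {
  if (nQ <= 0) stop("nQ must be positive", call. = FALSE)
  if (sigma_g2 <= 0) stop("sigma_g2 must be positive", call. = FALSE)
  if (nrow(W) != length(y) || nrow(X) != length(y))
    stop("dimensions of y, X and W must agree", call. = FALSE)
  lambda <- sigma_e2 / (sigma_g2 / nQ)
  M <- cbind(X, W)
  C <- crossprod(M)
  p <- ncol(X)
  dk <- p + seq_len(ncol(W))
  C[cbind(dk, dk)] <- C[cbind(dk, dk)] + lambda
  list(C = C, rhs = crossprod(M, y), lambda = lambda, p = p,
       n = length(y), n_markers = ncol(W))
}

#' Solve the genomic mixed-model equations directly
#'
#' Exact dense solve of the ridge system from \code{\link{build_mme}};
#' the genomic breeding value of individual j is the dosage-weighted sum
#' of its marker effects, \code{gebv = W m}.
#'
#' @inheritParams build_mme
#' @return A \code{gblup_fit}: \code{b_hat}, \code{m_hat}, \code{gebv},
#'   \code{lambda}, \code{method = "direct"}.
#' @export
solve_direct <- function(y, X = matrix(1, length(y), 1), W,
                         sigma_g2, sigma_e2, nQ = ncol(W)) {
  mme <- build_mme(y, X, W, sigma_g2, sigma_e2, nQ)
  sol <- tryCatch(solve(mme$C, mme$rhs),
                  error = function(e) stop("singular MME system: ",
                                           conditionMessage(e), call. = FALSE))
  b_hat <- sol[seq_len(mme$p), 1]
  m_hat <- stats::setNames(sol[-seq_len(mme$p), 1], colnames(W))
  structure(list(b_hat = b_hat, m_hat = m_hat,
                 gebv = stats::setNames(drop(W %*% m_hat), rownames(W)),
                 lambda = mme$lambda, method = "direct"),
            class = "gblup_fit")
}

#' Solve the equivalent individual-level kernel model
#'
#' Fits y = Xb + g + e with Var(g) = sigma_g2 K by generalized least
#' squares on V = sigma_g2 K + sigma_e2 I; handles singular K without
#' inverting it. With \code{K = W W'} and \code{sigma_g2} set to the
#' per-marker variance \code{sigma_g2/nQ}, the fitted values equal the
#' marker-space GEBVs of \code{\link{solve_direct}}.
#'
#' @param y Response.
#' @param X Fixed design (default intercept).
#' @param K Symmetric positive semidefinite kernel (individuals x
#'   individuals).
#' @param sigma_g2 Variance multiplier of K.
#' @param sigma_e2 Residual variance.
#' @param jitter_tol Tolerance for negative kernel eigenvalues.
#' @return A \code{gblup_fit} with \code{method = "kernel"}; \code{gebv}
#'   holds the BLUP of g.
#' @export
solve_kernel <- function(y, X = matrix(1, length(y), 1), K,
                         sigma_g2, sigma_e2, jitter_tol = 1e-8) {
  if (!isSymmetric(unname(K), tol = 1e-8))
    stop("K must be symmetric", call. = FALSE)
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -jitter_tol * max(1, max(abs(K))))
    stop("K is not positive semidefinite", call. = FALSE)
  n <- length(y)
  V <- sigma_g2 * K + diag(sigma_e2, n)
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  b_hat <- drop(solve(XtVi %*% X, XtVi %*% y))
  resid <- y - drop(X %*% b_hat)
  gebv <- drop(sigma_g2 * K %*% (Vi %*% resid))
  structure(list(b_hat = b_hat, m_hat = NULL,
                 gebv = stats::setNames(gebv, rownames(K)),
                 lambda = sigma_e2 / sigma_g2, method = "kernel"),
            class = "gblup_fit")
}

#' Predict GEBVs of new individuals from a kernel fit
#'
#' BLUP of the genetic values of unphenotyped individuals given their
#' kernel rows against the training set: \code{g_new = sigma_g2 K_new
#' V^{-1} (y - X b)}.
#'
#' @param y,X Training response and fixed design.
#' @param K_train Training kernel (n x n).
#' @param K_new Cross-kernel of new individuals vs training (m x n).
#' @param sigma_g2,sigma_e2 Variances as in \code{\link{solve_kernel}}.
#' @return Numeric vector of m predicted GEBVs.
#' @export
predict_kernel <- function(y, X = matrix(1, length(y), 1), K_train, K_new,
                           sigma_g2, sigma_e2) {
  n <- length(y)
  V <- sigma_g2 * K_train + diag(sigma_e2, n)
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  b_hat <- drop(solve(XtVi %*% X, XtVi %*% y))
  drop(sigma_g2 * K_new %*% (Vi %*% (y - drop(X %*% b_hat))))
}

#' Gaussian kernel over marker genotypes
#'
#' \code{K_ij = exp(-d_ij^2 / theta)} with d the Euclidean marker distance;
#' the default bandwidth is the median squared distance between distinct
#' individuals.
#'
#' @param W Dosage matrix without missing values.
#' @param theta Bandwidth; default median squared pairwise distance.
#' @return Kernel matrix with unit diagonal.
#' @export
gaussian_kernel <- function(W, theta = NULL) {
  d2 <- as.matrix(stats::dist(W))^2
  if (is.null(theta)) theta <- stats::median(d2[upper.tri(d2)])
  if (theta <= 0) theta <- 1
  exp(-d2 / theta)
}

#' Gibbs sampler for the genomic ridge model
#'
#' Bayesian counterpart of \code{\link{solve_direct}}: block-samples
#' (b, m) from their joint normal full conditional and, unless variances
#' are fixed, the marker-effect and residual variances from scaled
#' inverse-chi-square full conditionals with weak priors
#' (nu0 = 4, scale matched to the initial variances). With fixed
#' variances the posterior mean of the GEBVs converges to the MME solution.
#'
#' @inheritParams build_mme
#' @param n_iter,burn_in,thin Chain settings.
#' @param fix_variances Keep sigma_g2/nQ and sigma_e2 fixed at their inputs.
#' @param nu0 Prior degrees of freedom for both variances.
#' @param seed Integer seed.
#' @return A \code{gblup_fit} with \code{method = "gibbs"}, posterior-mean
#'   effects and GEBVs, plus \code{posterior_sd} per individual and the
#'   retained \code{samples} of the variances.
#' @export
solve_gibbs <- function(y, X = matrix(1, length(y), 1), W,
                        sigma_g2, sigma_e2, nQ = ncol(W),
                        n_iter = 2000L, burn_in = 500L, thin = 1L,
                        fix_variances = FALSE, nu0 = 4, seed = 1L) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(y); p <- ncol(X); q <- ncol(W)
  M <- cbind(X, W)
  MtM <- crossprod(M)
  Mty <- crossprod(M, y)
  dk <- p + seq_len(q)

  s2m <- sigma_g2 / nQ   # per-marker effect variance
  s2e <- sigma_e2
  Sm0 <- s2m; Se0 <- s2e # prior scales anchored at the inputs

  keep <- seq(burn_in + 1L, n_iter, by = thin)
  gebv_sum <- gebv_sq <- numeric(n)
  eff_sum <- numeric(p + q)
  var_samp <- matrix(NA_real_, length(keep), 2,
                     dimnames = list(NULL, c("sigma_m2", "sigma_e2")))
  kept <- 0L

  theta <- numeric(p + q)
  for (it in seq_len(n_iter)) {
    C <- MtM / s2e
    C[cbind(dk, dk)] <- C[cbind(dk, dk)] + 1 / s2m
    ch <- chol(C)
    mu <- backsolve(ch, forwardsolve(t(ch), Mty / s2e))
    theta <- drop(mu + backsolve(ch, stats::rnorm(p + q)))
    if (any(!is.finite(theta))) stop("divergent chain", call. = FALSE)

    if (!fix_variances) {
      m <- theta[dk]
      s2m <- (sum(m^2) + nu0 * Sm0) / stats::rchisq(1, q + nu0)
      e <- y - drop(M %*% theta)
      s2e <- (sum(e^2) + nu0 * Se0) / stats::rchisq(1, n + nu0)
    }

    if (it %in% keep) {
      kept <- kept + 1L
      g <- drop(W %*% theta[dk])
      gebv_sum <- gebv_sum + g
      gebv_sq <- gebv_sq + g^2
      eff_sum <- eff_sum + theta
      var_samp[kept, ] <- c(s2m, s2e)
    }
  }

  gebv <- gebv_sum / kept
  post_sd <- sqrt(pmax(0, gebv_sq / kept - gebv^2))
  eff <- eff_sum / kept
  structure(list(b_hat = eff[seq_len(p)],
                 m_hat = stats::setNames(eff[dk], colnames(W)),
                 gebv = stats::setNames(gebv, rownames(W)),
                 posterior_sd = stats::setNames(post_sd, rownames(W)),
                 samples = var_samp, n_kept = kept,
                 lambda = s2e / s2m, method = "gibbs"),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit (", x$method, "): ", length(x$gebv), " GEBVs",
      if (!is.null(x$m_hat)) paste0(", ", length(x$m_hat), " marker effects"),
      "\n", sep = "")
  invisible(x)
}

#' Genomic relationship matrix
#'
#' VanRaden's first method: dosages centered at twice the observed allele
#' frequency, \code{G = M M' / (2 sum p (1 - p))}, so the average diagonal
#' is near 1 and heritability estimated on G is on the individual scale.
#' \code{method = "crossprod"} returns the raw \code{W W'} kernel used for
#' the marker/kernel duality.
#'
#' @param W Dosage matrix 0/1/2 without missing values.
#' @param method \code{"vanraden"} or \code{"crossprod"}.
#' @return Symmetric n x n relationship matrix.
#' @export
grm <- function(W, method = c("vanraden", "crossprod")) {
  method <- match.arg(method)
  if (method == "crossprod") return(tcrossprod(W))
  pfreq <- colMeans(W) / 2
  keep <- pfreq > 0 & pfreq < 1
  M <- sweep(W[, keep, drop = FALSE], 2, 2 * pfreq[keep])
  tcrossprod(M) / (2 * sum(pfreq[keep] * (1 - pfreq[keep])))
}

#' REML estimation of genomic heritability on a kernel
#'
#' Spectral (eigen-decomposition) REML for the two-component model
#' y = Xb + g + e with Var(g) = sigma_g2 K: the restricted likelihood is
#' profiled down to the single variance ratio delta = sigma_e2/sigma_g2
#' and maximized by one-dimensional search over log(delta). With K a
#' genomic relationship matrix scaled to unit average diagonal, the
#' reported h2 is the genomic heritability sigma_g2/(sigma_g2 + sigma_e2).
#'
#' @param y Response, one value per individual.
#' @param K PSD kernel, e.g. \code{\link{grm}}.
#' @param X Fixed design (default intercept).
#' @param interval Search interval for log(delta).
#' @return List with \code{sigma_g2}, \code{sigma_e2}, \code{h2},
#'   \code{loglik}.
#' @export
kernel_reml <- function(y, K, X = matrix(1, length(y), 1),
                        interval = c(-12, 12)) {
  n <- length(y); p <- qr(X)$rank
  # project out the fixed effects, then rotate to the kernel eigenbasis
  qrX <- qr(X)
  Q2 <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
  KS <- crossprod(Q2, K %*% Q2)
  es <- eigen((KS + t(KS)) / 2, symmetric = TRUE)
  xi <- pmax(es$values, 0)
  eta <- drop(crossprod(es$vectors, crossprod(Q2, y)))
  m <- n - p

  negll <- function(logd) {
    d <- exp(logd)
    w <- xi + d
    0.5 * (m * log(sum(eta^2 / w) / m) + sum(log(w)))
  }
  opt <- stats::optimize(negll, interval = interval)
  d <- exp(opt$minimum)
  sigma_g2 <- sum(eta^2 / (xi + d)) / m
  sigma_e2 <- d * sigma_g2
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
       h2 = sigma_g2 / (sigma_g2 + sigma_e2),
       loglik = -opt$objective - 0.5 * m * (log(2 * pi) + 1))
}
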