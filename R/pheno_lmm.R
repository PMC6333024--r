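#' Build the design of the multi-year phenotypic mixed model
#'
#' The model is y = Xu + Zg + Wp + Vr + Tb + Ri + e: fixed year means u and
#' independent random effects for genotype (g), permanent plant environment
#' (p), population type (r), plot (b) and family-by-year interaction (i).
#'
#' With a single plant per genotype (the usual case here) the permanent
#' plant effect has exactly the same incidence as an individual-level
#' genotype effect, and a genotype-by-year effect would coincide with the
#' residual; such structurally confounded terms are detected and dropped
#' from the design (their variance is reported as 0). The interaction is
#' therefore indexed by family x year, which stays estimable, and the
#' progeny-level model of classical perennial evaluations is available via
#' \code{genotype = "family"} (then p is fitted as the plant effect).
#'
#' @param table Long-format phenotype data frame with columns
#'   \code{individual}, \code{family}, \code{pop_type}, \code{plot},
#'   \code{year}, \code{trait}, \code{value}.
#' @param trait Trait name to extract.
#' @param genotype Level of the genetic effect: \code{"individual"}
#'   (default) or \code{"family"}.
#' @return An \code{lmm_design}: response \code{y}, fixed design \code{X}
#'   (one column per year), named list \code{terms} of random-effect
#'   factors, the record \code{data}, and bookkeeping fields.
#' @export
build_design <- function(table, trait, genotype = c("individual", "family")) {
  genotype <- match.arg(genotype)
  need <- c("individual", "family", "pop_type", "plot", "year", "trait", "value")
  if (!all(need %in% names(table)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- table[table$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("trait not found: ", trait, call. = FALSE)
  n_missing <- sum(is.na(d$value))
  if (n_missing > 0) {
    message("dropping ", n_missing, " records with missing values")
    d <- d[!is.na(d$value), , drop = FALSE]
  }
  d <- d[order(d$individual, d$year), , drop = FALSE]

  gcol <- if (genotype == "individual") d$individual else d$family
  if (length(unique(gcol)) < 2) stop("need at least 2 genotypes", call. = FALSE)
  if (length(unique(d$year)) < 2)
    stop("need at least 2 years to separate year means from the residual",
         call. = FALSE)

  fac <- function(x) factor(x, levels = sort(unique(x)))
  terms <- list(genotype = fac(gcol),
                permanent = fac(d$individual),
                poptype = fac(d$pop_type),
                plot = fac(d$plot),
                interaction = fac(paste(d$family, d$year, sep = ":")))

  # structural confounding: identical grouping to an earlier term, a single
  # level, or one level per record (coincides with the residual)
  grouping_id <- function(f) paste(match(f, unique(f)), collapse = ",")
  seen <- character(0); dropped <- character(0)
  for (nm in names(terms)) {
    f <- terms[[nm]]
    gid <- grouping_id(f)
    if (nlevels(f) < 2 || nlevels(f) == length(f) || gid %in% seen) {
      dropped <- c(dropped, nm)
    } else seen <- c(seen, gid)
  }
  active <- setdiff(names(terms), dropped)

  X <- stats::model.matrix(~ 0 + fac(d$year))
  colnames(X) <- paste0("year", sort(unique(d$year)))

  structure(list(y = d$value, X = X, terms = terms[active],
                 dropped = dropped, data = d, trait = trait,
                 genotype_level = genotype, n_missing_dropped = n_missing),
            class = "lmm_design")
}

#' @export
print.lmm_design <- function(x, ...) {
  cat("lmm_design for trait", x$trait, "-", length(x$y), "records,",
      ncol(x$X), "years\n  random terms:",
      paste(sprintf("%s(%d)", names(x$terms), vapply(x$terms, nlevels, 1L)),
            collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped (confounded):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

canonical_components <- c("genotype", "permanent", "poptype", "plot",
                          "interaction", "residual")

# incidence matrices of the active random terms
design_Z <- function(design)
  lapply(design$terms, function(f) {
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- levels(f)
    Z
  })

# restricted log-likelihood at given components, V-parameterization
reml_loglik <- function(y, X, Glist, sigma2, sigma_e2) {
  n <- length(y)
  V <- diag(sigma_e2, n)
  for (k in seq_along(Glist)) if (sigma2[k] > 0) V <- V + sigma2[k] * Glist[[k]]
  ch <- chol(V)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Vi %*% r))
  -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX, logarithm = TRUE)$modulus +
            quad + (n - ncol(X)) * log(2 * pi))
}

#' EM-REML estimation of the variance components
#'
#' Expectation-maximization REML on Henderson's mixed-model equations:
#' each iteration solves the MME at the current components and updates
#' \code{sigma_k^2 = (u_k'u_k + sigma_e^2 tr(C^kk)) / q_k} and
#' \code{sigma_e^2 = y'(y - X b - Z u) / (n - rank X)}. EM keeps every
#' component nonnegative; a component falling below \code{zero_tol} times
#' the total variance is projected to 0 and removed from the system. The
#' restricted log-likelihood is non-decreasing across iterations (recorded
#' when \code{keep_loglik = TRUE}).
#'
#' @param design An \code{lmm_design}.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence: maximum relative change of any component.
#' @param keep_loglik Record the restricted log-likelihood per iteration
#'   (costs one dense n x n factorization per iteration).
#' @param zero_tol Relative floor below which a component is fixed at 0.
#' @param boundary_check_every Every this many iterations, any component
#'   below 0.1\% of the total variance is tested against the boundary: it
#'   is frozen at 0 when that does not lower the restricted likelihood
#'   (plain EM only approaches a boundary optimum asymptotically).
#' @return A \code{variance_components} object: \code{sigma2} (named vector
#'   over genotype, permanent, poptype, plot, interaction, residual; dropped
#'   or zeroed terms are 0), \code{converged}, \code{n_iterations},
#'   \code{loglik} trace (if kept) and the design dimensions.
#' @export
reml_fit <- function(design, max_iter = 500L, tol = 1e-6,
                     keep_loglik = FALSE, zero_tol = 1e-8,
                     boundary_check_every = 25L) {
  stopifnot(inherits(design, "lmm_design"))
  y <- design$y; X <- design$X
  Zs <- design_Z(design)
  K <- length(Zs)
  n <- length(y)
  q <- vapply(Zs, ncol, 1L)

  M <- cbind(X, do.call(cbind, Zs))
  A <- crossprod(M)                    # constant across iterations
  rhs <- crossprod(M, y)
  p <- ncol(X)
  idx <- split(p + seq_len(sum(q)), rep(seq_len(K), q))  # MME rows per term

  Glist <- lapply(Zs, tcrossprod)

  vtot <- stats::var(y)
  sigma2 <- rep(vtot / (K + 1), K)
  names(sigma2) <- names(Zs)
  sigma_e2 <- vtot / (K + 1)
  active <- rep(TRUE, K)
  last_checked <- rep(Inf, K)
  ll <- numeric(0)
  yty <- sum(y^2)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    use <- c(seq_len(p), unlist(idx[active], use.names = FALSE))
    C <- A[use, use, drop = FALSE]
    off <- p
    for (k in which(active)) {
      dk <- off + seq_len(q[k])
      C[cbind(dk, dk)] <- C[cbind(dk, dk)] + sigma_e2 / sigma2[k]
      off <- off + q[k]
    }
    Ci <- chol2inv(chol(C))
    sol <- drop(Ci %*% rhs[use])

    new_e <- (yty - sum(sol * rhs[use])) / (n - p)
    new_s <- sigma2
    off <- p
    for (k in which(active)) {
      dk <- off + seq_len(q[k])
      uk <- sol[dk]
      new_s[k] <- (sum(uk^2) + sigma_e2 * sum(diag(Ci)[dk])) / q[k]
      off <- off + q[k]
    }

    tot <- sum(new_s[active]) + new_e
    zero <- active & (new_s < zero_tol * tot)
    # boundary check: freeze a creeping component at 0 when that does not
    # lower the restricted likelihood
    if (iter %% boundary_check_every == 0L) {
      small <- which(active & !zero & new_s < 0.05 * tot &
                       new_s < last_checked)
      for (k in small) {
        cur <- reml_loglik(y, X, Glist, new_s, new_e)
        s_try <- new_s; s_try[k] <- 0
        if (reml_loglik(y, X, Glist, s_try, new_e) >= cur - 1e-6)
          zero[k] <- TRUE
      }
      last_checked <- new_s
    }
    new_s[zero] <- 0
    active <- active & !zero

    rel <- abs(c(new_s[active], new_e) - c(sigma2[active], sigma_e2)) /
      pmax(abs(c(sigma2[active], sigma_e2)), 1e-12)
    delta <- if (length(rel)) max(rel) else 0
    sigma2 <- new_s; sigma_e2 <- new_e
    if (keep_loglik)
      ll <- c(ll, reml_loglik(y, X, Glist, sigma2, sigma_e2))
    if (delta < tol && !any(zero)) { converged <- TRUE; break }
  }

  out <- stats::setNames(numeric(length(canonical_components)),
                         canonical_components)
  out[names(sigma2)] <- sigma2
  out["residual"] <- sigma_e2
  structure(list(sigma2 = out, converged = converged, n_iterations = iter,
                 loglik = if (keep_loglik) ll else NULL,
                 n_records = n, n_fixed = p,
                 active_terms = names(Zs)[active],
                 dropped_terms = design$dropped),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components (EM-REML,", x$n_iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  print(round(x$sigma2, 6))
  invisible(x)
}

#' Solve Henderson's mixed-model equations for BLUPs and year means
#'
#' @param design An \code{lmm_design}.
#' @param components A \code{variance_components} (or a named vector over
#'   the canonical component names).
#' @return List with \code{fixed} (estimated year means), \code{blups}
#'   (named list of per-level predictions, one vector per random term with
#'   positive variance), \code{pev} (prediction error variance per genotype
#'   level, from the inverse MME coefficient matrix), and \code{sigma2}.
#' @export
blup_solve <- function(design, components) {
  stopifnot(inherits(design, "lmm_design"))
  s2 <- if (inherits(components, "variance_components")) components$sigma2
        else components
  sigma_e2 <- s2[["residual"]]
  if (sigma_e2 <= 0) stop("residual variance must be positive", call. = FALSE)
  terms <- design$terms
  use_terms <- names(terms)[s2[names(terms)] > 0]
  Zs <- design_Z(design)[use_terms]
  y <- design$y; X <- design$X; p <- ncol(X)

  if (qr(X)$rank < p)
    stop("singular fixed-effect block; aliased year levels: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)

  M <- cbind(X, if (length(Zs)) do.call(cbind, Zs))
  C <- crossprod(M)
  off <- p
  for (nm in use_terms) {
    dk <- off + seq_len(ncol(Zs[[nm]]))
    C[cbind(dk, dk)] <- C[cbind(dk, dk)] + sigma_e2 / s2[[nm]]
    off <- off + ncol(Zs[[nm]])
  }
  Ci <- chol2inv(chol(C))
  sol <- drop(Ci %*% crossprod(M, y))

  fixed <- stats::setNames(sol[seq_len(p)], colnames(X))
  blups <- list(); pev <- NULL
  off <- p
  for (nm in use_terms) {
    dk <- off + seq_len(ncol(Zs[[nm]]))
    blups[[nm]] <- stats::setNames(sol[dk], colnames(Zs[[nm]]))
    if (nm == "genotype")
      pev <- stats::setNames(diag(Ci)[dk] * sigma_e2, colnames(Zs[[nm]]))
    off <- off + ncol(Zs[[nm]])
  }
  # zero-variance terms predict 0 for every level
  for (nm in setdiff(names(terms), use_terms))
    blups[[nm]] <- stats::setNames(numeric(nlevels(terms[[nm]])),
                                   levels(terms[[nm]]))
  list(fixed = fixed, blups = blups, pev = pev, sigma2 = s2)
}

#' Phenotypic heritability and selective accuracy
#'
#' Heritability is reported at the across-years mean level: components that
#' are constant for a plant (genotype, permanent, population type, plot)
#' enter whole, while interaction and residual variance are divided by the
#' mean number of records per genotype. Selective accuracy r_yy is, per
#' genotype, \code{sqrt(1 - PEV / sigma_g^2)} with the prediction error
#' variance taken from the inverse of the MME coefficient matrix, averaged
#' over genotypes; \code{method = "sqrt_h2"} instead returns the square
#' root of the mean-level heritability, which the PEV-based value tracks
#' closely on near-balanced designs.
#'
#' @param design An \code{lmm_design}.
#' @param components A \code{variance_components}.
#' @param method Accuracy definition, \code{"pev"} (default) or
#'   \code{"sqrt_h2"}.
#' @return List with \code{h2_phen} and \code{r_yy}, both in [0, 1].
#' @export
phenotypic_accuracy <- function(design, components, method = c("pev", "sqrt_h2")) {
  method <- match.arg(method)
  s2 <- components$sigma2
  t_bar <- length(design$y) / nlevels(design$terms$genotype)
  denom <- s2[["genotype"]] + s2[["permanent"]] + s2[["poptype"]] +
    s2[["plot"]] + (s2[["interaction"]] + s2[["residual"]]) / t_bar
  h2_phen <- if (denom > 0) s2[["genotype"]] / denom else 0
  r_yy <- if (s2[["genotype"]] <= 0) 0
  else if (method == "sqrt_h2") sqrt(h2_phen)
  else {
    fit <- blup_solve(design, components)
    mean(sqrt(pmax(0, 1 - fit$pev / s2[["genotype"]])))
  }
  list(h2_phen = unname(h2_phen), r_yy = unname(r_yy))
}

#' Correct phenotypes for year and plot effects
#'
#' Subtracts from each record its estimated year mean and plot BLUP, then
#' averages each individual's corrected records across years — one value
#' per individual, the response used by the genomic analyses. Only field
#' and temporal effects are removed: genotype, permanent, population-type
#' and family-by-year signal is deliberately retained (the last averages
#' toward zero over years), because the corrected value must keep the
#' genetic differences the markers are asked to predict.
#'
#' @param design An \code{lmm_design}.
#' @param fit Output of \code{\link{blup_solve}}.
#' @return Named numeric vector, one corrected phenotype per individual.
#' @export
correct_phenotypes <- function(design, fit) {
  d <- design$data
  corr <- design$y - fit$fixed[paste0("year", d$year)]
  bl <- fit$blups
  if (!is.null(bl$plot)) corr <- corr - bl$plot[d$plot]
  out <- tapply(corr, d$individual, mean)
  empty <- setdiff(unique(d$individual), names(out))
  if (length(empty)) warning("individuals with no records excluded: ",
                             paste(empty, collapse = ", "))
  stats::setNames(as.numeric(out), names(out))
}

#' Individual-level heritability from variance components
#'
#' The ratio of the genotype variance to the total of all six components,
#' \code{h2 = sg2 / (sg2 + sp2 + sr2 + sb2 + si2 + se2)}.
#'
#' @param components A \code{variance_components} or named numeric vector
#'   over the canonical component names.
#' @return Heritability in [0, 1].
#' @export
individual_h2 <- function(components) {
  s2 <- if (inherits(components, "variance_components")) components$sigma2
        else components[canonical_components]
  if (any(is.na(s2))) stop("all six components are required", call. = FALSE)
  if (any(s2 < 0)) stop("variances must be nonnegative", call. = FALSE)
  tot <- sum(s2)
  if (tot <= 0) stop("total variance is zero", call. = FALSE)
  unname(s2[["genotype"]] / tot)
}
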