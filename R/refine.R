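# ---- importance-sampling refinement ----------------------------------------
# The Laplace fit provides, per subject, one or two posterior modes with
# curvatures. A fixed mixture-of-Gaussians proposal is built on those modes
# (two components where the posterior is bimodal), a fixed set of draws is
# taken once, and the marginal likelihood is then estimated by importance
# sampling with those common random numbers. The resulting objective is a
# smooth deterministic function of the population parameters and integrates
# both posterior basins, which the single-mode Laplace expansion cannot.

# build the fixed proposal draws at the incumbent model
.build_is_draws <- function(model, prep, settings) {
  rd <- names(model$omega2)[model$omega2 > 0]
  p <- length(rd)
  ns <- length(prep$subs)
  M <- settings$refine_draws
  infl <- settings$is_inflation
  typ <- resolve_typicals(model, prep$ucov)[prep$batch$ucov_idx, ,
                                            drop = FALSE]
  w2m <- matrix(model$omega2[rd], ns, p, byrow = TRUE)
  lb <- .laplace_batch(typ, prep$batch, rd, w2m, rep(model$sigma2, ns),
                       matrix(0, ns, p), settings, collect_modes = TRUE)
  if (!lb$ok) stop("Laplace pass failed while building the importance ",
                   "proposal", call. = FALSE)
  md <- lb$modes
  second <- match(seq_len(ns), md$idx2)   # NA where unimodal
  etas <- matrix(0, ns * M, p)
  logq <- numeric(ns * M)
  const <- -p / 2 * log(2 * pi * infl)
  for (i in seq_len(ns)) {
    comp <- list(list(mode = md$eta1[i, ], A = md$A1[i, , ]))
    if (!is.na(second[i]))
      comp <- c(comp, list(list(mode = md$eta2[second[i], ],
                                A = md$A2[second[i], , ])))
    nc <- length(comp)
    for (c in seq_len(nc)) {
      comp[[c]]$R <- chol(matrix(comp[[c]]$A, p, p))
      comp[[c]]$ldA <- 2 * sum(log(diag(comp[[c]]$R)))
    }
    z <- matrix(stats::rnorm(M * p), M, p)
    pickc <- rep_len(seq_len(nc), M)
    D <- matrix(0, M, p)
    for (c in seq_len(nc)) {
      rows <- which(pickc == c)
      # draw ~ N(mode, infl * A^{-1}); A = R'R so cov factor is R^{-1}
      D[rows, ] <- sqrt(infl) *
        t(backsolve(comp[[c]]$R, t(z[rows, , drop = FALSE]))) +
        matrix(comp[[c]]$mode, length(rows), p, byrow = TRUE)
    }
    lq <- matrix(-Inf, M, nc)
    for (c in seq_len(nc)) {
      V <- (D - matrix(comp[[c]]$mode, M, p, byrow = TRUE)) %*%
        t(comp[[c]]$R)
      lq[, c] <- const + comp[[c]]$ldA / 2 - rowSums(V^2) / (2 * infl)
    }
    mx <- apply(lq, 1, max)
    rows <- (i - 1) * M + seq_len(M)
    etas[rows, ] <- D
    logq[rows] <- mx + log(rowMeans(exp(lq - mx)))
  }
  list(etas = etas, logq = logq, M = M, ns = ns, rd = rd, p = p)
}

# importance-sampling OFV of a model at the fixed draws
.is_ofv <- function(model, prep, isd, ba_is) {
  rd <- isd$rd
  typ <- resolve_typicals(model, prep$ucov)
  idx_sub <- rep(prep$batch$ucov_idx, each = isd$M)
  typ_big <- typ[idx_sub, , drop = FALSE]
  w2m <- matrix(model$omega2[rd], isd$ns * isd$M, isd$p, byrow = TRUE)
  sig2 <- rep(model$sigma2, isd$ns * isd$M)
  val <- .batch_eval(isd$etas, typ_big, ba_is, seq_len(isd$ns * isd$M),
                     rd, w2m, sig2, deriv = FALSE)$value
  lw <- matrix(-val / 2 - isd$logq, isd$M, isd$ns)
  mx <- apply(lw, 2, max)
  if (any(!is.finite(mx))) return(1e10)
  persub <- -2 * (mx + log(.colMeans(exp(sweep(lw, 2, mx)), isd$M,
                                     isd$ns)))
  sum(persub)
}

# analytic gradient of the importance-sampling OFV with respect to the
# log-transformed free parameters. Per draw, d(joint -2LL)/d(log theta_P)
# equals the eta_P gradient component's data part (P enters as
# theta_P * exp(eta_P)), recovered from the batched eta-gradient; the
# omega2 and sigma2 components are analytic in closed form. The OFV
# gradient is then the softmax-weighted average over draws per subject.
.is_grad <- function(model, prep, isd, ba_is, map, masks) {
  rd <- isd$rd
  p <- isd$p
  N <- isd$ns * isd$M
  typ <- resolve_typicals(model, prep$ucov)
  idx_sub <- rep(prep$batch$ucov_idx, each = isd$M)
  typ_big <- typ[idx_sub, , drop = FALSE]
  w2 <- model$omega2[rd]
  w2m <- matrix(w2, N, p, byrow = TRUE)
  sigma2 <- model$sigma2
  sig2 <- rep(sigma2, N)
  ev <- .batch_eval(isd$etas, typ_big, ba_is, seq_len(N), rd, w2m, sig2)
  val <- ev$value
  # recover the data cross-products S_p = sum_j J_p r_j and the residual
  # sum of squares from the eta-gradient and the joint value
  S <- matrix(0, N, p)
  for (a in seq_len(p))
    S[, a] <- (2 * isd$etas[, a] / w2[a] - ev$grad[, a]) * sigma2 / 2
  prior <- rowSums(log(2 * pi * w2m)) + rowSums(isd$etas^2 / w2m)
  SS <- (val - ba_is$nobs * log(2 * pi * sigma2) - prior) * sigma2
  lw <- matrix(-val / 2 - isd$logq, isd$M, isd$ns)
  mx <- apply(lw, 2, max)
  ew <- exp(sweep(lw, 2, mx))
  u <- as.vector(sweep(ew, 2, .colSums(ew, isd$M, isd$ns), "/"))
  vapply(seq_along(map), function(k) {
    e <- map[[k]]
    D <- switch(e$type,
      theta = -2 * S[, match(e$param, rd)] / sigma2,
      level = -2 * S[, match(e$param, rd)] / sigma2 *
        masks[[names(map)[k]]],
      omega2 = {
        a <- match(e$param, rd)
        1 - isd$etas[, a]^2 / w2[a]
      },
      sigma2 = ba_is$nobs - SS / sigma2)
    sum(u * D)
  }, numeric(1))
}

# refine a Laplace solution by optimising the importance-sampling OFV,
# re-adapting the proposal at the incumbent optimum between rounds (the
# expectation-maximisation structure of importance-sampling estimation)
.refine_importance <- function(start, map, x_hat, prep, settings, bb) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  ba <- prep$batch
  # per-map-entry row masks for split-level gradient components
  covs <- prep$cov
  masks <- list()
  M <- settings$refine_draws
  for (k in seq_along(map)) {
    e <- map[[k]]
    if (e$type != "level") next
    ef <- Filter(function(x) x$kind == "split" && x$target == e$param,
                 start$effects)[[1]]
    keys <- do.call(paste, c(lapply(ef$covariates, function(nm)
      as.integer(covs[[toupper(nm)]])), sep = ":"))
    masks[[names(map)[k]]] <- rep(as.numeric(keys == e$key), each = M)
  }
  x_cur <- x_hat
  opt <- NULL
  for (round in seq_len(settings$refine_rounds)) {
    set.seed(settings$is_seed + round)
    model_cur <- .map_set(start, map, exp(x_cur))
    isd <- .build_is_draws(model_cur, prep, settings)
    idx_sub <- rep(seq_len(isd$ns), each = isd$M)
    ba_is <- list(Z = ba$Z[idx_sub, , drop = FALSE],
                  Tm = ba$Tm[idx_sub, , drop = FALSE],
                  mask = ba$mask[idx_sub, , drop = FALSE],
                  nobs = ba$nobs[idx_sub])
    obj <- function(x) .is_ofv(.map_set(start, map, exp(x)), prep, isd,
                               ba_is)
    rdhere <- names(.map_set(start, map,
                             exp(x_cur))$omega2)[
      .map_set(start, map, exp(x_cur))$omega2 > 0]
    analytic_ok <- all(vapply(map, function(e)
      e$type %in% c("omega2", "sigma2") || e$param %in% rdhere, TRUE))
    grad <- if (analytic_ok) {
      function(x) .is_grad(.map_set(start, map, exp(x)), prep, isd,
                           ba_is, map, masks)
    } else {
      function(x) {
        f0 <- obj(x)
        hstep <- 1e-6
        vapply(seq_along(x), function(k) {
          xk <- x
          xk[k] <- xk[k] + hstep
          (obj(xk) - f0) / hstep
        }, numeric(1))
      }
    }
    opt <- stats::nlminb(x_cur, obj, gradient = grad, lower = bb$lower,
                         upper = bb$upper,
                         control = list(rel.tol = max(settings$outer_tol,
                                                      1e-5),
                                        iter.max = 300,
                                        eval.max = 900))
    moved <- max(abs(opt$par - x_cur))
    x_cur <- opt$par
    if (settings$trace)
      message(sprintf("  IS round %d: OFV %.4f, moved %.4f (%s)", round,
                      opt$objective, moved, opt$message))
    if (moved < 1e-3) break
  }
  list(par = x_cur, objective = opt$objective,
       converged = opt$convergence == 0 ||
         grepl("relative convergence|X-convergence|both X", opt$message),
       message = opt$message)
}
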