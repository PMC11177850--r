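# ---- internal likelihood machinery -----------------------------------------
# Observations are modelled on the log scale: log DV_ij = m(t_ij; theta_i) +
# eps_ij, with theta_i = typical * exp(eta_i) on the parameters carrying
# between-subject variability. All functions below work with one subject's
# z = log(DV) and t = TIME.

# mean log-prediction and its Jacobian with respect to eta (analytic),
# for the random-effect dimensions rd (character vector of parameter names)
.mean_and_jac <- function(t, p7, rd, jac = TRUE) {
  qm <- p7[["qmax_uf"]]; k <- p7[["k"]]; pp <- p7[["pna_p"]]
  ks <- p7[["ksyn_gfr0"]]; s <- p7[["gfrss_gfr0"]]
  t50 <- p7[["pna50"]]; gm <- p7[["gamma"]]
  d <- t - pp
  Q <- qm * exp(-(k^2 / 2) * d^2)
  FF <- 1 / (1 + (t50 / t)^gm)
  R <- 1 + (s - 1) * FF
  m <- log1p(Q) + log(ks) - log(R)
  if (!jac) return(list(m = m))
  J <- matrix(0, length(t), length(rd), dimnames = list(NULL, rd))
  w <- Q / (1 + Q)
  F1 <- FF * (1 - FF)
  for (p in rd) {
    J[, p] <- switch(p,
      qmax_uf = w,
      k = -w * k^2 * d^2,
      pna_p = w * k^2 * d * pp,
      ksyn_gfr0 = rep(1, length(t)),
      gfrss_gfr0 = -s * FF / R,
      pna50 = (s - 1) * gm * F1 / R,
      gamma = -(s - 1) * gm * log(t / t50) * F1 / R)
  }
  list(m = m, J = J)
}

# joint -2 log-likelihood of one subject's data and random effects
.joint_value <- function(eta, z, t, typ, rd, w2, sigma2, grad = FALSE) {
  p7 <- typ
  p7[rd] <- p7[rd] * exp(eta)
  mj <- .mean_and_jac(t, p7, rd, jac = grad)
  r <- z - mj$m
  val <- length(z) * log(2 * pi * sigma2) + sum(r^2) / sigma2 +
    sum(log(2 * pi * w2) + eta^2 / w2)
  if (!grad) return(val)
  g <- -2 * drop(crossprod(mj$J, r)) / sigma2 + 2 * eta / w2
  list(value = val, grad = g, m = mj$m, J = mj$J, r = r)
}

#' Joint -2 log-likelihood of one subject's data and random effects
#'
#' The penalised individual objective combining the log-additive residual
#' density of the observations with the lognormal random-effect prior:
#' `-2 * [sum_j log phi(log DV_j; m(t_j; theta*e^eta), sigma2) +
#' sum_p log phi(eta_p; 0, omega2_p)]`. Its minimiser over `eta` is the
#' subject's empirical Bayes estimate.
#'
#' @param dv Observed sCr (mg/dL), positive.
#' @param times Observation times (postnatal days).
#' @param params Covariate-adjusted typical [scr_params] for the subject.
#' @param eta Named random-effect vector; names must be a subset of the
#'   parameter names and each must have `omega2 > 0`.
#' @param omega2 Named variances of the random effects (log scale).
#' @param sigma2 Residual variance of log sCr (> 0).
#' @return The scalar joint -2 log-likelihood.
#' @export
joint_neg2ll <- function(dv, times, params, eta, omega2, sigma2) {
  stopifnot(length(dv) == length(times), length(dv) >= 1, sigma2 > 0)
  rd <- names(eta)
  if (!all(rd %in% .scr_param_names))
    stop("unknown random-effect name(s)", call. = FALSE)
  w2 <- omega2[rd]
  if (any(is.na(w2) | w2 <= 0))
    stop("every random effect needs omega2 > 0; fixed-effect parameters ",
         "take eta = 0 and must be omitted", call. = FALSE)
  .joint_value(as.numeric(eta), log(dv), times, params, rd, w2, sigma2)
}

# inner Hessian of the joint -2LL at eta (method per settings$hessian)
.inner_hessian <- function(eta, z, t, typ, rd, w2, sigma2, hessian) {
  if (hessian == "gauss_newton") {
    jv <- .joint_value(eta, z, t, typ, rd, w2, sigma2, grad = TRUE)
    H <- 2 * crossprod(jv$J) / sigma2 + 2 * diag(1 / w2,
                                                 nrow = length(w2))
  } else {
    g0 <- .joint_value(eta, z, t, typ, rd, w2, sigma2, grad = TRUE)$grad
    p <- length(eta)
    H <- matrix(0, p, p)
    for (kk in seq_len(p)) {
      h <- 1e-5 * (1 + abs(eta[kk]))
      e2 <- eta; e2[kk] <- e2[kk] + h
      g1 <- .joint_value(e2, z, t, typ, rd, w2, sigma2, grad = TRUE)$grad
      H[, kk] <- (g1 - g0) / h
    }
    H <- (H + t(H)) / 2
  }
  H
}

# find the joint mode for one subject by damped Gauss-Newton iteration;
# one iteration costs a single analytic gradient evaluation (the Jacobian
# doubles as the curvature), so the mode is cheap, deterministic and
# accurate given its starting value. Falls back to a quasi-Newton solve if
# the iteration stalls away from a stationary point.
.inner_mode <- function(z, t, typ, rd, w2, sigma2, eta0, settings) {
  eta <- eta0
  jv <- .joint_value(eta, z, t, typ, rd, w2, sigma2, grad = TRUE)
  val <- jv$value
  J <- jv$J
  ok <- FALSE
  for (it in 1:60) {
    g <- jv$grad
    if (max(abs(g)) < 1e-8) { ok <- TRUE; break }
    H <- 2 * crossprod(J) / sigma2 + 2 * diag(1 / w2, nrow = length(w2))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    repeat {
      cand <- eta - lambda * step
      cv <- .joint_value(cand, z, t, typ, rd, w2, sigma2, grad = TRUE)
      if (is.finite(cv$value) && cv$value <= val + 1e-12) {
        moved <- max(abs(lambda * step))
        eta <- cand; val <- cv$value; jv <- cv; J <- cv$J
        improved <- TRUE
        if (moved < 1e-11) ok <- TRUE   # numerically stationary
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    if (!improved || ok) break
  }
  if (!ok && max(abs(jv$grad)) > 1e-5) {
    # stalled: robust fallback
    opt <- stats::nlminb(eta,
                         function(e) .joint_value(e, z, t, typ, rd, w2,
                                                  sigma2),
                         gradient = function(e)
                           .joint_value(e, z, t, typ, rd, w2, sigma2,
                                        grad = TRUE)$grad,
                         control = list(rel.tol = settings$inner_tol,
                                        iter.max = 300))
    if (is.finite(opt$objective) && opt$objective <= val) {
      eta <- opt$par
      jv <- .joint_value(eta, z, t, typ, rd, w2, sigma2, grad = TRUE)
      val <- jv$value
    }
  }
  list(eta = eta, value = val, J = jv$J)
}

# Laplace-approximate -2 log marginal likelihood of one subject;
# returns ofv, mode (eta-hat) and curvature
.laplace_subject <- function(z, t, typ, rd, w2, sigma2, eta0, settings) {
  p <- length(rd)
  mode <- .inner_mode(z, t, typ, rd, w2, sigma2, eta0, settings)
  eta_hat <- mode$eta
  H <- if (settings$hessian == "gauss_newton")
    2 * crossprod(mode$J) / sigma2 + 2 * diag(1 / w2, nrow = length(w2))
  else
    .inner_hessian(eta_hat, z, t, typ, rd, w2, sigma2, "fd")
  ch <- tryCatch(chol(H / 2), error = function(e) NULL)
  if (is.null(ch))
    return(list(ofv = NA_real_, eta = eta_hat, ok = FALSE, H = H))
  ofv <- mode$value - p * log(2 * pi) + 2 * sum(log(diag(ch)))
  list(ofv = ofv, eta = eta_hat, ok = TRUE, H = H)
}

# importance-sampling -2 log marginal likelihood of one subject, with a
# Gaussian proposal centred at the empirical Bayes mode
.importance_subject <- function(z, t, typ, rd, w2, sigma2, eta0, settings) {
  lap <- .laplace_subject(z, t, typ, rd, w2, sigma2, eta0, settings)
  if (!lap$ok) return(lap)
  p <- length(rd)
  M <- settings$is_draws
  C <- 2 * solve(lap$H) * 1.3   # posterior covariance, mildly inflated
  L <- chol(C)
  zs <- matrix(stats::rnorm(M * p), M, p)
  etas <- sweep(zs %*% L, 2, lap$eta, "+")
  logq <- -p / 2 * log(2 * pi) - sum(log(diag(L))) - rowSums(zs^2) / 2
  Lj <- .joint_batch(etas, z, t, typ, rd, w2, sigma2)
  lw <- -Lj / 2 - logq
  mx <- max(lw)
  ofv <- -2 * (mx + log(mean(exp(lw - mx))))
  list(ofv = ofv, eta = lap$eta, ok = TRUE, H = lap$H)
}

# joint -2LL evaluated for a batch of eta draws (rows of etas)
.joint_batch <- function(etas, z, t, typ, rd, w2, sigma2) {
  M <- nrow(etas); n <- length(t)
  P <- matrix(typ[.scr_param_names], M, 7, byrow = TRUE,
              dimnames = list(NULL, .scr_param_names))
  P[, rd] <- P[, rd] * exp(etas)
  d <- -outer(P[, "pna_p"], t, "-")             # t - pna_p, M x n
  Q <- P[, "qmax_uf"] * exp(-(P[, "k"]^2 / 2) * d^2)
  FF <- 1 / (1 + outer(P[, "pna50"], t, "/")^P[, "gamma"])
  R <- 1 + (P[, "gfrss_gfr0"] - 1) * FF
  m <- log1p(Q) + log(P[, "ksyn_gfr0"]) - log(R)
  r <- sweep(m, 2, z, "-")
  n * log(2 * pi * sigma2) + rowSums(r^2) / sigma2 +
    sum(log(2 * pi * w2)) + rowSums(sweep(etas^2, 2, 1 / w2, "*"))
}

# exact marginal -2LL when the only random effect is ksyn_gfr0: the model is
# log-linear in eta, so log DV ~ N(m0, sigma2*I + omega2*J) with
# compound-symmetric covariance (Sherman-Morrison / matrix determinant lemma)
.linear_marginal <- function(z, t, typ, w2, sigma2) {
  m0 <- .mean_and_jac(t, typ, character(0), jac = FALSE)$m
  r <- z - m0
  n <- length(z)
  S <- sum(r)
  eta_hat <- w2 * S / (sigma2 + n * w2)
  ofv <- n * log(2 * pi * sigma2) + log1p(n * w2 / sigma2) +
    sum(r^2) / sigma2 - w2 * S^2 / (sigma2 * (sigma2 + n * w2))
  list(ofv = ofv, eta = eta_hat, ok = TRUE)
}

# ---- batched Laplace over all subjects -------------------------------------
# Observation vectors are padded into nsub x K matrices with a 0/1 mask so
# the damped Gauss-Newton mode search runs for every subject at once; the
# per-subject 7x7 solves and Cholesky factorisations remain scalar loops.

.batch_arrays <- function(prep) {
  K <- max(vapply(prep$subs, function(s) length(s$z), 1L))
  ns <- length(prep$subs)
  Z <- Tm <- matrix(0, ns, K)
  Tm[] <- 1                      # harmless padding time
  mask <- matrix(0, ns, K)
  for (i in seq_len(ns)) {
    n <- length(prep$subs[[i]]$z)
    Z[i, seq_len(n)] <- prep$subs[[i]]$z
    Tm[i, seq_len(n)] <- prep$subs[[i]]$t
    mask[i, seq_len(n)] <- 1
  }
  list(Z = Z, Tm = Tm, mask = mask,
       nobs = vapply(prep$subs, function(s) length(s$z), 1L),
       ucov_idx = vapply(prep$subs, function(s) s$ucov_idx, 1L))
}

# mean log-prediction and Jacobian pieces for all subjects at once
.batch_mean_jac <- function(P, Tm, rd, jac = TRUE) {
  qm <- P[, "qmax_uf"]; k2 <- P[, "k"]^2; pp <- P[, "pna_p"]
  ks <- P[, "ksyn_gfr0"]; s <- P[, "gfrss_gfr0"]
  t50 <- P[, "pna50"]; gm <- P[, "gamma"]
  D <- Tm - pp
  Q <- qm * exp(-(k2 / 2) * D^2)
  FF <- 1 / (1 + (t50 / Tm)^gm)
  R <- 1 + (s - 1) * FF
  m <- log1p(Q) + log(ks) - log(R)
  if (!jac) return(list(m = m))
  J <- vector("list", length(rd))
  names(J) <- rd
  w <- Q / (1 + Q)
  F1 <- FF * (1 - FF)
  for (p in rd) J[[p]] <- switch(p,
    qmax_uf = w,
    k = -w * k2 * D^2,
    pna_p = w * k2 * D * pp,
    ksyn_gfr0 = NULL,              # constant 1; handled specially
    gfrss_gfr0 = -s * FF / R,
    pna50 = (s - 1) * gm * F1 / R,
    gamma = -(s - 1) * gm * log(Tm / t50) * F1 / R)
  list(m = m, J = J)
}

# joint -2LL value / gradient / curvature blocks for a set of subjects.
# w2m is an ns x p matrix and sig2 an ns-vector so that rows belonging to
# different population-parameter vectors can share one batch (used to
# compute the outer finite-difference gradient in a single pass).
.batch_eval <- function(eta, typ, ba, rows, rd, w2m, sig2, deriv = TRUE) {
  P <- typ[rows, , drop = FALSE]
  P[, rd] <- P[, rd] * exp(eta)
  Tm <- ba$Tm[rows, , drop = FALSE]
  mask <- ba$mask[rows, , drop = FALSE]
  mj <- .batch_mean_jac(P, Tm, rd, jac = deriv)
  r <- (ba$Z[rows, , drop = FALSE] - mj$m) * mask
  p <- length(rd)
  w2r <- w2m[rows, , drop = FALSE]
  s2r <- sig2[rows]
  val <- ba$nobs[rows] * log(2 * pi * s2r) +
    rowSums(r * r) / s2r + rowSums(log(2 * pi * w2r)) +
    rowSums(eta^2 / w2r)
  if (!deriv) return(list(value = val))
  g <- matrix(0, length(rows), p)
  JJ <- array(0, c(length(rows), p, p))
  Jm <- vector("list", p)
  for (a in seq_len(p)) {
    Jm[[a]] <- if (rd[a] == "ksyn_gfr0") mask else mj$J[[rd[a]]] * mask
    g[, a] <- -2 * rowSums(Jm[[a]] * r) / s2r + 2 * eta[, a] / w2r[, a]
  }
  for (a in seq_len(p)) for (b in a:p)
    JJ[, a, b] <- JJ[, b, a] <- rowSums(Jm[[a]] * Jm[[b]])
  list(value = val, grad = g, JJ = JJ)
}

# batched Cholesky factorisation / solve / log-determinant for a stack of
# small symmetric positive-definite systems, vectorised across subjects.
# A: ns x p x p array; g: ns x p right-hand sides (may be NULL).
.batch_chol <- function(A, g = NULL) {
  ns <- dim(A)[1]; p <- dim(A)[2]
  L <- array(0, c(ns, p, p))
  ok <- rep(TRUE, ns)
  for (a in seq_len(p)) {
    s <- A[, a, a]
    if (a > 1) for (k in seq_len(a - 1)) s <- s - L[, a, k]^2
    ok <- ok & is.finite(s) & s > 0
    L[, a, a] <- sqrt(pmax(s, 1e-300))
    if (a < p) for (b in (a + 1):p) {
      v <- A[, b, a]
      if (a > 1) for (k in seq_len(a - 1)) v <- v - L[, b, k] * L[, a, k]
      L[, b, a] <- v / L[, a, a]
    }
  }
  logdet <- 0
  for (a in seq_len(p)) logdet <- logdet + 2 * log(L[, a, a])
  out <- list(ok = ok, logdet = logdet)
  if (!is.null(g)) {
    y <- matrix(0, ns, p)
    for (a in seq_len(p)) {
      v <- g[, a]
      if (a > 1) for (k in seq_len(a - 1)) v <- v - L[, a, k] * y[, k]
      y[, a] <- v / L[, a, a]
    }
    x <- matrix(0, ns, p)
    for (a in rev(seq_len(p))) {
      v <- y[, a]
      if (a < p) for (k in (a + 1):p) v <- v - L[, k, a] * x[, k]
      x[, a] <- v / L[, a, a]
    }
    out$x <- x
  }
  out
}

# damped Gauss-Newton mode search for a batch of subjects; returns the
# modes with their joint values, gradients and curvature blocks
.gn_modes <- function(typ, ba, rd, w2m, sig2, eta, settings) {
  ns <- nrow(eta)
  p <- length(rd)
  ev <- .batch_eval(eta, typ, ba, seq_len(ns), rd, w2m, sig2)
  val <- ev$value
  grad <- ev$grad
  JJ <- ev$JJ
  stalled <- rep(FALSE, ns)
  done <- rep(FALSE, ns)
  gtol <- 3e-7
  for (it in 1:80) {
    gmax <- do.call(pmax, lapply(seq_len(p), function(a) abs(grad[, a])))
    done <- done | gmax <= gtol
    act <- which(!done & !stalled)
    if (!length(act)) break
    A <- (2 / sig2[act]) * JJ[act, , , drop = FALSE]
    for (a in seq_len(p)) A[, a, a] <- A[, a, a] + 2 / w2m[act, a]
    bc <- .batch_chol(A, grad[act, , drop = FALSE])
    stalled[act[!bc$ok]] <- TRUE
    step <- bc$x
    step[!bc$ok, ] <- 0
    # predicted quadratic decrease g'H^{-1}g/2 estimates the OFV gap to
    # the mode; subjects already within tolerance need no further steps
    pred_dec <- rowSums(step * grad[act, , drop = FALSE]) / 2
    close_enough <- bc$ok & pred_dec < 1e-9
    done[act[close_enough]] <- TRUE
    keep <- !close_enough & bc$ok
    act <- act[keep]
    if (!length(act)) next
    step <- step[keep, , drop = FALSE]
    lam <- rep(1, length(act))
    open <- seq_along(act)
    accepted_idx <- integer(0)
    while (length(open)) {
      idx <- act[open]
      cand <- eta[idx, , drop = FALSE] -
        lam[open] * step[open, , drop = FALSE]
      cv <- .batch_eval(cand, typ, ba, idx, rd, w2m, sig2, deriv = FALSE)
      better <- is.finite(cv$value) & cv$value <= val[idx] + 1e-12
      if (any(better)) {
        bi <- idx[better]
        eta[bi, ] <- cand[better, , drop = FALSE]
        val[bi] <- cv$value[better]
        moved <- apply(abs(lam[open][better] *
                             step[open[better], , drop = FALSE]), 1, max)
        done[bi[moved < 1e-9]] <- TRUE   # numerically stationary
        accepted_idx <- c(accepted_idx, bi)
      }
      open <- open[!better]
      lam[open] <- lam[open] / 2
      give_up <- lam[open] < 1e-6
      stalled[act[open[give_up]]] <- TRUE
      open <- open[!give_up]
    }
    if (length(accepted_idx)) {
      cv <- .batch_eval(eta[accepted_idx, , drop = FALSE], typ, ba,
                        accepted_idx, rd, w2m, sig2)
      grad[accepted_idx, ] <- cv$grad
      JJ[accepted_idx, , ] <- cv$JJ
    }
  }
  list(eta = eta, val = val, grad = grad, JJ = JJ, stalled = stalled)
}

# batched Laplace with a two-mode (mixture) extension. Mode 1 is searched
# from the supplied starting values; mode 2 from the *reflection* of mode 1
# through the prior mean, which lands in the opposite basin of the bimodal
# "early riser / late riser" posteriors that the steep maturation term
# creates. Where the two searches reach distinct modes, both contribute to
# the marginal via log-sum-exp; the construction is deterministic given the
# data and parameters, so OFVs are comparable across fits and with cold
# evaluations. w2m: ns x p matrix; sig2: ns-vector (see .batch_eval).
.laplace_batch <- function(typ, ba, rd, w2m, sig2, eta0, settings,
                           collect_modes = FALSE) {
  ns <- nrow(eta0)
  p <- length(rd)
  polish <- function(g, typ_, ba_, w2m_, sig2_) {
    # scalar fallback where the batched search stalled off a mode
    redo <- g$stalled & (do.call(pmax, lapply(seq_len(p), function(a)
      abs(g$grad[, a]))) > 1e-5)
    for (i in which(redo)) {
      rows_i <- which(ba_$mask[i, ] == 1)
      z <- ba_$Z[i, rows_i]; t <- ba_$Tm[i, rows_i]
      mode <- .inner_mode(z, t, typ_[i, ], rd, w2m_[i, ], sig2_[i],
                          g$eta[i, ], settings)
      g$eta[i, ] <- mode$eta
      g$val[i] <- mode$value
      ev1 <- .batch_eval(g$eta[i, , drop = FALSE], typ_, ba_, i, rd,
                         w2m_, sig2_)
      g$JJ[i, , ] <- ev1$JJ
      g$grad[i, ] <- ev1$grad
    }
    g
  }
  g1 <- polish(.gn_modes(typ, ba, rd, w2m, sig2, eta0, settings),
               typ, ba, w2m, sig2)
  po1 <- .persub_ofv(g1$eta, g1$val, g1$JJ, typ, ba, rd, w2m, sig2,
                     settings)
  if (!po1$ok) return(list(ofv = NA_real_, ok = FALSE, ebes = g1$eta))
  persub <- po1$persub
  ebes <- g1$eta
  # second search only where mode 1 is away from the prior mean
  need2 <- which(do.call(pmax, lapply(seq_len(p), function(a)
    abs(g1$eta[, a]))) > 1e-3)
  if (length(need2)) {
    ba2 <- list(Z = ba$Z[need2, , drop = FALSE],
                Tm = ba$Tm[need2, , drop = FALSE],
                mask = ba$mask[need2, , drop = FALSE],
                nobs = ba$nobs[need2])
    typ2 <- typ[need2, , drop = FALSE]
    w2m2 <- w2m[need2, , drop = FALSE]
    sig22 <- sig2[need2]
    g2 <- polish(.gn_modes(typ2, ba2, rd, w2m2, sig22,
                           -g1$eta[need2, , drop = FALSE], settings),
                 typ2, ba2, w2m2, sig22)
    po2 <- .persub_ofv(g2$eta, g2$val, g2$JJ, typ2, ba2, rd, w2m2, sig22,
                       settings)
    if (!po2$ok) return(list(ofv = NA_real_, ok = FALSE, ebes = ebes))
    o1 <- persub[need2]
    o2 <- po2$persub
    distinct <- do.call(pmax, lapply(seq_len(p), function(a)
      abs(g1$eta[need2, a] - g2$eta[, a]))) > 1e-4
    lo <- pmin(o1, o2)
    hi <- pmax(o1, o2)
    persub[need2] <- ifelse(distinct,
                            lo - 2 * log1p(exp(-(hi - lo) / 2)),
                            lo)
    swap <- distinct & (o2 < o1)
    if (any(swap)) ebes[need2[swap], ] <- g2$eta[swap, , drop = FALSE]
    better_same <- !distinct & (o2 < o1)
    if (any(better_same))
      ebes[need2[better_same], ] <- g2$eta[better_same, , drop = FALSE]
  }
  out <- list(ofv = sum(persub), ok = TRUE, ebes = ebes, persub = persub)
  if (collect_modes) {
    out$modes <- list(eta1 = g1$eta, A1 = po1$A,
                      idx2 = if (length(need2)) need2[distinct]
                             else integer(0),
                      eta2 = if (length(need2))
                        g2$eta[distinct, , drop = FALSE]
                      else matrix(0, 0, p),
                      A2 = if (length(need2))
                        po2$A[distinct, , , drop = FALSE]
                      else array(0, c(0, p, p)))
  }
  out
}

# per-subject Laplace -2 log contribution at given modes: joint value minus
# p log(2 pi) plus the log-determinant correction (Gauss-Newton curvature,
# or the full finite-difference Hessian where positive definite)
.persub_ofv <- function(eta, val, JJ, typ, ba, rd, w2m, sig2, settings) {
  ns <- nrow(eta)
  p <- length(rd)
  A <- (1 / sig2) * JJ
  for (a in seq_len(p)) A[, a, a] <- A[, a, a] + 1 / w2m[, a]
  if (settings$hessian == "fd") {
    g0 <- .batch_eval(eta, typ, ba, seq_len(ns), rd, w2m, sig2)$grad
    Hx <- array(0, c(ns, p, p))
    for (b in seq_len(p)) {
      hb <- 1e-5 * (1 + abs(eta[, b]))
      eb <- eta
      eb[, b] <- eb[, b] + hb
      gb <- .batch_eval(eb, typ, ba, seq_len(ns), rd, w2m, sig2)$grad
      Hx[, , b] <- (gb - g0) / hb
    }
    for (a in seq_len(p)) for (b in a:p)
      Hx[, a, b] <- Hx[, b, a] <- (Hx[, a, b] + Hx[, b, a]) / 4
    pd <- .batch_chol(Hx)$ok
    A[pd, , ] <- Hx[pd, , , drop = FALSE]
  }
  bc <- .batch_chol(A)
  if (!all(bc$ok) || !all(is.finite(bc$logdet)))
    return(list(ok = FALSE))
  list(ok = TRUE, persub = val - p * log(2 * pi) + bc$logdet, A = A)
}

# split a dataset into per-subject structures used by the estimator
.prep_subjects <- function(data) {
  df <- as.data.frame(data)
  df <- df[df$MDV == 0, , drop = FALSE]
  ids <- unique(df$ID)
  cov <- df[!duplicated(df$ID), c("ID", "GA", "BWT", "AKI", "DEATH")]
  ucov <- unique(cov[c("GA", "AKI", "DEATH")])
  key <- function(g, a, d) paste(g, a, d, sep = "|")
  ukey <- key(ucov$GA, ucov$AKI, ucov$DEATH)
  covkey <- key(cov$GA, cov$AKI, cov$DEATH)
  subs <- lapply(seq_along(ids), function(i) {
    rows <- df$ID == ids[i]
    list(id = ids[i], z = log(df$DV[rows]), t = df$TIME[rows],
         ucov_idx = match(covkey[i], ukey))
  })
  ucov_df <- data.frame(ga = ucov$GA, aki = ucov$AKI, death = ucov$DEATH)
  prep <- list(subs = subs, ucov = ucov_df, ids = ids,
               n_obs = nrow(df), cov = cov)
  prep$batch <- .batch_arrays(prep)
  prep
}

# population -2 log marginal likelihood over prepared subjects. eta0_mat
# holds *frozen* per-subject inner starting values (never mutated here), so
# the objective is a deterministic smooth function of the population
# parameters; the fitter refreshes the matrix between optimisation epochs.
.marginal_ofv <- function(model, prep, settings, eta0_mat = NULL,
                          collect = FALSE) {
  rd <- names(model$omega2)[model$omega2 > 0]
  w2 <- model$omega2[rd]
  sigma2 <- model$sigma2
  typ_mat <- resolve_typicals(model, prep$ucov)
  subs <- prep$subs
  nsub <- length(subs)
  p <- length(rd)
  use_linear <- settings$linear_fast_path && identical(rd, "ksyn_gfr0") &&
    settings$method == "laplace"
  if (p > 0 && !use_linear && settings$method == "laplace") {
    typ <- typ_mat[prep$batch$ucov_idx, , drop = FALSE]
    e0 <- if (is.null(eta0_mat)) matrix(0, nsub, p)
          else eta0_mat[, seq_len(p), drop = FALSE]
    w2m <- matrix(w2, nsub, p, byrow = TRUE)
    res <- .laplace_batch(typ, prep$batch, rd, w2m, rep(sigma2, nsub),
                          e0, settings)
    out <- list(ofv = res$ofv, ok = res$ok)
    if (collect) {
      dimnames(res$ebes) <- list(prep$ids, rd)
      out$ebes <- res$ebes
    }
    return(out)
  }
  ofv <- 0
  ok <- TRUE
  ebes <- if (collect) matrix(0, nsub, max(p, 0),
                              dimnames = list(prep$ids, rd))
  for (i in seq_len(nsub)) {
    s <- subs[[i]]
    typ <- typ_mat[s$ucov_idx, ]
    if (p == 0) {
      m0 <- .mean_and_jac(s$t, typ, character(0), jac = FALSE)$m
      res <- list(ofv = length(s$z) * log(2 * pi * sigma2) +
                    sum((s$z - m0)^2) / sigma2, ok = TRUE)
    } else if (use_linear) {
      res <- .linear_marginal(s$z, s$t, typ, w2, sigma2)
      if (collect) res$eta <- rep(res$eta, p)
    } else {
      eta0 <- if (!is.null(eta0_mat)) eta0_mat[i, seq_len(p)] else rep(0, p)
      res <- if (settings$method == "importance")
        .importance_subject(s$z, s$t, typ, rd, w2, sigma2, eta0, settings)
      else
        .laplace_subject(s$z, s$t, typ, rd, w2, sigma2, eta0, settings)
    }
    if (!res$ok || !is.finite(res$ofv)) { ok <- FALSE; ofv <- NA_real_; break }
    ofv <- ofv + res$ofv
    if (collect && p > 0) ebes[i, ] <- res$eta
  }
  out <- list(ofv = ofv, ok = ok)
  if (collect) out$ebes <- ebes
  out
}

#' Approximate -2 log marginal likelihood (OFV) of a population model
#'
#' Integrates the subject-level random effects out of the joint likelihood,
#' either by the Laplace approximation at the per-subject mode (with a
#' log-determinant curvature correction) or by importance sampling with a
#' mode-centred Gaussian proposal, and sums over subjects. OFV values are
#' comparable between nested fits of this implementation, not across
#' software.
#'
#' @param model An [scr_model] with `sigma2 > 0`.
#' @param data An [scr_dataset]; every subject needs at least one
#'   observation.
#' @param method Overrides `settings$method` if given.
#' @param settings An [scr_settings] list.
#' @return The OFV (scalar). Attribute `"ok"` is `FALSE` when any subject's
#'   curvature was not positive definite (flagged non-convergence).
#' @export
marginal_neg2ll <- function(model, data, method = NULL,
                            settings = scr_settings()) {
  stopifnot(inherits(model, "scr_model"))
  if (model$sigma2 <= 0) stop("estimation requires sigma2 > 0",
                              call. = FALSE)
  if (!is.null(method)) settings$method <- match.arg(method,
                                                     c("laplace",
                                                       "importance"))
  prep <- .prep_subjects(data)
  res <- .marginal_ofv(model, prep, settings)
  structure(res$ofv, ok = res$ok)
}
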