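# ---- outer parameterisation -------------------------------------------------
# The population optimisation works on log-transformed free parameters:
# typical values (or split-level values), between-subject variances of the
# non-fixed parameters, and the residual variance.

.build_map <- function(model, settings) {
  est <- setdiff(.scr_param_names, model$fixed)
  entries <- list()
  split_targets <- vapply(Filter(function(e) e$kind == "split",
                                 model$effects), `[[`, "", "target")
  for (p in est) {
    if (p %in% split_targets) {
      ef <- Filter(function(e) e$kind == "split" && e$target == p,
                   model$effects)[[1]]
      for (key in sort(names(ef$levels)))
        entries <- c(entries, list(list(type = "level", param = p,
                                        key = key)))
    } else {
      entries <- c(entries, list(list(type = "theta", param = p)))
    }
  }
  for (p in est) if (model$omega2[[p]] > 0 &&
                     !p %in% settings$fix_omega2)
    entries <- c(entries, list(list(type = "omega2", param = p)))
  entries <- c(entries, list(list(type = "sigma2")))
  names(entries) <- vapply(entries, function(e) switch(e$type,
    theta = e$param,
    level = paste0(e$param, "[", e$key, "]"),
    omega2 = paste0("omega2.", e$param),
    sigma2 = "sigma2"), "")
  entries
}

.map_get <- function(model, map) {
  vapply(map, function(e) switch(e$type,
    theta = model$theta[[e$param]],
    level = {
      ef <- Filter(function(x) x$kind == "split" && x$target == e$param,
                   model$effects)[[1]]
      ef$levels[[e$key]]
    },
    omega2 = model$omega2[[e$param]],
    sigma2 = model$sigma2), numeric(1))
}

.map_set <- function(model, map, values) {
  for (i in seq_along(map)) {
    e <- map[[i]]; v <- values[i]
    if (e$type == "theta") model$theta[[e$param]] <- v
    else if (e$type == "level") {
      for (j in seq_along(model$effects)) {
        ef <- model$effects[[j]]
        if (ef$kind == "split" && ef$target == e$param) {
          model$effects[[j]]$levels[[e$key]] <- v
          if (e$key == sort(names(ef$levels))[1])
            model$theta[[e$param]] <- v   # keep placeholder in range
        }
      }
    }
    else if (e$type == "omega2") model$omega2[[e$param]] <- v
    else model$sigma2 <- v
  }
  model
}

.map_bounds <- function(map, settings) {
  lo <- hi <- numeric(length(map))
  for (i in seq_along(map)) {
    e <- map[[i]]
    b <- switch(e$type,
                theta = , level = settings$theta_bounds,
                omega2 = settings$omega2_bounds,
                sigma2 = settings$sigma2_bounds)
    if (e$type %in% c("theta", "level") && e$param == "gamma")
      b[2] <- min(b[2], settings$gamma_max)
    lo[i] <- log(b[1]); hi[i] <- log(b[2])
  }
  list(lower = lo, upper = hi)
}

#' Fit the population sCr model by maximum marginal likelihood
#'
#' Minimises the approximate -2 log marginal likelihood
#' ([marginal_neg2ll]) over the free typical values (including
#' dichotomous-split level values), the between-subject variances of the
#' non-fixed parameters, and the residual variance, all log-reparameterised
#' to enforce positivity. Parameters named in `model$fixed` (here the
#' back-flow block) keep their typical values and variances; their random
#' effects are still integrated over.
#'
#' @param data An [scr_dataset] (already filtered/converted; fitting uses
#'   `log(DV)`).
#' @param start An [scr_model] providing the model structure and starting
#'   values.
#' @param settings An [scr_settings] list.
#' @param compute_se Also compute standard errors ([standard_errors]);
#'   requires a finite-difference Hessian of the OFV and is the slow step,
#'   hence off by default.
#' @param init `"direct"` starts the optimisation at `start` as given;
#'   `"pooled"` first fits the typical values under a pooled fixed-effects
#'   model (all variances zero) and starts the mixed fit from that point,
#'   which is robust to distant starting values.
#' @return An object of class `"scr_fit"`: list with `model` (the fitted
#'   [scr_model]), `ofv`, `ebes` (subjects x random effects), `shrinkage_pct`,
#'   `converged`, `message`, `n_subjects`, `n_obs`, `estimates` (named
#'   vector of free parameters), `se`/`rse_pct` (if computed), `data`,
#'   `settings`.
#' @seealso [coef.scr_fit], [predict.scr_fit], [residuals.scr_fit],
#'   [simulate.scr_fit], [vpc]
#' @export
scr_fit <- function(data, start, settings = scr_settings(),
                    compute_se = FALSE, init = c("direct", "pooled")) {
  stopifnot(inherits(start, "scr_model"))
  init <- match.arg(init)
  if (start$sigma2 <= 0) stop("starting sigma2 must be > 0", call. = FALSE)
  if (init == "pooled" && any(start$omega2[setdiff(.scr_param_names,
                                                   start$fixed)] > 0)) {
    # stage the fit: locate the typical-value surface with a pooled
    # fixed-effects fit first (all variances off), then start the mixed
    # fit from there; distant starting values otherwise risk the local
    # optima created by variance/typical-value trade-offs
    pooled <- start
    pooled$omega2[] <- 0
    pre <- scr_fit(data, pooled, settings = settings, init = "direct")
    staged <- pre$model
    staged$omega2 <- start$omega2
    staged$sigma2 <- start$sigma2
    return(scr_fit(data, staged, settings = settings,
                   compute_se = compute_se, init = "direct"))
  }
  prep <- .prep_subjects(data)
  if (any(vapply(prep$subs, function(s) length(s$z), 1L) < 1))
    stop("every subject needs at least one observation", call. = FALSE)
  map <- .build_map(start, settings)
  x0 <- log(.map_get(start, map))
  bb <- .map_bounds(map, settings)
  x0 <- pmin(pmax(x0, bb$lower), bb$upper)
  rd <- names(start$omega2)[start$omega2 > 0]
  p <- length(rd)
  nsub <- length(prep$subs)
  eta0 <- matrix(0, nsub, p)
  cache <- new.env(parent = emptyenv())
  objective <- function(x) {
    m <- .map_set(start, map, exp(x))
    res <- .marginal_ofv(m, prep, settings, eta0_mat = eta0)
    if (!res$ok || !is.finite(res$ofv)) return(1e10)
    cache$x <- x
    cache$f <- res$ofv
    res$ofv
  }
  # explicit forward-difference gradient evaluated as one stacked batch
  # (all perturbations and subjects in a single vectorised Laplace pass)
  use_batch_grad <- p > 0 && settings$method == "laplace" &&
    !(settings$linear_fast_path && identical(rd, "ksyn_gfr0"))
  gradient <- NULL
  if (use_batch_grad) {
    npar <- length(map)
    ba <- prep$batch
    seg <- rep(seq_len(nsub), npar)
    ba_big <- list(Z = ba$Z[seg, , drop = FALSE],
                   Tm = ba$Tm[seg, , drop = FALSE],
                   mask = ba$mask[seg, , drop = FALSE],
                   nobs = ba$nobs[seg])
    grp <- rep(seq_len(npar), each = nsub)
    hstep <- 1e-6
    gradient <- function(x) {
      f0 <- if (!is.null(cache$x) && isTRUE(all.equal(cache$x, x,
                                                      tolerance = 0)))
        cache$f else objective(x)
      typs <- w2s <- s2s <- vector("list", npar)
      for (k in seq_len(npar)) {
        xk <- x
        xk[k] <- xk[k] + hstep
        mk <- .map_set(start, map, exp(xk))
        typs[[k]] <- resolve_typicals(mk, prep$ucov)[ba$ucov_idx, ,
                                                     drop = FALSE]
        w2s[[k]] <- matrix(mk$omega2[rd], nsub, p, byrow = TRUE)
        s2s[[k]] <- rep(mk$sigma2, nsub)
      }
      res <- .laplace_batch(do.call(rbind, typs), ba_big, rd,
                            do.call(rbind, w2s), unlist(s2s),
                            eta0[seg, , drop = FALSE], settings)
      if (!res$ok) return(rep(0, npar))   # flat: forces re-evaluation
      fk <- rowsum(res$persub, grp)
      drop(fk - f0) / hstep
    }
  }
  # optimisation epochs: within an epoch the per-subject inner starting
  # values are frozen (deterministic objective); between epochs they are
  # refreshed at the incumbent optimum, restarting the quasi-Newton search
  x_cur <- x0
  ofv_prev <- Inf
  opt <- NULL
  stable <- FALSE
  for (epoch in seq_len(settings$max_epochs)) {
    opt <- stats::nlminb(x_cur, objective, gradient = gradient,
                         lower = bb$lower, upper = bb$upper,
                         control = list(rel.tol = settings$outer_tol,
                                        iter.max = settings$outer_iter_max,
                                        eval.max =
                                          4 * settings$outer_iter_max))
    x_cur <- opt$par
    mid <- .marginal_ofv(.map_set(start, map, exp(x_cur)), prep, settings,
                         eta0_mat = eta0, collect = TRUE)
    if (mid$ok && length(rd)) eta0 <- mid$ebes
    if (settings$trace)
      message(sprintf("epoch %d: OFV %.4f (%s)", epoch, opt$objective,
                      opt$message))
    if (is.finite(opt$objective) &&
        abs(ofv_prev - opt$objective) < settings$epoch_tol) {
      stable <- TRUE
      break
    }
    ofv_prev <- opt$objective
  }
  converged <- stable
  refine_msg <- NULL
  if (settings$refine == "importance" && p > 0) {
    ref <- .refine_importance(start, map, x_cur, prep, settings, bb)
    if (settings$trace)
      message(sprintf("IS refinement: OFV %.4f (%s)", ref$objective,
                      ref$message))
    x_cur <- ref$par
    converged <- ref$converged
    refine_msg <- ref$message
  }
  fitted_model <- .map_set(start, map, exp(x_cur))
  final <- .marginal_ofv(fitted_model, prep, settings, eta0_mat = eta0,
                         collect = TRUE)
  converged <- converged && final$ok && final$ofv < 1e9
  rd <- names(fitted_model$omega2)[fitted_model$omega2 > 0]
  shr <- if (length(rd) && !is.null(final$ebes))
    eta_shrinkage(final$ebes, fitted_model$omega2[rd])
  else setNames(numeric(0), character(0))
  fit <- structure(list(model = fitted_model, ofv = final$ofv,
                        estimates = setNames(exp(x_cur), names(map)),
                        map = map, ebes = final$ebes,
                        shrinkage_pct = shr, converged = converged,
                        message = if (is.null(refine_msg)) opt$message
                                  else refine_msg,
                        n_subjects = length(prep$subs),
                        n_obs = prep$n_obs, data = data,
                        settings = settings, se = NULL, rse_pct = NULL),
                   class = "scr_fit")
  if (compute_se) {
    se <- standard_errors(fit)
    fit$se <- se$se; fit$rse_pct <- se$rse_pct
  }
  fit
}

#' Empirical Bayes estimates of the subject-level random effects
#'
#' For each subject, minimises the joint -2 log-likelihood
#' ([joint_neg2ll]) over `eta` at the given population parameters (the
#' posterior mode).
#'
#' @param model An [scr_model] with at least one `omega2 > 0`.
#' @param data An [scr_dataset].
#' @param settings An [scr_settings] list.
#' @return A subjects x random-effects matrix of eta-hat values (rownames =
#'   subject IDs).
#' @export
empirical_bayes <- function(model, data, settings = scr_settings()) {
  stopifnot(inherits(model, "scr_model"))
  rd <- names(model$omega2)[model$omega2 > 0]
  if (!length(rd)) stop("model has no random effects", call. = FALSE)
  prep <- .prep_subjects(data)
  typ_mat <- resolve_typicals(model, prep$ucov)
  w2 <- model$omega2[rd]
  out <- matrix(NA_real_, length(prep$subs), length(rd),
                dimnames = list(prep$ids, rd))
  for (i in seq_along(prep$subs)) {
    s <- prep$subs[[i]]
    typ <- typ_mat[s$ucov_idx, ]
    mode <- tryCatch(
      .inner_mode(s$z, s$t, typ, rd, w2, model$sigma2,
                  rep(0, length(rd)), settings),
      error = function(e)
        stop("empirical Bayes optimisation failed for subject ", s$id,
             call. = FALSE))
    out[i, ] <- mode$eta
  }
  out
}

#' Shrinkage of the empirical Bayes estimate distribution
#'
#' `100 * (1 - SD(eta-hat) / omega)` per random effect: 0% when the EBEs
#' are as dispersed as the population distribution, approaching 100% when
#' uninformative data collapse them to zero.
#'
#' @param ebes Subjects x random-effects matrix of EBEs.
#' @param omega2 Named variances matching the EBE columns.
#' @return Named percentage vector; `NA` where `omega2 = 0`.
#' @export
eta_shrinkage <- function(ebes, omega2) {
  ebes <- as.matrix(ebes)
  if (nrow(ebes) < 2) stop("shrinkage needs at least 2 subjects",
                           call. = FALSE)
  omega2 <- omega2[colnames(ebes)]
  out <- 100 * (1 - apply(ebes, 2, stats::sd) / sqrt(omega2))
  out[omega2 == 0] <- NA_real_
  out
}

#' Coefficient of variation of a lognormal between-subject distribution
#'
#' `%CV = 100 * sqrt(exp(omega2) - 1)`.
#'
#' @param omega2 Variance(s) on the log scale (>= 0).
#' @return Percent coefficient of variation.
#' @export
cv_percent <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be >= 0", call. = FALSE)
  100 * sqrt(exp(omega2) - 1)
}

#' Standard errors of the population estimates
#'
#' Inverts the observed information: a central finite-difference Hessian of
#' the marginal -2 log-likelihood over the log-transformed free parameters
#' at the optimum, with a delta-method back-transform to the natural scale.
#'
#' @param fit An `"scr_fit"` object.
#' @return A list with `se` and `rse_pct` (`100 * se / |estimate|`), named
#'   as in `fit$estimates`. Fixed parameters have no entries. If the
#'   information matrix is singular, the values are `NA` with a warning.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "scr_fit"))
  prep <- .prep_subjects(fit$data)
  map <- fit$map
  eta0 <- fit$ebes   # frozen inner starts: deterministic objective
  objective <- function(x) {
    m <- .map_set(fit$model, map, exp(x))
    res <- .marginal_ofv(m, prep, fit$settings, eta0_mat = eta0)
    if (!res$ok || !is.finite(res$ofv)) return(1e10)
    res$ofv
  }
  xhat <- log(fit$estimates)
  H <- stats::optimHess(xhat, objective)
  cov_log <- tryCatch(2 * solve(H), error = function(e) NULL)
  est <- fit$estimates
  if (is.null(cov_log) || any(diag(cov_log) < 0)) {
    warning("information matrix singular or not positive definite; ",
            "standard errors unavailable")
    se <- setNames(rep(NA_real_, length(est)), names(est))
    return(list(se = se, rse_pct = se))
  }
  se_log <- sqrt(diag(cov_log))
  se <- est * se_log              # delta method for the log transform
  rse <- 100 * se / abs(est)
  list(se = setNames(se, names(est)), rse_pct = setNames(rse, names(est)))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.scr_fit <- function(x, ...) {
  cat("Population sCr kinetic model fit (Laplace marginal likelihood)\n")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f; converged: %s\n",
              x$n_subjects, x$n_obs, x$ofv, x$converged))
  cat("Estimates:\n")
  print(signif(x$estimates, 4))
  invisible(x)
}

#' @export
coef.scr_fit <- function(object, ...) object$estimates

#' @export
logLik.scr_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$estimates),
            nobs = object$n_obs, class = "logLik")
}

#' Summarise a population fit in the layout of a parameter table
#'
#' One row per free parameter: estimate, %RSE (if computed), and for
#' between-subject variances the lognormal %CV ([cv_percent]); plus
#' shrinkage per random effect.
#'
#' @param object An `"scr_fit"`.
#' @param ... Unused.
#' @return An object of class `"summary.scr_fit"`.
#' @export
summary.scr_fit <- function(object, ...) {
  est <- object$estimates
  is_om <- startsWith(names(est), "omega2.")
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    rse_pct = if (is.null(object$rse_pct)) NA_real_
                              else unname(object$rse_pct),
                    cv_pct = ifelse(is_om, cv_percent(pmax(unname(est), 0)),
                                    NA_real_))
  structure(list(table = tab, shrinkage_pct = object$shrinkage_pct,
                 ofv = object$ofv, converged = object$converged,
                 n_subjects = object$n_subjects, n_obs = object$n_obs),
            class = "summary.scr_fit")
}

#' @export
print.summary.scr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Fit of %d subjects / %d observations, OFV %.3f (%s)\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, digits)
  tab$rse_pct <- signif(tab$rse_pct, 3)
  tab$cv_pct <- signif(tab$cv_pct, 3)
  print(tab, row.names = FALSE)
  if (length(x$shrinkage_pct)) {
    cat("Eta shrinkage (%):\n")
    print(round(x$shrinkage_pct, 1))
  }
  invisible(x)
}

#' Model predictions for the fitted data or new data
#'
#' @param object An `"scr_fit"`.
#' @param newdata Optional [scr_dataset]; defaults to the fitted data.
#' @param type `"population"` (typical-value prediction, eta = 0) or
#'   `"individual"` (empirical Bayes prediction).
#' @param ... Unused.
#' @return Predicted sCr (mg/dL) per observation row.
#' @export
predict.scr_fit <- function(object, newdata = NULL,
                            type = c("population", "individual"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  prep <- .prep_subjects(data)
  model <- object$model
  typ_mat <- resolve_typicals(model, prep$ucov)
  rd <- names(model$omega2)[model$omega2 > 0]
  ebes <- if (type == "individual") empirical_bayes(model, data,
                                                    object$settings)
  out <- numeric(0)
  for (i in seq_along(prep$subs)) {
    s <- prep$subs[[i]]
    p7 <- typ_mat[s$ucov_idx, ]
    if (type == "individual" && length(rd))
      p7[rd] <- p7[rd] * exp(ebes[i, ])
    out <- c(out, exp(.mean_and_jac(s$t, p7, character(0),
                                    jac = FALSE)$m))
  }
  out
}

#' @export
fitted.scr_fit <- function(object, ...) predict(object, type = "individual")

#' Weighted residuals of a population fit
#'
#' @param object An `"scr_fit"`.
#' @param type `"cwres"` (conditional weighted residuals, default) or
#'   `"ciwres"` (individual weighted residuals at the EBEs).
#' @param ... Unused.
#' @return Per-observation residual vector (see [cwres], [ciwres]).
#' @export
residuals.scr_fit <- function(object, type = c("cwres", "ciwres"), ...) {
  type <- match.arg(type)
  if (type == "cwres") cwres(object$model, object$data, object$settings)
  else ciwres(object$model, object$data, settings = object$settings)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new random effects and residual errors at the design (times and
#' covariates) of the fitted data; the backbone of the visual predictive
#' check.
#'
#' @param object An `"scr_fit"` or [scr_model] plus data.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed (local to this call).
#' @param ... Unused.
#' @return A list of `nsim` numeric vectors of simulated DVs aligned with
#'   the observation rows of the fitted data.
#' @export
simulate.scr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .simulate_replicates(object$model, object$data, nsim, seed)
}

.simulate_replicates <- function(model, data, nsim, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  prep <- .prep_subjects(data)
  typ_mat <- resolve_typicals(model, prep$ucov)
  rd <- names(model$omega2)[model$omega2 > 0]
  w <- sqrt(model$omega2[rd])
  sd_eps <- sqrt(model$sigma2)
  lapply(seq_len(nsim), function(rep) {
    unlist(lapply(prep$subs, function(s) {
      p7 <- typ_mat[s$ucov_idx, ]
      if (length(rd))
        p7[rd] <- p7[rd] * exp(stats::rnorm(length(rd), 0, w))
      m <- .mean_and_jac(s$t, p7, character(0), jac = FALSE)$m
      exp(m + stats::rnorm(length(s$t), 0, sd_eps))
    }), use.names = FALSE)
  })
}

#' @export
plot.scr_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  obs <- as.data.frame(x$data)
  obs <- obs[obs$MDV == 0, ]
  ipred <- predict(x, type = "individual")
  plot(ipred, obs$DV, xlab = "Individual prediction (mg/dL)",
       ylab = "Observed sCr (mg/dL)", pch = 16,
       col = grDevices::adjustcolor("black", 0.4))
  graphics::abline(0, 1, col = "red")
  cw <- residuals(x, "cwres")
  plot(obs$TIME, cw, xlab = "Postnatal age (day)", ylab = "CWRES",
       pch = 16, col = grDevices::adjustcolor("black", 0.4))
  graphics::abline(h = 0, col = "red")
  invisible(x)
}

#' Write a fit report as aligned text plus a JSON twin
#'
#' @param fit An `"scr_fit"`.
#' @param path Output path for the text report; the JSON twin replaces the
#'   extension with `.json` (written only if the jsonlite package is
#'   available).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  s <- summary(fit)
  lines <- c(
    sprintf("subjects %d", s$n_subjects),
    sprintf("observations %d", s$n_obs),
    sprintf("ofv %.6f", s$ofv),
    sprintf("converged %s", s$converged),
    sprintf("%-22s %12s %8s %8s", "parameter", "estimate", "rse_pct",
            "cv_pct"),
    sprintf("%-22s %12.6g %8.3g %8.3g", s$table$parameter,
            s$table$estimate, s$table$rse_pct, s$table$cv_pct))
  writeLines(lines, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jpath <- sub("\\.[^.]*$", ".json", path)
    jsonlite::write_json(
      list(n_subjects = s$n_subjects, n_obs = s$n_obs, ofv = s$ofv,
           converged = s$converged,
           estimates = as.list(setNames(s$table$estimate,
                                        s$table$parameter)),
           shrinkage_pct = as.list(s$shrinkage_pct)),
      jpath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
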