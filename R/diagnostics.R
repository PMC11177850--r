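#' Conditional weighted residuals (CWRES)
#'
#' First-order-conditional residuals on the log scale: the model is
#' linearised in the random effects at each subject's empirical Bayes mode,
#' giving the marginal mean `m(eta-hat) - J eta-hat` and covariance
#' `J Omega J' + sigma2 I`; the residual vector is whitened by the inverse
#' Cholesky factor of that covariance.
#'
#' @param model An [scr_model].
#' @param data An [scr_dataset].
#' @param settings An [scr_settings] list.
#' @return Per-observation residual vector in data order (observed rows
#'   only). Under the true model these are approximately standard normal.
#' @export
cwres <- function(model, data, settings = scr_settings()) {
  stopifnot(inherits(model, "scr_model"))
  prep <- .prep_subjects(data)
  typ_mat <- resolve_typicals(model, prep$ucov)
  rd <- names(model$omega2)[model$omega2 > 0]
  w2 <- model$omega2[rd]
  ebes <- if (length(rd)) empirical_bayes(model, data, settings)
  out <- vector("list", length(prep$subs))
  for (i in seq_along(prep$subs)) {
    s <- prep$subs[[i]]
    typ <- typ_mat[s$ucov_idx, ]
    if (!length(rd)) {
      m0 <- .mean_and_jac(s$t, typ, character(0), jac = FALSE)$m
      out[[i]] <- (s$z - m0) / sqrt(model$sigma2)
      next
    }
    eta <- ebes[i, ]
    p7 <- typ
    p7[rd] <- p7[rd] * exp(eta)
    mj <- .mean_and_jac(s$t, p7, rd)
    mu <- mj$m - drop(mj$J %*% eta)
    V <- mj$J %*% (w2 * t(mj$J)) + diag(model$sigma2, length(s$t))
    ch <- tryCatch(chol(V), error = function(e)
      stop("singular conditional covariance for subject ", s$id,
           call. = FALSE))
    out[[i]] <- drop(backsolve(ch, s$z - mu, transpose = TRUE))
  }
  unlist(out, use.names = FALSE)
}

#' Individual weighted residuals at the empirical Bayes estimates (CIWRES)
#'
#' `(log DV - log individual prediction) / sigma` with the individual
#' prediction evaluated at each subject's EBE parameters.
#'
#' @param model An [scr_model].
#' @param data An [scr_dataset].
#' @param ebes Optional precomputed EBE matrix ([empirical_bayes]).
#' @param settings An [scr_settings] list.
#' @return Per-observation residual vector in data order.
#' @export
ciwres <- function(model, data, ebes = NULL, settings = scr_settings()) {
  stopifnot(inherits(model, "scr_model"))
  prep <- .prep_subjects(data)
  typ_mat <- resolve_typicals(model, prep$ucov)
  rd <- names(model$omega2)[model$omega2 > 0]
  if (length(rd) && is.null(ebes))
    ebes <- empirical_bayes(model, data, settings)
  sd_eps <- sqrt(model$sigma2)
  out <- vector("list", length(prep$subs))
  for (i in seq_along(prep$subs)) {
    s <- prep$subs[[i]]
    p7 <- typ_mat[s$ucov_idx, ]
    if (length(rd)) p7[rd] <- p7[rd] * exp(ebes[i, ])
    m <- .mean_and_jac(s$t, p7, character(0), jac = FALSE)$m
    out[[i]] <- (s$z - m) / sd_eps
  }
  unlist(out, use.names = FALSE)
}

#' Visual predictive check
#'
#' Simulates `n_reps` replicate datasets at the observed design (each
#' subject's covariates and sampling times), bins observations by postnatal
#' age, and contrasts the observed 5th/50th/95th percentiles per bin with
#' the 95% envelope (2.5-97.5 percentiles across replicates) of the same
#' simulated percentiles. Bins holding fewer than `min_bin_n` observations
#' are merged with their left neighbour (the first bin merges right).
#'
#' @param model An [scr_model] (typically a fitted one).
#' @param data An [scr_dataset].
#' @param n_reps Number of simulation replicates (default 500).
#' @param bins Numeric vector of bin edges in days (default unit-day bins
#'   `0:10`).
#' @param seed Optional integer seed (local to this call).
#' @param min_bin_n Minimum observations per bin before merging (default 5).
#' @param settings An [scr_settings] list.
#' @return An object of class `"scr_vpc"`: `table` (bin, statistic,
#'   observed, sim_lo, sim_hi, n_obs), `bins` (edges after merging),
#'   `n_reps`, `merged` (message log).
#' @export
vpc <- function(model, data, n_reps = 500, bins = 0:10, seed = NULL,
                min_bin_n = 5, settings = scr_settings()) {
  stopifnot(inherits(model, "scr_model"), n_reps >= 1)
  df <- as.data.frame(data)
  df <- df[df$MDV == 0, , drop = FALSE]
  # order must match .prep_subjects / .simulate_replicates (by subject)
  df <- df[order(match(df$ID, unique(df$ID))), , drop = FALSE]
  edges <- sort(unique(bins))
  merged_log <- character(0)
  repeat {
    cnt <- table(cut(df$TIME, edges, include.lowest = TRUE, right = FALSE))
    small <- which(cnt < min_bin_n)
    if (!length(small)) break
    j <- small[1]
    drop_edge <- if (j == 1) 2L else j
    merged_log <- c(merged_log,
                    sprintf("merged bin %d (n=%d) with neighbour", j,
                            cnt[j]))
    edges <- edges[-drop_edge]
    if (length(edges) < 2) break
  }
  bin_id <- cut(df$TIME, edges, include.lowest = TRUE, right = FALSE)
  probs <- c(0.05, 0.5, 0.95)
  obs_q <- t(vapply(levels(bin_id), function(b)
    stats::quantile(df$DV[bin_id == b], probs, names = FALSE, type = 7),
    numeric(3)))
  sims <- .simulate_replicates(model, data, n_reps, seed)
  sim_q <- array(NA_real_, c(n_reps, nlevels(bin_id), 3))
  for (r in seq_len(n_reps)) {
    dv <- sims[[r]]
    sim_q[r, , ] <- t(vapply(seq_len(nlevels(bin_id)), function(b)
      stats::quantile(dv[as.integer(bin_id) == b], probs, names = FALSE,
                      type = 7), numeric(3)))
  }
  lo <- apply(sim_q, c(2, 3), stats::quantile, probs = 0.025,
              names = FALSE)
  hi <- apply(sim_q, c(2, 3), stats::quantile, probs = 0.975,
              names = FALSE)
  stat_names <- c("p5", "p50", "p95")
  tab <- do.call(rbind, lapply(1:3, function(k)
    data.frame(bin = levels(bin_id), statistic = stat_names[k],
               observed = obs_q[, k], sim_lo = lo[, k], sim_hi = hi[, k],
               n_obs = as.integer(table(bin_id)))))
  rownames(tab) <- NULL
  structure(list(table = tab, bins = edges, n_reps = n_reps,
                 merged = merged_log), class = "scr_vpc")
}

#' @export
print.scr_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check: %d replicates, %d bins\n",
              x$n_reps, length(x$bins) - 1))
  tab <- x$table
  tab$observed <- round(tab$observed, 3)
  tab$sim_lo <- round(tab$sim_lo, 3)
  tab$sim_hi <- round(tab$sim_hi, 3)
  print(tab, row.names = FALSE)
  if (length(x$merged)) cat(paste(x$merged, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.scr_vpc <- function(x, ...) {
  tab <- x$table
  mids <- (x$bins[-1] + x$bins[-length(x$bins)]) / 2
  plot(NULL, xlim = range(x$bins), ylim = range(tab$sim_lo, tab$sim_hi,
                                                tab$observed),
       xlab = "Postnatal age (day)", ylab = "sCr (mg/dL)", ...)
  cols <- c(p5 = "grey60", p50 = "steelblue", p95 = "grey60")
  for (st in unique(tab$statistic)) {
    sub <- tab[tab$statistic == st, ]
    graphics::polygon(c(mids, rev(mids)), c(sub$sim_lo, rev(sub$sim_hi)),
                      col = grDevices::adjustcolor(cols[st], 0.3),
                      border = NA)
    graphics::lines(mids, sub$observed, col = cols[st], lwd = 2,
                    lty = if (st == "p50") 1 else 2)
  }
  invisible(x)
}
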