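#' Draw individual structural parameters from the population model
#'
#' Each parameter is the covariate-adjusted typical value multiplied by
#' `exp(eta)` with `eta ~ N(0, omega2)` drawn independently per parameter;
#' parameters with zero variance return the typical value.
#'
#' @param model An [scr_model].
#' @param cov A single covariate row ([scr_covariates] or one-row data
#'   frame).
#' @param n Number of subjects to draw.
#' @param seed Optional integer seed (local to this call).
#' @return For `n = 1` an [scr_params] vector; otherwise an `n` x 7 matrix
#'   of per-subject parameters.
#' @export
sample_individual <- function(model, cov, n = 1, seed = NULL) {
  stopifnot(inherits(model, "scr_model"), n >= 1)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  typ <- resolve_typicals(model, cov)
  if (nrow(typ) == 1) typ <- typ[rep(1, n), , drop = FALSE]
  stopifnot(nrow(typ) == n)
  out <- typ
  for (p in .scr_param_names) {
    w2 <- model$omega2[[p]]
    if (w2 > 0) out[, p] <- out[, p] * exp(stats::rnorm(n, 0, sqrt(w2)))
  }
  if (n == 1) {
    v <- out[1, ]
    class(v) <- "scr_params"
    return(v)
  }
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate cohort-level sCr and GFR trajectory summaries
#'
#' Draws `n` subjects with the given covariates, evaluates each subject's
#' noise-free sCr and GFR/GFR0 curves on a postnatal-age grid, and summarises
#' them per grid time as the median and the 5th/95th percentiles across
#' subjects (a 90% prediction interval). Percentiles use the
#' linear-interpolation definition (R quantile type 7). No residual error is
#' applied.
#'
#' @param model An [scr_model].
#' @param cov A single covariate row shared by the simulated cohort.
#' @param n Number of simulated subjects (default 700).
#' @param grid Postnatal-age grid in days; default 0.1-day increments over
#'   (0, 10].
#' @param seed Optional integer seed (local to this call).
#' @return An object of class `"scr_trajectory"`: a list with the grid, the
#'   percentile arrays for sCr (mg/dL) and GFR/GFR0, `n_subjects` and
#'   `seed`.
#' @export
simulate_cohort_summary <- function(model, cov, n = 700,
                                    grid = seq(0.1, 10, by = 0.1),
                                    seed = NULL) {
  stopifnot(n >= 1)
  if (length(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  if (any(grid < 0)) stop("grid times must be >= 0", call. = FALSE)
  pars <- sample_individual(model, cov, n = n, seed = seed)
  if (is.null(dim(pars))) pars <- matrix(pars, nrow = 1,
                                         dimnames = list(NULL, names(pars)))
  nt <- length(grid)
  scr <- gfr <- matrix(NA_real_, nrow = n, ncol = nt)
  # vectorise over subjects at each grid time
  q0 <- pars[, "qmax_uf"]; kk <- pars[, "k"]; pp <- pars[, "pna_p"]
  ks <- pars[, "ksyn_gfr0"]; ss <- pars[, "gfrss_gfr0"]
  t50 <- pars[, "pna50"]; gm <- pars[, "gamma"]
  for (j in seq_len(nt)) {
    t <- grid[j]
    q <- q0 * exp(-(kk^2 / 2) * (t - pp)^2)
    g <- if (t > 0) 1 + (ss - 1) / (1 + (t50 / t)^gm) else rep(1, n)
    gfr[, j] <- g
    scr[, j] <- (1 + q) * ks / g
  }
  qs <- function(m) apply(m, 2, stats::quantile,
                          probs = c(0.05, 0.5, 0.95), names = FALSE,
                          type = 7)
  sq <- qs(scr); gq <- qs(gfr)
  structure(list(grid = grid,
                 scr_p5 = sq[1, ], scr_median = sq[2, ], scr_p95 = sq[3, ],
                 gfr_p5 = gq[1, ], gfr_median = gq[2, ], gfr_p95 = gq[3, ],
                 n_subjects = n, seed = seed),
            class = "scr_trajectory")
}

#' @export
print.scr_trajectory <- function(x, ...) {
  cat(sprintf(
    "Simulated trajectory summary: %d subjects, %d grid times (%.1f-%.1f d)\n",
    x$n_subjects, length(x$grid), min(x$grid), max(x$grid)))
  i <- which.min(abs(x$grid - max(x$grid)))
  cat(sprintf("  sCr median at day %.1f: %.3f mg/dL (90%% PI %.3f-%.3f)\n",
              x$grid[i], x$scr_median[i], x$scr_p5[i], x$scr_p95[i]))
  cat(sprintf("  GFR/GFR0 median at day %.1f: %.3f (90%% PI %.3f-%.3f)\n",
              x$grid[i], x$gfr_median[i], x$gfr_p5[i], x$gfr_p95[i]))
  invisible(x)
}

#' Tabulate a trajectory summary in long form
#'
#' @param x An `"scr_trajectory"` object.
#' @param row.names,optional,... Passed on conventionally (unused).
#' @return A data frame with columns `pna`, `quantity`, `percentile`,
#'   `value`.
#' @export
as.data.frame.scr_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  long <- function(qty, p5, p50, p95)
    data.frame(pna = rep(x$grid, 3),
               quantity = qty,
               percentile = rep(c(5, 50, 95), each = length(x$grid)),
               value = c(p5, p50, p95))
  rbind(long("scr", x$scr_p5, x$scr_median, x$scr_p95),
        long("gfr", x$gfr_p5, x$gfr_median, x$gfr_p95))
}

#' @export
plot.scr_trajectory <- function(x, quantity = c("scr", "gfr"), add = FALSE,
                                col = "steelblue", ...) {
  quantity <- match.arg(quantity)
  med <- x[[paste0(quantity, "_median")]]
  lo <- x[[paste0(quantity, "_p5")]]
  hi <- x[[paste0(quantity, "_p95")]]
  ylab <- if (quantity == "scr") "sCr (mg/dL)" else "GFR/GFR0"
  if (!add)
    plot(x$grid, med, type = "n", ylim = range(lo, hi),
         xlab = "Postnatal age (day)", ylab = ylab, ...)
  shade <- grDevices::adjustcolor(col, alpha.f = 0.25)
  graphics::polygon(c(x$grid, rev(x$grid)), c(lo, rev(hi)), col = shade,
                    border = NA)
  graphics::lines(x$grid, med, col = col, lwd = 2)
  invisible(x)
}

#' Contrast the median trajectories of two simulated cohorts
#'
#' Computes the elementwise difference of the median curves of two
#' [simulate_cohort_summary] results on a shared grid and locates the
#' largest absolute difference.
#'
#' @param summary_a,summary_b `"scr_trajectory"` objects on identical grids.
#' @param quantity `"scr"` or `"gfr"`.
#' @return A list with `max_difference` (of medians, `a - b` at the argmax
#'   of the absolute difference), `day` (grid time of the maximum),
#'   and `profile` (data frame `pna`, `difference`).
#' @export
compare_populations <- function(summary_a, summary_b,
                                quantity = c("scr", "gfr")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(summary_a, "scr_trajectory"),
            inherits(summary_b, "scr_trajectory"))
  if (length(summary_a$grid) != length(summary_b$grid) ||
      !isTRUE(all.equal(summary_a$grid, summary_b$grid)))
    stop("trajectory grids differ; simulate both cohorts on one grid",
         call. = FALSE)
  nm <- paste0(quantity, "_median")
  d <- summary_a[[nm]] - summary_b[[nm]]
  i <- which.max(abs(d))
  list(max_difference = d[i], day = summary_a$grid[i],
       profile = data.frame(pna = summary_a$grid, difference = d))
}
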