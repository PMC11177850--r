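#' Screen covariates against empirical Bayes estimates
#'
#' Computes the squared correlation between each random effect's EBEs and
#' each candidate covariate (Pearson; for a 0/1 covariate this is the
#' point-biserial r^2) and retains pairs exceeding the threshold.
#'
#' @param ebes Subjects x random-effects matrix ([empirical_bayes]).
#' @param covariates Data frame of per-subject covariates aligned with the
#'   EBE rows (e.g. columns `ga`, `aki`, `death`).
#' @param r2_threshold Retention threshold on r^2 (default 0.1).
#' @return A data frame with one row per (parameter, covariate) pair:
#'   `parameter`, `covariate`, `r2`, `candidate` (logical), `reason`.
#' @export
screen_covariates <- function(ebes, covariates, r2_threshold = 0.1) {
  ebes <- as.matrix(ebes)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(ebes) == nrow(covariates))
  out <- list()
  for (p in colnames(ebes)) {
    for (cv in names(covariates)) {
      x <- as.numeric(covariates[[cv]])
      y <- ebes[, p]
      if (stats::sd(x) == 0) {
        warning("covariate '", cv, "' has zero variance; excluded")
        out[[length(out) + 1]] <- data.frame(
          parameter = p, covariate = cv, r2 = NA_real_, candidate = FALSE,
          reason = "zero-variance covariate")
        next
      }
      r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
      out[[length(out) + 1]] <- data.frame(
        parameter = p, covariate = cv, r2 = r2,
        candidate = r2 > r2_threshold,
        reason = if (r2 > r2_threshold) "retained"
                 else sprintf("r2 <= %g", r2_threshold))
    }
  }
  do.call(rbind, out)
}

#' Likelihood-ratio test between nested population fits
#'
#' The statistic is the OFV drop of the full model relative to the reduced
#' model, referred to the upper tail of a chi-square with `df` degrees of
#' freedom.
#'
#' @param ofv_reduced,ofv_full OFVs of the nested fits (full <= reduced up
#'   to optimiser tolerance).
#' @param df Degrees of freedom (number of extra typical-value parameters).
#' @param alpha Significance level.
#' @param tol Tolerance for a slightly negative statistic from optimiser
#'   noise (clamped to 0); beyond it the nesting is considered violated.
#' @return A list with `chi2`, `p`, `significant`.
#' @export
lrt <- function(ofv_reduced, ofv_full, df, alpha = 0.001, tol = 0.01) {
  stopifnot(df >= 1)
  chi2 <- ofv_reduced - ofv_full
  if (chi2 < -tol)
    stop("full model has higher OFV than reduced model (delta = ",
         signif(chi2, 4), "); nested-fit violation", call. = FALSE)
  chi2 <- max(chi2, 0)
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, p = p, significant = p < alpha)
}

#' Add or remove a dichotomous-covariate term on a parameter
#'
#' `add_covariate_term` splits the parameter's typical value on the
#' covariate (or extends an existing split to the full cross), initialising
#' every new level at the current value. `drop_covariate_term` collapses the
#' split over that covariate, averaging levels as the new starting value.
#' The degrees of freedom gained/lost equal the change in the number of
#' level parameters.
#'
#' @param model An [scr_model].
#' @param param Target structural parameter name.
#' @param covariate A 0/1 covariate name (`"aki"`, `"death"`).
#' @return The modified model; attribute `"df"` carries the change in
#'   parameter count.
#' @export
add_covariate_term <- function(model, param, covariate) {
  stopifnot(param %in% .scr_param_names)
  idx <- which(vapply(model$effects, function(e)
    e$kind == "split" && e$target == param, TRUE))
  if (!length(idx)) {
    eff <- effect_split(param, covariate,
                        stats::setNames(rep(model$theta[[param]], 2),
                                        c("0", "1")))
    model$effects <- c(model$effects, list(eff))
    attr(model, "df") <- 1L
    return(model)
  }
  ef <- model$effects[[idx]]
  if (covariate %in% ef$covariates)
    stop("parameter '", param, "' already split on '", covariate, "'",
         call. = FALSE)
  old_n <- length(ef$levels)
  covs <- c(ef$covariates, covariate)
  new_levels <- c(stats::setNames(ef$levels,
                                  paste0(names(ef$levels), ":0")),
                  stats::setNames(ef$levels,
                                  paste0(names(ef$levels), ":1")))
  model$effects[[idx]] <- effect_split(param, covs, new_levels)
  attr(model, "df") <- length(new_levels) - old_n
  model
}

#' @rdname add_covariate_term
#' @export
drop_covariate_term <- function(model, param, covariate) {
  idx <- which(vapply(model$effects, function(e)
    e$kind == "split" && e$target == param, TRUE))
  if (!length(idx)) stop("no split on '", param, "'", call. = FALSE)
  ef <- model$effects[[idx]]
  pos <- match(covariate, ef$covariates)
  if (is.na(pos)) stop("'", param, "' is not split on '", covariate, "'",
                       call. = FALSE)
  old_n <- length(ef$levels)
  if (length(ef$covariates) == 1) {
    model$theta[[param]] <- mean(ef$levels)
    model$effects[[idx]] <- NULL
    attr(model, "df") <- -(old_n - 1L)
    return(model)
  }
  keys <- do.call(rbind, strsplit(names(ef$levels), ":"))
  rest <- apply(keys[, -pos, drop = FALSE], 1, paste, collapse = ":")
  new_levels <- tapply(ef$levels, rest, mean)
  model$effects[[idx]] <- effect_split(param, ef$covariates[-pos],
                                       stats::setNames(as.numeric(new_levels),
                                                       names(new_levels)))
  attr(model, "df") <- length(new_levels) - old_n
  model
}

#' Forward-inclusion backward-elimination covariate selection
#'
#' Greedy stepwise selection over (parameter, covariate) candidate pairs by
#' likelihood-ratio test: the forward phase repeatedly adds the candidate
#' with the largest OFV drop while its p-value is below `alpha_in`; the
#' backward phase removes included terms whose deletion is not significant
#' at `alpha_out` (least significant first). Ties break by larger OFV drop,
#' then alphabetical candidate name. A candidate whose intermediate fit
#' does not converge is skipped that round and logged.
#'
#' @param base An [scr_model]: the base model (starting values).
#' @param candidates Data frame with columns `parameter`, `covariate` (e.g.
#'   the retained rows of [screen_covariates]).
#' @param data An [scr_dataset].
#' @param alpha_in,alpha_out Inclusion / elimination significance levels
#'   (defaults 0.001 and 0.0001).
#' @param settings An [scr_settings] list.
#' @return An object of class `"scr_selection"`: list with `steps` (one row
#'   per tested candidate: step, phase, candidate, ofv_before, ofv_after,
#'   df, p_value, accepted), `final_model`, `final_fit`, `base_ofv`.
#' @export
forward_backward_select <- function(base, candidates, data,
                                    alpha_in = 0.001, alpha_out = 0.0001,
                                    settings = scr_settings()) {
  stopifnot(inherits(base, "scr_model"))
  candidates <- as.data.frame(candidates)
  if (nrow(candidates))
    candidates$name <- paste0(candidates$parameter, "~",
                              candidates$covariate)
  current_fit <- scr_fit(data, base, settings)
  base_ofv <- current_fit$ofv
  current_model <- current_fit$model
  included <- character(0)
  steps <- list()
  step_no <- 0L
  log_step <- function(phase, name, before, after, df, p, accepted) {
    step_no <<- step_no + 1L
    steps[[step_no]] <<- data.frame(step = step_no, phase = phase,
                                    candidate = name, ofv_before = before,
                                    ofv_after = after, df = df,
                                    p_value = p, accepted = accepted)
  }
  # forward phase
  repeat {
    open <- if (nrow(candidates))
      candidates[!candidates$name %in% included, , drop = FALSE]
    else candidates
    if (!NROW(open) || alpha_in <= 0) break
    trials <- list()
    for (i in seq_len(nrow(open))) {
      cand <- open[i, ]
      trial_model <- tryCatch(
        add_covariate_term(current_model, cand$parameter, cand$covariate),
        error = function(e) NULL)
      if (is.null(trial_model)) next
      df <- attr(trial_model, "df")
      fit <- tryCatch(scr_fit(data, trial_model, settings),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        log_step("forward", cand$name, current_fit$ofv, NA_real_, df,
                 NA_real_, FALSE)
        next
      }
      delta <- current_fit$ofv - fit$ofv
      p <- stats::pchisq(max(delta, 0), df, lower.tail = FALSE)
      trials[[length(trials) + 1]] <- list(cand = cand, fit = fit,
                                           df = df, delta = delta, p = p)
      log_step("forward", cand$name, current_fit$ofv, fit$ofv, df, p,
               FALSE)
    }
    if (!length(trials)) break
    ps <- vapply(trials, `[[`, 0, "p")
    sig <- ps < alpha_in
    if (!any(sig)) break
    deltas <- vapply(trials, `[[`, 0, "delta")
    nms <- vapply(trials, function(tr) tr$cand$name, "")
    ord <- order(!sig, -deltas, nms)
    best <- trials[[ord[1]]]
    included <- c(included, best$cand$name)
    current_fit <- best$fit
    current_model <- best$fit$model
    for (k in seq_along(steps))
      if (steps[[k]]$phase == "forward" &&
          steps[[k]]$candidate == best$cand$name &&
          isTRUE(all.equal(steps[[k]]$ofv_after, best$fit$ofv)))
        steps[[k]]$accepted <- TRUE
  }
  # backward phase
  repeat {
    if (!length(included)) break
    trials <- list()
    for (name in sort(included)) {
      parts <- strsplit(name, "~", fixed = TRUE)[[1]]
      trial_model <- tryCatch(
        drop_covariate_term(current_model, parts[1], parts[2]),
        error = function(e) NULL)
      if (is.null(trial_model)) next
      df <- -attr(trial_model, "df")
      fit <- tryCatch(scr_fit(data, trial_model, settings),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        log_step("backward", name, current_fit$ofv, NA_real_, df,
                 NA_real_, FALSE)
        next
      }
      delta <- fit$ofv - current_fit$ofv
      p <- stats::pchisq(max(delta, 0), df, lower.tail = FALSE)
      trials[[length(trials) + 1]] <- list(name = name, fit = fit,
                                           df = df, delta = delta, p = p)
      log_step("backward", name, current_fit$ofv, fit$ofv, df, p, FALSE)
    }
    if (!length(trials)) break
    ps <- vapply(trials, `[[`, 0, "p")
    removable <- ps >= alpha_out
    if (!any(removable)) break
    nms <- vapply(trials, `[[`, "", "name")
    ord <- order(!removable, -ps, nms)
    worst <- trials[[ord[1]]]
    included <- setdiff(included, worst$name)
    current_fit <- worst$fit
    current_model <- worst$fit$model
    for (k in seq_along(steps))
      if (steps[[k]]$phase == "backward" &&
          steps[[k]]$candidate == worst$name &&
          isTRUE(all.equal(steps[[k]]$ofv_after, worst$fit$ofv)))
        steps[[k]]$accepted <- TRUE
  }
  structure(list(steps = if (length(steps)) do.call(rbind, steps)
                 else data.frame(step = integer(0), phase = character(0),
                                 candidate = character(0),
                                 ofv_before = numeric(0),
                                 ofv_after = numeric(0), df = integer(0),
                                 p_value = numeric(0),
                                 accepted = logical(0)),
                 included = included, final_model = current_model,
                 final_fit = current_fit, base_ofv = base_ofv),
            class = "scr_selection")
}

#' @export
print.scr_selection <- function(x, ...) {
  cat("Forward-inclusion / backward-elimination covariate selection\n")
  cat(sprintf("  base OFV %.3f -> final OFV %.3f\n", x$base_ofv,
              x$final_fit$ofv))
  cat("  included terms:",
      if (length(x$included)) paste(x$included, collapse = ", ")
      else "(none)", "\n")
  if (nrow(x$steps)) {
    tab <- x$steps
    tab$ofv_before <- round(tab$ofv_before, 2)
    tab$ofv_after <- round(tab$ofv_after, 2)
    tab$p_value <- signif(tab$p_value, 3)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
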