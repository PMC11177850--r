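#' Population model of serum-creatinine kinetics
#'
#' Couples the structural model ([scr_value]) with covariate effects,
#' lognormal between-subject variability and a log-additive residual error.
#' Each subject's parameter is `P = theta_P(cov) * exp(eta_P)` with
#' `eta_P ~ N(0, omega2_P)` independently per parameter, and observations
#' follow `log sCr_ij = log sCr(PNA_j) + eps_ij`, `eps_ij ~ N(0, sigma2)`.
#'
#' @param theta Named numeric vector of typical values covering all seven
#'   structural parameters (see [scr_params] for names and units). For a
#'   parameter carrying a [effect_split], `theta` holds a placeholder that
#'   the split replaces.
#' @param effects List of [effect_linear] / [effect_split] objects. Splits
#'   replace the typical value, linear effects then scale (or shift) it,
#'   and `exp(eta)` is applied last.
#' @param omega2 Named numeric vector of between-subject variances on the
#'   log scale; parameters not listed (or 0) carry no variability.
#' @param sigma2 Residual variance of log sCr (>= 0; must be > 0 to fit).
#' @param fixed Character vector of parameter names whose typical value and
#'   variance are not estimated (the back-flow block in this analysis).
#' @return An object of class `"scr_model"`.
#' @export
scr_model <- function(theta, effects = list(), omega2 = numeric(0),
                      sigma2 = 0, fixed = character(0)) {
  if (!all(.scr_param_names %in% names(theta)))
    stop("theta must name all of: ",
         paste(.scr_param_names, collapse = ", "), call. = FALSE)
  theta <- theta[.scr_param_names]
  if (any(theta <= 0)) stop("typical values must be positive", call. = FALSE)
  om <- setNames(numeric(length(.scr_param_names)), .scr_param_names)
  if (length(omega2)) {
    if (!all(names(omega2) %in% .scr_param_names))
      stop("unknown omega2 name(s): ",
           paste(setdiff(names(omega2), .scr_param_names), collapse = ", "),
           call. = FALSE)
    if (any(omega2 < 0)) stop("omega2 must be >= 0", call. = FALSE)
    om[names(omega2)] <- omega2
  }
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!all(fixed %in% .scr_param_names))
    stop("unknown fixed parameter name(s)", call. = FALSE)
  if (length(effects)) {
    if (!all(vapply(effects, inherits, TRUE, "scr_effect")))
      stop("effects must be scr_effect objects", call. = FALSE)
    tgt <- vapply(effects, `[[`, "", "target")
    kd <- vapply(effects, `[[`, "", "kind")
    if (anyDuplicated(paste(tgt, kd)))
      stop("at most one split and one linear effect per parameter",
           call. = FALSE)
  }
  structure(list(theta = theta, effects = effects, omega2 = om,
                 sigma2 = sigma2, fixed = fixed), class = "scr_model")
}

#' @export
print.scr_model <- function(x, ...) {
  cat("Population sCr kinetic model\n")
  cat("Typical values:\n")
  print(signif(x$theta, 4))
  for (ef in x$effects) {
    if (ef$kind == "split")
      cat(sprintf("  split  %s ~ %s: %s\n", ef$target,
                  paste(ef$covariates, collapse = " x "),
                  paste(sprintf("%s=%g", names(ef$levels), ef$levels),
                        collapse = ", ")))
    else
      cat(sprintf("  linear %s ~ %s: slope %g, center %g (%s)\n",
                  ef$target, ef$covariate, ef$slope, ef$center, ef$form))
  }
  est <- x$omega2[x$omega2 > 0]
  if (length(est)) {
    cat("Between-subject variances (omega^2):\n")
    print(signif(est, 4))
  }
  cat(sprintf("Residual variance sigma^2 (log scale): %g\n", x$sigma2))
  if (length(x$fixed))
    cat("Fixed parameters:", paste(x$fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Covariate-adjusted typical parameter values
#'
#' Resolves the typical value of every structural parameter for each row of
#' a covariate table: split effects replace the typical value, linear
#' effects then adjust it. The between-subject random effect is *not*
#' applied here (see [sample_individual]).
#'
#' @param model An [scr_model].
#' @param cov A data frame of covariates (columns `ga`, `aki`, `death`, ...),
#'   one row per subject, or a single [scr_covariates] row.
#' @return A numeric matrix, rows = subjects, columns = the seven structural
#'   parameters.
#' @export
resolve_typicals <- function(model, cov) {
  stopifnot(inherits(model, "scr_model"))
  cov <- as.data.frame(cov)
  n <- nrow(cov)
  out <- matrix(rep(unname(model$theta), each = n), nrow = n,
                dimnames = list(NULL, .scr_param_names))
  for (ef in model$effects) {
    if (ef$kind == "split") {
      keys <- do.call(paste, c(lapply(ef$covariates, function(nm) {
        if (is.null(cov[[nm]])) stop("covariate '", nm, "' missing from data",
                                     call. = FALSE)
        as.integer(cov[[nm]])
      }), sep = ":"))
      bad <- !keys %in% names(ef$levels)
      if (any(bad))
        stop("no level value configured for combination ", keys[bad][1],
             call. = FALSE)
      out[, ef$target] <- unname(ef$levels[keys])
    }
  }
  for (ef in model$effects) {
    if (ef$kind == "linear") {
      if (is.null(cov[[ef$covariate]]))
        stop("covariate '", ef$covariate, "' missing from data",
             call. = FALSE)
      out[, ef$target] <- apply_continuous_covariate(
        out[, ef$target], ef$slope, cov[[ef$covariate]],
        center = ef$center, form = ef$form)
    }
  }
  out
}

# read a plain-text "key value" parameter table (one pair per line, '#'
# comments allowed); returns a named numeric vector
read_param_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(vals)) stop("non-numeric value in parameter table ", path,
                        call. = FALSE)
  setNames(vals, keys)
}

.fixture_path <- function(name)
  system.file("extdata", name, package = "neoscr", mustWork = TRUE)

# shared back-flow block (fixed in this analysis): typical values at the
# gestational-age reference plus linear GA effects on the peak height and
# peak time
.backflow_effects <- function(tab, covariate_form = "multiplicative") {
  list(
    effect_linear("qmax_uf", "ga", slope = tab[["ga_slope_qmax_uf"]],
                  center = tab[["ga_center"]], form = "multiplicative"),
    effect_linear("pna_p", "ga", slope = tab[["ga_slope_pna_p"]],
                  center = tab[["ga_center"]], form = covariate_form)
  )
}

.model_from_table <- function(tab, covariate_form) {
  effects <- .backflow_effects(tab, covariate_form)
  if ("pna50_aki0" %in% names(tab)) {
    effects <- c(effects, list(
      effect_split("pna50", "aki",
                   c("0" = tab[["pna50_aki0"]], "1" = tab[["pna50_aki1"]])),
      effect_split("gamma", "aki",
                   c("0" = tab[["gamma_aki0"]], "1" = tab[["gamma_aki1"]])),
      effect_split("ksyn_gfr0", c("aki", "death"),
                   c("0:0" = tab[["ksyn_gfr0_aki0_death0"]],
                     "1:0" = tab[["ksyn_gfr0_aki1_death0"]],
                     "0:1" = tab[["ksyn_gfr0_aki0_death1"]],
                     "1:1" = tab[["ksyn_gfr0_aki1_death1"]]))))
    theta <- c(qmax_uf = tab[["qmax_uf"]], k = tab[["k"]],
               pna_p = tab[["pna_p"]],
               ksyn_gfr0 = tab[["ksyn_gfr0_aki0_death0"]],
               gfrss_gfr0 = tab[["gfrss_gfr0"]],
               pna50 = tab[["pna50_aki0"]], gamma = tab[["gamma_aki0"]])
  } else {
    theta <- c(qmax_uf = tab[["qmax_uf"]], k = tab[["k"]],
               pna_p = tab[["pna_p"]], ksyn_gfr0 = tab[["ksyn_gfr0"]],
               gfrss_gfr0 = tab[["gfrss_gfr0"]], pna50 = tab[["pna50"]],
               gamma = tab[["gamma"]])
  }
  om <- c(qmax_uf = tab[["omega2_qmax_uf"]], k = tab[["omega2_k"]],
          pna_p = tab[["omega2_pna_p"]],
          ksyn_gfr0 = tab[["omega2_ksyn_gfr0"]],
          gfrss_gfr0 = tab[["omega2_gfrss_gfr0"]],
          pna50 = tab[["omega2_pna50"]], gamma = tab[["omega2_gamma"]])
  scr_model(theta = theta, effects = effects, omega2 = om,
            sigma2 = tab[["sigma2"]],
            fixed = c("qmax_uf", "k", "pna_p"))
}

#' Packaged population-model parameter sets
#'
#' `scr_model_th_final()` and `scr_model_th_base()` return the final
#' (covariate) and base population models estimated for the cooled-neonate
#' cohort; `scr_model_reference()` returns the reference (non-asphyxiated)
#' neonate model with its maturation parameters at the gestational-age-39
#' typical values. In all three the back-flow block (`qmax_uf`, `k`,
#' `pna_p`, their gestational-age slopes and variances) is fixed. The
#' reference set carries no between-subject variances for the maturation
#' parameters (they are not part of this packaged table) and no residual
#' variance; it is intended for typical-curve simulation and
#' population-contrast arithmetic.
#'
#' @param covariate_form Form of the gestational-age adjustment of the
#'   back-flow peak time `pna_p`: `"multiplicative"` (default) or
#'   `"additive"`. The published slope's units are ambiguous between the
#'   two readings; both are supported.
#' @return An [scr_model].
#' @export
scr_model_th_final <- function(covariate_form = c("multiplicative",
                                                  "additive")) {
  covariate_form <- match.arg(covariate_form)
  .model_from_table(read_param_table(.fixture_path("th_final_params.txt")),
                    covariate_form)
}

#' @rdname scr_model_th_final
#' @export
scr_model_th_base <- function(covariate_form = c("multiplicative",
                                                 "additive")) {
  covariate_form <- match.arg(covariate_form)
  .model_from_table(read_param_table(.fixture_path("th_base_params.txt")),
                    covariate_form)
}

#' @rdname scr_model_th_final
#' @export
scr_model_reference <- function(covariate_form = c("multiplicative",
                                                   "additive")) {
  covariate_form <- match.arg(covariate_form)
  .model_from_table(read_param_table(
    .fixture_path("reference_params_ga39.txt")), covariate_form)
}
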