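#' @keywords internal
".scr_param_names" <- c("qmax_uf", "k", "pna_p", "ksyn_gfr0",
                        "gfrss_gfr0", "pna50", "gamma")

#' Structural kinetic parameters for one subject
#'
#' Bundles the identifiable parameters of the creatinine turnover model.
#' Because absolute GFR, creatinine synthesis rate and urinary flow are not
#' identifiable from serum creatinine alone, everything is stored as a ratio:
#' the back-flow peak relative to urinary flow (`qmax_uf`), the synthesis
#' rate relative to GFR at birth (`ksyn_gfr0`, mg/dL) and the GFR plateau
#' relative to GFR at birth (`gfrss_gfr0`).
#'
#' @param qmax_uf Peak tubular back-flow ratio Qmax/UF (dimensionless).
#' @param k Time-scale factor of the back-flow Gaussian (1/day); `1/k` is the
#'   standard deviation of the back-flow peak.
#' @param pna_p Postnatal age at the back-flow peak (day).
#' @param ksyn_gfr0 Creatinine synthesis rate over GFR at birth (mg/dL).
#' @param gfrss_gfr0 GFR plateau over GFR at birth (dimensionless).
#' @param pna50 Postnatal age at which half of the GFR plateau gain is
#'   reached (day).
#' @param gamma Hill coefficient of the GFR maturation curve.
#' @return A named numeric vector of class `"scr_params"`.
#' @examples
#' p <- scr_params(qmax_uf = 0.575, k = 0.709, pna_p = 2.42,
#'                 ksyn_gfr0 = 0.654, gfrss_gfr0 = 1.78,
#'                 pna50 = 2.31, gamma = 5.26)
#' scr_value(c(1, 3, 10), p)
#' @export
scr_params <- function(qmax_uf, k, pna_p, ksyn_gfr0, gfrss_gfr0, pna50,
                       gamma) {
  p <- c(qmax_uf = qmax_uf, k = k, pna_p = pna_p, ksyn_gfr0 = ksyn_gfr0,
         gfrss_gfr0 = gfrss_gfr0, pna50 = pna50, gamma = gamma)
  if (any(!is.finite(p)))
    stop("all structural parameters must be finite", call. = FALSE)
  if (any(p <= 0))
    stop("all structural parameters must be strictly positive", call. = FALSE)
  class(p) <- "scr_params"
  p
}

#' Tubular back-flow of creatinine relative to urinary flow
#'
#' Truncated-Gaussian back-flow profile Q(PNA)/UF. The curve peaks at
#' `pna_p` with height `qmax_uf` and decays with Gaussian width `1/k`;
#' truncation means the function is only defined for postnatal ages at or
#' after birth (no renormalisation is applied).
#'
#' @param pna Postnatal age in days (vectorised); must be non-negative.
#' @param qmax_uf Peak back-flow ratio Qmax/UF.
#' @param k Time-scale factor (1/day).
#' @param pna_p Postnatal age of the peak (day).
#' @return Q(PNA)/UF, same length as `pna`.
#' @export
backflow_q <- function(pna, qmax_uf, k, pna_p) {
  if (any(pna < 0)) stop("pna must be >= 0 (back-flow truncated at birth)",
                         call. = FALSE)
  if (qmax_uf < 0 || k <= 0 || pna_p <= 0)
    stop("back-flow parameters must be positive", call. = FALSE)
  qmax_uf * exp(-(k^2 / 2) * (pna - pna_p)^2)
}

#' GFR maturation relative to its value at birth
#'
#' Sigmoidal-Emax maturation of glomerular filtration rate:
#' GFR(PNA)/GFR0 = 1 + (GFRss/GFR0 - 1) * PNA^gamma / (PNA50^gamma +
#' PNA^gamma). At birth the ratio is exactly 1; for a plateau ratio above 1
#' it rises monotonically to `gfrss_gfr0`.
#'
#' @param pna Postnatal age in days (vectorised); must be non-negative.
#' @param gfrss_gfr0 Plateau ratio GFRss/GFR0.
#' @param pna50 Age at which half of the plateau gain is reached (day).
#' @param gamma Hill coefficient.
#' @return GFR(PNA)/GFR0, same length as `pna`.
#' @export
gfr_ratio <- function(pna, gfrss_gfr0, pna50, gamma) {
  if (any(pna < 0)) stop("pna must be >= 0", call. = FALSE)
  if (gfrss_gfr0 <= 0 || pna50 <= 0 || gamma <= 0)
    stop("GFR maturation parameters must be positive", call. = FALSE)
  # stable Hill fraction: 1 / (1 + (pna50/pna)^gamma), exactly 0 at pna = 0
  frac <- ifelse(pna > 0, 1 / (1 + (pna50 / pna)^gamma), 0)
  1 + (gfrss_gfr0 - 1) * frac
}

#' Serum creatinine concentration predicted by the structural model
#'
#' sCr(PNA) = (1 + Q(PNA)/UF) * (ksyn/GFR0) / (GFR(PNA)/GFR0). Creatinine is
#' produced at a constant rate from muscle, cleared by glomerular filtration
#' and transiently returned to plasma by tubular back-flow during the first
#' postnatal days.
#'
#' @param pna Postnatal age in days (vectorised); must be non-negative.
#' @param p An [scr_params] vector (or named numeric with the same fields).
#' @return Serum creatinine in mg/dL, same length as `pna`.
#' @export
scr_value <- function(pna, p) {
  q <- backflow_q(pna, p[["qmax_uf"]], p[["k"]], p[["pna_p"]])
  g <- gfr_ratio(pna, p[["gfrss_gfr0"]], p[["pna50"]], p[["gamma"]])
  (1 + q) * p[["ksyn_gfr0"]] / g
}

#' Linear continuous-covariate adjustment of a typical value
#'
#' Adjusts a typical parameter value for a continuous covariate (here
#' gestational age) around a reference value. The multiplicative form is
#' `theta * (1 + slope * (cov - center))`; the additive form is
#' `theta + slope * (cov - center)`.
#'
#' @param theta Typical value at the covariate reference.
#' @param slope Covariate coefficient (per covariate unit).
#' @param cov_value Observed covariate value (vectorised).
#' @param center Covariate reference value (default 34.2 weeks, the study
#'   gestational-age reference).
#' @param form `"multiplicative"` (default) or `"additive"`.
#' @return Adjusted typical value(s); an error if any result is non-positive.
#' @export
apply_continuous_covariate <- function(theta, slope, cov_value,
                                       center = 34.2,
                                       form = c("multiplicative",
                                                "additive")) {
  form <- match.arg(form)
  out <- if (form == "multiplicative")
    theta * (1 + slope * (cov_value - center))
  else
    theta + slope * (cov_value - center)
  if (any(out <= 0))
    stop("covariate adjustment produced a non-positive typical value",
         call. = FALSE)
  out
}

#' Per-subject covariate vector
#'
#' @param ga Gestational age in weeks, in (20, 45).
#' @param bwt Birth weight in grams (> 0).
#' @param aki Acute kidney injury flag (0/1).
#' @param death Neonatal death (day 1-28) flag (0/1).
#' @return A one-row data frame of class `"scr_covariates"`.
#' @export
scr_covariates <- function(ga, bwt = 3340, aki = 0, death = 0) {
  stopifnot(length(ga) == length(bwt) || length(bwt) == 1,
            all(aki %in% c(0, 1)), all(death %in% c(0, 1)))
  if (any(ga <= 20 | ga >= 45))
    stop("ga must lie in (20, 45) weeks", call. = FALSE)
  if (any(bwt <= 0)) stop("bwt must be positive", call. = FALSE)
  out <- data.frame(ga = ga, bwt = bwt, aki = as.integer(aki),
                    death = as.integer(death))
  class(out) <- c("scr_covariates", "data.frame")
  out
}

# level key for dichotomous-covariate splits, e.g. "0:1" for aki=0, death=1
.level_key <- function(values) paste(as.integer(values), collapse = ":")

#' Continuous (linear) covariate effect specification
#'
#' @param target Name of the structural parameter the effect acts on.
#' @param covariate Covariate column name (e.g. `"ga"`).
#' @param slope Linear coefficient.
#' @param center Covariate reference value.
#' @param form `"multiplicative"` or `"additive"` (see
#'   [apply_continuous_covariate]).
#' @return An object of class `"scr_effect"` with kind `"linear"`.
#' @export
effect_linear <- function(target, covariate = "ga", slope, center = 34.2,
                          form = c("multiplicative", "additive")) {
  form <- match.arg(form)
  stopifnot(target %in% .scr_param_names, is.numeric(slope))
  structure(list(kind = "linear", target = target, covariate = covariate,
                 slope = slope, center = center, form = form),
            class = "scr_effect")
}

#' Dichotomous-covariate split of a typical value
#'
#' Replaces a parameter's typical value by a level-specific value indexed by
#' one or more 0/1 covariates: theta_P = theta_{P,COV=1} * COV +
#' theta_{P,COV=0} * (1 - COV), extended to the full cross for several
#' covariates. Level names are colon-joined flag values in covariate order
#' (e.g. `"0:1"` for the first covariate absent and the second present).
#'
#' @param target Name of the structural parameter the split acts on.
#' @param covariates Character vector of 0/1 covariate names.
#' @param levels Named numeric vector of typical values, one per level key;
#'   must cover every combination (2^length(covariates) entries).
#' @return An object of class `"scr_effect"` with kind `"split"`.
#' @export
effect_split <- function(target, covariates, levels) {
  stopifnot(target %in% .scr_param_names, length(covariates) >= 1)
  need <- apply(expand.grid(rep(list(0:1), length(covariates))), 1,
                paste, collapse = ":")
  if (!all(need %in% names(levels)))
    stop("effect_split: levels must cover every combination: ",
         paste(setdiff(need, names(levels)), collapse = ", "),
         call. = FALSE)
  if (any(levels <= 0))
    stop("effect_split: level typical values must be positive", call. = FALSE)
  structure(list(kind = "split", target = target, covariates = covariates,
                 levels = levels), class = "scr_effect")
}

#' Look up the level-specific typical value of a dichotomous split
#'
#' @param spec An [effect_split] specification.
#' @param cov A covariate row (list, data frame row, or named vector) holding
#'   the split's covariates as 0/1 flags.
#' @return The typical value for the observed level combination.
#' @export
apply_categorical_covariate <- function(spec, cov) {
  stopifnot(inherits(spec, "scr_effect"), spec$kind == "split")
  vals <- vapply(spec$covariates, function(nm) {
    v <- cov[[nm]]
    if (is.null(v) || is.na(v)) stop("covariate '", nm, "' missing",
                                     call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  key <- .level_key(vals)
  if (!key %in% names(spec$levels))
    stop("no level value configured for combination ", key, call. = FALSE)
  unname(spec$levels[[key]])
}
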