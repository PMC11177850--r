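#' Convert Jaffe-assay serum creatinine to IDMS-traceable equivalents
#'
#' Linear recalibration `sCr_IDMS = 1.003 * sCr_Jaffe + 0.057` (mg/dL),
#' harmonising colorimetric Jaffe measurements with isotope-dilution mass
#' spectrometry traceable enzymatic values.
#'
#' @param scr_jaffe Jaffe-assay sCr in mg/dL (vectorised, >= 0).
#' @return IDMS-equivalent sCr in mg/dL.
#' @export
jaffe_to_idms <- function(scr_jaffe) {
  if (any(scr_jaffe < 0)) stop("scr_jaffe must be >= 0", call. = FALSE)
  1.003 * scr_jaffe + 0.057
}

#' Display serum creatinine in SI units
#'
#' All package computation is in mg/dL; this converts for display only
#' (1 mg/dL = 88.4 umol/L).
#'
#' @param scr_mgdl sCr in mg/dL.
#' @return sCr in umol/L.
#' @export
scr_to_umol <- function(scr_mgdl) 88.4 * scr_mgdl

.dataset_columns <- c("ID", "TIME", "DV", "MDV", "ASSAY", "GA", "BWT",
                      "AKI", "DEATH")
.assay_levels <- c("jaffe", "idms", "unknown")

#' Construct and validate a longitudinal sCr dataset
#'
#' The dataset is a NONMEM-style flat table: one row per observation with
#' the subject's covariates repeated. Columns: `ID`, `TIME` (postnatal age,
#' days), `DV` (sCr, mg/dL), `MDV` (missing-DV flag), `ASSAY`
#' (`"jaffe"`, `"idms"` or `"unknown"`), `GA` (weeks), `BWT` (g), `AKI`,
#' `DEATH` (0/1).
#'
#' @param df A data frame with the columns above (`MDV` optional, default
#'   0).
#' @param provenance Optional data frame of filter-chain counts (stage,
#'   n_subjects, n_obs); maintained by [apply_inclusion_filters].
#' @return The validated data frame with class `"scr_data"`.
#' @export
scr_dataset <- function(df, provenance = NULL) {
  df <- as.data.frame(df)
  if (is.null(df$MDV)) df$MDV <- 0L
  missing_cols <- setdiff(.dataset_columns, names(df))
  if (length(missing_cols))
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[.dataset_columns]
  if (!is.numeric(df$DV)) stop("DV must be numeric", call. = FALSE)
  if (!is.numeric(df$TIME)) stop("TIME must be numeric", call. = FALSE)
  if (nrow(df)) {
    if (any(df$TIME <= 0 | df$TIME > 10))
      stop("TIME must lie in (0, 10] days", call. = FALSE)
    if (any(df$DV <= 0 & df$MDV == 0))
      stop("observed DV must be positive", call. = FALSE)
    if (!all(df$ASSAY %in% .assay_levels))
      stop("ASSAY must be one of: ", paste(.assay_levels, collapse = ", "),
           call. = FALSE)
    bad <- tapply(df$TIME, df$ID, function(t) any(diff(t) <= 0))
    if (any(unlist(bad)))
      stop("TIME must be strictly increasing within subject (ID ",
           paste(names(bad)[unlist(bad)][1]), ")", call. = FALSE)
    percov <- unique(df[c("ID", "GA", "BWT", "AKI", "DEATH")])
    if (anyDuplicated(percov$ID))
      stop("covariates must be constant within subject", call. = FALSE)
  }
  if (is.null(provenance))
    provenance <- data.frame(stage = "input",
                             n_subjects = length(unique(df$ID)),
                             n_obs = nrow(df))
  structure(df, class = c("scr_data", "data.frame"),
            provenance = provenance)
}

#' Drop the dataset class and bookkeeping attributes
#'
#' @param x An [scr_dataset].
#' @param row.names,optional,... Conventional arguments (unused).
#' @return A plain data frame without the `provenance`/`eta` attributes.
#' @export
as.data.frame.scr_data <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  class(x) <- "data.frame"
  attr(x, "provenance") <- NULL
  attr(x, "eta") <- NULL
  rownames(x) <- NULL
  x
}

#' @export
print.scr_data <- function(x, ...) {
  cat(sprintf("sCr dataset: %d subjects, %d observations\n",
              length(unique(x$ID)), nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nrow(prov) > 1) {
    cat("Provenance:\n")
    print(prov, row.names = FALSE)
  }
  NextMethod()
}

#' Generate a synthetic cohort of neonatal covariates
#'
#' Emulates the covariate margins of the cooled-neonate study cohort:
#' gestational age as a discretised truncated normal on 34-42 weeks with
#' median 39, birth weight conditionally normal given gestational age, and
#' independent Bernoulli AKI and death flags with the study prevalences.
#'
#' @param n Number of subjects.
#' @param config List overriding the defaults: `ga_mean` (39), `ga_sd` (2),
#'   `ga_range` (c(34, 42)), `aki_prev` (79/975), `death_prev` (148/975),
#'   `bwt_mean` (3340 g at GA 39), `bwt_slope` (170 g/week), `bwt_sd`
#'   (450 g), `bwt_min` (1200 g).
#' @param seed Optional integer seed (local to this call).
#' @return A data frame (class `"scr_covariates"`) with columns `ga`,
#'   `bwt`, `aki`, `death`.
#' @export
generate_cohort <- function(n, config = list(), seed = NULL) {
  stopifnot(n >= 0)
  cfg <- utils::modifyList(list(
    ga_mean = 39, ga_sd = 2, ga_range = c(34, 42),
    aki_prev = 79 / 975, death_prev = 148 / 975,
    bwt_mean = 3340, bwt_slope = 170, bwt_sd = 450, bwt_min = 1200),
    config)
  if (cfg$aki_prev < 0 || cfg$aki_prev > 1 ||
      cfg$death_prev < 0 || cfg$death_prev > 1)
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  if (n == 0)
    return(scr_covariates(ga = numeric(0), bwt = numeric(0),
                          aki = integer(0), death = integer(0)))
  # truncated normal by inverse-CDF, then rounded to whole weeks
  lo <- stats::pnorm(cfg$ga_range[1] - 0.5, cfg$ga_mean, cfg$ga_sd)
  hi <- stats::pnorm(cfg$ga_range[2] + 0.5, cfg$ga_mean, cfg$ga_sd)
  ga <- round(stats::qnorm(stats::runif(n, lo, hi), cfg$ga_mean, cfg$ga_sd))
  ga <- pmin(pmax(ga, cfg$ga_range[1]), cfg$ga_range[2])
  bwt <- stats::rnorm(n, cfg$bwt_mean + cfg$bwt_slope * (ga - 39),
                      cfg$bwt_sd)
  bwt <- pmax(bwt, cfg$bwt_min)
  aki <- stats::rbinom(n, 1, cfg$aki_prev)
  death <- stats::rbinom(n, 1, cfg$death_prev)
  scr_covariates(ga = ga, bwt = round(bwt), aki = aki, death = death)
}

#' Generate noisy longitudinal sCr observations for a cohort
#'
#' For each subject: draws individual structural parameters from the
#' population model ([sample_individual]), a clinically plausible sampling
#' schedule (observation count and early-skewed times), and observations
#' `DV = sCr(t) * exp(eps)`, `eps ~ N(0, sigma2)` with `sigma2` taken from
#' the model. Subjects measured by the Jaffe assay have their values stored
#' on the Jaffe scale (the inverse of [jaffe_to_idms]) so the
#' data-preparation chain is exercised end to end.
#'
#' @param cohort Covariate data frame from [generate_cohort].
#' @param model An [scr_model] used for both parameters and residual noise.
#' @param config List overriding schedule defaults: `n_obs_min` (1),
#'   `n_obs_max` (10), `n_obs_mean` (4.8), `time_meanlog` (log 3),
#'   `time_sdlog` (0.55), `assay_probs` (jaffe/idms/unknown mix,
#'   c(0.495, 0.495, 0.01)).
#' @param seed Optional integer seed (local to this call).
#' @return An [scr_dataset]. The attribute `"eta"` carries the simulated
#'   per-subject random effects (for simulation studies).
#' @export
generate_observations <- function(cohort, model, config = list(),
                                  seed = NULL) {
  stopifnot(inherits(model, "scr_model"))
  cohort <- as.data.frame(cohort)
  cfg <- utils::modifyList(list(
    n_obs_min = 1, n_obs_max = 10, n_obs_mean = 4.8,
    time_meanlog = log(3), time_sdlog = 0.55,
    assay_probs = c(jaffe = 0.495, idms = 0.495, unknown = 0.01)),
    config)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- nrow(cohort)
  if (n == 0)
    return(scr_dataset(data.frame(ID = integer(0), TIME = numeric(0),
                                  DV = numeric(0), MDV = integer(0),
                                  ASSAY = character(0), GA = numeric(0),
                                  BWT = numeric(0), AKI = integer(0),
                                  DEATH = integer(0))))
  pars <- sample_individual(model, cohort, n = n)
  if (is.null(dim(pars)))
    pars <- matrix(pars, nrow = 1, dimnames = list(NULL, names(pars)))
  typ <- resolve_typicals(model, cohort)
  eta <- log(pars / typ)
  span <- cfg$n_obs_max - cfg$n_obs_min
  nobs <- if (span > 0)
    cfg$n_obs_min + stats::rbinom(n, span,
                                  (cfg$n_obs_mean - cfg$n_obs_min) / span)
  else rep(cfg$n_obs_min, n)
  assay <- sample(names(cfg$assay_probs), n, replace = TRUE,
                  prob = cfg$assay_probs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- nobs[i]
    t <- numeric(0)
    while (length(t) < m) {
      draw <- stats::rlnorm(4 * m, cfg$time_meanlog, cfg$time_sdlog)
      t <- c(t, draw[draw > 0.01 & draw <= 10])
    }
    t <- sort(unique(round(t[seq_len(m)], 2)))
    pred <- scr_value(t, structure(pars[i, ], class = "scr_params"))
    dv <- pred * exp(stats::rnorm(length(t), 0, sqrt(model$sigma2)))
    if (assay[i] == "jaffe") dv <- pmax((dv - 0.057) / 1.003, 1e-6)
    rows[[i]] <- data.frame(ID = i, TIME = t, DV = dv, MDV = 0L,
                            ASSAY = assay[i], GA = cohort$ga[i],
                            BWT = cohort$bwt[i], AKI = cohort$aki[i],
                            DEATH = cohort$death[i])
  }
  out <- scr_dataset(do.call(rbind, rows))
  attr(out, "eta") <- eta
  out
}

#' Apply the study's data-preparation rules
#'
#' In order: (1) observations from an unidentified assay are excluded;
#' (2) Jaffe values are converted to IDMS-traceable equivalents
#' ([jaffe_to_idms]); (3) subjects with any sCr above 2 mg/dL are excluded
#' (or, with `scr_filter = "observation"`, only the offending observations);
#' (4) subjects with gestational age above 42 weeks are excluded. The
#' filter-chain subject/observation counts are recorded in the
#' `"provenance"` attribute.
#'
#' @param ds An [scr_dataset].
#' @param scr_filter `"subject"` (default) or `"observation"`: scope of the
#'   2 mg/dL exclusion.
#' @param scr_max sCr inclusion threshold in mg/dL (default 2).
#' @param ga_max Gestational-age inclusion threshold in weeks (default 42).
#' @return The filtered [scr_dataset] with updated provenance.
#' @export
apply_inclusion_filters <- function(ds, scr_filter = c("subject",
                                                       "observation"),
                                    scr_max = 2, ga_max = 42) {
  scr_filter <- match.arg(scr_filter)
  stopifnot(inherits(ds, "scr_data"))
  prov <- attr(ds, "provenance")
  note <- function(df, stage) {
    prov <<- rbind(prov, data.frame(stage = stage,
                                    n_subjects = length(unique(df$ID)),
                                    n_obs = nrow(df)))
    df
  }
  df <- as.data.frame(ds)
  df <- note(df[df$ASSAY != "unknown", , drop = FALSE], "drop_unknown_assay")
  jaffe <- df$ASSAY == "jaffe"
  if (any(jaffe)) {
    df$DV[jaffe] <- jaffe_to_idms(df$DV[jaffe])
    df$ASSAY[jaffe] <- "idms"
  }
  if (scr_filter == "subject") {
    bad_ids <- unique(df$ID[df$DV > scr_max & df$MDV == 0])
    df <- df[!df$ID %in% bad_ids, , drop = FALSE]
  } else {
    df <- df[!(df$DV > scr_max & df$MDV == 0), , drop = FALSE]
  }
  df <- note(df, paste0("scr_le_", scr_max))
  df <- note(df[df$GA <= ga_max, , drop = FALSE], paste0("ga_le_", ga_max))
  scr_dataset(df, provenance = prov)
}

#' Read / write the flat NONMEM-style sCr dataset
#'
#' Comma-separated with a mandatory header, decimal points, no thousands
#' separators; columns as documented in [scr_dataset]. `read_dataset`
#' validates on load and reports offending rows.
#'
#' @param path File path.
#' @return `read_dataset`: an [scr_dataset]. `write_dataset`: `path`,
#'   invisibly.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(.dataset_columns, "MDV"), names(df))
  if (length(missing_cols))
    stop("dataset file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("TIME", "DV", "GA", "BWT", "AKI", "DEATH")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]) == is.na(v)))
      stop("non-numeric ", col, " at line(s) ",
           paste(which(is.na(v) & !is.na(df[[col]]))[1] + 1L, collapse = ", "),
           " of ", path, call. = FALSE)
    df[[col]] <- v
  }
  scr_dataset(df)
}

#' @rdname read_dataset
#' @param ds An [scr_dataset] to write.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "scr_data"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
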