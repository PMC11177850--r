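# Shared test fixtures and independent oracles.

# final-model typical values (AKI=0, DEATH=0, GA at the 34.2-week reference)
th_typ <- function() {
  scr_params(qmax_uf = 0.575, k = 0.709, pna_p = 2.42, ksyn_gfr0 = 0.631,
             gfrss_gfr0 = 1.74, pna50 = 1.94, gamma = 4.46)
}

# plain model without covariate effects; omega2/sigma2 configurable
flat_model <- function(omega2 = numeric(0), sigma2 = 0.0227,
                       theta = th_typ(), fixed = character(0)) {
  scr_model(theta = unclass(theta), omega2 = omega2, sigma2 = sigma2,
            fixed = fixed)
}

# idms-only observation config (no assay conversion in the way)
idms_only <- list(assay_probs = c(jaffe = 0, idms = 1, unknown = 0))

# independent closed-form -2 log marginal likelihood for the log-linear
# submodel (random effect on ksyn_gfr0 only): log DV ~ N(log scr_typ,
# sigma2*I + omega2*11'), evaluated with dense matrix algebra
closedform_loglin_ofv <- function(model, data) {
  df <- as.data.frame(data)
  df <- df[df$MDV == 0, ]
  total <- 0
  for (id in unique(df$ID)) {
    rows <- df[df$ID == id, ]
    cov <- data.frame(ga = rows$GA[1], aki = rows$AKI[1],
                      death = rows$DEATH[1])
    typ <- resolve_typicals(model, cov)[1, ]
    m0 <- log(scr_value(rows$TIME, structure(typ, class = "scr_params")))
    n <- nrow(rows)
    V <- diag(model$sigma2, n) + model$omega2[["ksyn_gfr0"]]
    r <- log(rows$DV) - m0
    total <- total + n * log(2 * pi) + determinant(V)$modulus +
      drop(r %*% solve(V, r))
  }
  as.numeric(total)
}

# small deterministic dataset builder (no RNG): fixed times, DVs from the
# structural model times given multiplicative deviations
tiny_dataset <- function(model, cov_df, times_list, dev_list) {
  rows <- lapply(seq_len(nrow(cov_df)), function(i) {
    t <- times_list[[i]]
    typ <- resolve_typicals(model, cov_df[i, , drop = FALSE])[1, ]
    dv <- scr_value(t, structure(typ, class = "scr_params")) * dev_list[[i]]
    data.frame(ID = i, TIME = t, DV = dv, MDV = 0L, ASSAY = "idms",
               GA = cov_df$ga[i], BWT = 3300, AKI = cov_df$aki[i],
               DEATH = cov_df$death[i])
  })
  scr_dataset(do.call(rbind, rows))
}
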