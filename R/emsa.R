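# -- equilibrium RNA-protein binding (EMSA) --------------------------------

#' Equilibrium binding model with independent identical sites
#'
#' One RNA molecule carries `n_sites` independent, identical protein
#' binding sites of dissociation constant `kd`; multiple occupied sites on
#' one RNA account for the multiple band shifts seen in gels. With
#' `depletion = TRUE` the free protein concentration is obtained from exact
#' mass balance; otherwise free protein is approximated by total protein.
#'
#' @param kd Dissociation constant in nM (> 0).
#' @param n_sites Integer number of sites per RNA (>= 1).
#' @param depletion Use exact free-ligand accounting (default TRUE).
#' @return A `binding_model`.
#' @export
binding_model <- function(kd, n_sites = 1L, depletion = TRUE) {
  if (!is.numeric(kd) || kd <= 0) stop_param("kd must be > 0")
  if (n_sites < 1) stop_param("n_sites must be >= 1")
  structure(list(kd = kd, n_sites = as.integer(n_sites),
                 depletion = isTRUE(depletion)), class = "binding_model")
}

# per-site occupancy theta at total protein P and RNA R (vectorized in P).
# With depletion, P_free solves P_free = P - n*R*theta with
# theta = P_free/(kd + P_free); the positive root of
# P_free^2 + (kd + n*R - P) P_free - kd P = 0 is the unique one in [0, P].
site_occupancy <- function(model, P, R) {
  kd <- model$kd
  if (model$depletion) {
    b <- kd + model$n_sites * R - P
    pf <- (-b + sqrt(b^2 + 4 * kd * P)) / 2
    pf / (kd + pf)
  } else {
    P / (kd + P)
  }
}

#' Fraction of RNA bound and the occupancy (shift-class) distribution
#'
#' Fraction bound is defined as the probability that an RNA has at least
#' one occupied site, `f = 1 - (1 - theta)^n_sites`, matching gel-shift
#' quantification of any shifted species; the shift class k (number of
#' proteins on one RNA) is Binomial(`n_sites`, theta).
#'
#' @param model A [binding_model()].
#' @param P Total protein concentration(s), nM.
#' @param R Total RNA concentration, nM.
#' @return If `P` is scalar, a list with `fraction_bound`, `theta` and
#'   `occupancy` (probabilities of classes 0..n_sites); if vectorized, the
#'   numeric vector of fraction bound.
#' @examples
#' fraction_bound(binding_model(65, depletion = FALSE), P = 65, R = 0)
#' @export
fraction_bound <- function(model, P, R = 10.4) {
  stopifnot(inherits(model, "binding_model"), all(P >= 0), R >= 0)
  theta <- site_occupancy(model, P, R)
  f <- 1 - (1 - theta)^model$n_sites
  if (length(P) == 1L) {
    list(fraction_bound = f, theta = theta,
         occupancy = stats::setNames(
           stats::dbinom(0:model$n_sites, model$n_sites, theta),
           paste0("class", 0:model$n_sites)))
  } else f
}

#' The protein-concentration ladder of the reference titration
#'
#' @return Numeric vector: 0, 10.4, 26.3, 52.5, 78.3, 104, 158, 210, 420,
#'   630 nM.
#' @export
emsa_ladder <- function() {
  c(0, 10.4, 26.3, 52.5, 78.3, 104, 158, 210, 420, 630)
}

#' Simulate an EMSA titration series
#'
#' Evaluates the binding law over a protein ladder and adds Gaussian noise
#' truncated to `[0, 1]`; `noise_sd = 0` returns exact model values.
#'
#' @param model A [binding_model()].
#' @param ladder Protein concentrations, nM (default [emsa_ladder()]).
#' @param rna_conc Total RNA concentration, nM (default 10.4).
#' @param noise_sd Gaussian noise standard deviation on fraction bound.
#' @param seed Optional seed for the noise.
#' @return A `titration_series`: data frame (`protein_nM`,
#'   `fraction_bound`) with attribute `rna_conc`.
#' @export
simulate_titration <- function(model, ladder = emsa_ladder(),
                               rna_conc = 10.4, noise_sd = 0,
                               seed = NULL) {
  stopifnot(inherits(model, "binding_model"), all(ladder >= 0),
            noise_sd >= 0)
  f <- vapply(ladder, function(p)
    fraction_bound(model, p, rna_conc)$fraction_bound, numeric(1))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- pmin(1, pmax(0, f + stats::rnorm(length(f), sd = noise_sd)))
  }
  structure(data.frame(protein_nM = ladder, fraction_bound = f),
            class = c("titration_series", "data.frame"),
            rna_conc = rna_conc)
}

#' Read a titration series from TSV
#' @param path TSV with columns `protein_nM` and `fraction_bound`.
#' @param rna_conc RNA concentration of the series, nM.
#' @return A `titration_series`.
#' @export
read_titration_tsv <- function(path, rna_conc = 10.4) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("protein_nM", "fraction_bound") %in% names(df)))
  structure(df[, c("protein_nM", "fraction_bound")],
            class = c("titration_series", "data.frame"),
            rna_conc = rna_conc)
}

#' Estimate the dissociation constant from a titration series
#'
#' Least-squares fit of the independent-sites binding law, minimized over
#' `log10(Kd)` on `[1e-2, 1e5]` nM (positivity plus good conditioning over
#' the ladder scale) via a coarse grid followed by 1-D optimization. A
#' series with no detectable signal (maximum observed fraction bound below
#' `min_signal`) yields an explicit no-binding result carrying a Kd lower
#' bound (the largest protein concentration probed) instead of a numeric
#' estimate. Optional bootstrap resampling of titration points gives a
#' percentile confidence interval.
#'
#' @param series A `titration_series` (or data frame with `protein_nM`,
#'   `fraction_bound`).
#' @param n_sites,depletion Passed to [binding_model()].
#' @param rna_conc RNA concentration, nM; defaults to the series attribute.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap.
#' @param min_signal No-binding threshold on max fraction bound.
#' @return A `kd_fit` with elements `kd` (NA for no-binding), `status`
#'   (`"ok"`, `"no-binding"`), `kd_lower_bound`, `rss`, `n_sites`,
#'   `depletion`, `rna_conc`, `data`, and `ci` when bootstrapped.
#' @examples
#' s <- simulate_titration(binding_model(65))
#' fit_kd(s)
#' @export
fit_kd <- function(series, n_sites = 1L, depletion = TRUE,
                   rna_conc = NULL, bootstrap = 0L, seed = NULL,
                   min_signal = 0.05) {
  P <- series$protein_nM
  f <- series$fraction_bound
  if (is.null(rna_conc)) rna_conc <- attr(series, "rna_conc") %||% 10.4
  pos <- P > 0
  if (length(unique(P[pos])) < 3L)
    stop_param("need at least 3 distinct positive protein concentrations")

  out <- list(n_sites = as.integer(n_sites), depletion = isTRUE(depletion),
              rna_conc = rna_conc,
              data = data.frame(protein_nM = P, fraction_bound = f))
  class(out) <- "kd_fit"

  if (max(f) < min_signal) {
    out$status <- "no-binding"
    out$kd <- NA_real_
    out$kd_lower_bound <- max(P)
    out$rss <- sum(f^2)
    return(out)
  }

  fit1 <- function(Pv, fv) {
    obj <- function(l) {
      m <- binding_model(10^l, n_sites, depletion)
      sum((site_to_f(m, Pv, rna_conc) - fv)^2)
    }
    grid <- seq(-2, 5, by = 0.25)
    l0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
    opt <- stats::optimize(obj, c(max(-2, l0 - 0.5), min(5, l0 + 0.5)),
                           tol = 1e-10)
    list(kd = 10^opt$minimum, rss = opt$objective)
  }
  best <- fit1(P, f)
  out$status <- "ok"
  out$kd <- best$kd
  out$rss <- best$rss
  out$kd_lower_bound <- NA_real_

  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(P)
    reps <- vapply(seq_len(bootstrap), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(P[idx][P[idx] > 0])) < 3L) return(NA_real_)
      fit1(P[idx], f[idx])$kd
    }, numeric(1))
    out$bootstrap <- reps
    out$ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                              names = TRUE)
  }
  out
}

# model fraction bound over a vector of total protein concentrations
site_to_f <- function(model, P, R) {
  theta <- site_occupancy(model, P, R)
  1 - (1 - theta)^model$n_sites
}

#' @export
print.kd_fit <- function(x, ...) {
  if (x$status == "no-binding") {
    cat(sprintf("kd_fit: no detectable binding (Kd > %g nM)\n",
                x$kd_lower_bound))
  } else {
    cat(sprintf("kd_fit: Kd = %.4g nM (n_sites = %d, depletion %s)\n",
                x$kd, x$n_sites, if (x$depletion) "on" else "off"))
    cat(sprintf("  residual sum of squares = %.3g over %d points\n",
                x$rss, nrow(x$data)))
    if (!is.null(x$ci))
      cat(sprintf("  bootstrap 95%% CI: [%.4g, %.4g] nM\n",
                  x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(kd = object$kd)

#' Predict fraction bound from a fitted binding model
#' @param object A `kd_fit`.
#' @param newdata Optional data frame with `protein_nM` (default: the
#'   fitted data).
#' @param ... Ignored.
#' @return Numeric vector of model fraction bound.
#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  if (object$status != "ok")
    stop_param("cannot predict from a no-binding result")
  P <- if (is.null(newdata)) object$data$protein_nM else newdata$protein_nM
  m <- binding_model(object$kd, object$n_sites, object$depletion)
  site_to_f(m, P, object$rna_conc)
}

#' Residuals of a Kd fit
#' @param object A `kd_fit`.
#' @param ... Ignored.
#' @return Observed minus fitted fraction bound.
#' @export
residuals.kd_fit <- function(object, ...) {
  object$data$fraction_bound - predict(object)
}

#' Plot a titration and its fitted binding curve
#' @param x A `kd_fit`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.kd_fit <- function(x, ...) {
  plot(x$data$protein_nM, x$data$fraction_bound, xlab = "protein (nM)",
       ylab = "fraction bound", ylim = c(0, 1), ...)
  if (x$status == "ok") {
    pp <- seq(0, max(x$data$protein_nM), length.out = 200)
    graphics::lines(pp, predict(x, data.frame(protein_nM = pp)))
    graphics::legend("bottomright", bty = "n",
                     legend = sprintf("Kd = %.3g nM", x$kd))
  }
  invisible(x)
}

#' Write a Kd fit report to TSV
#' @param x A `kd_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kd_tsv <- function(x, path) {
  df <- data.frame(status = x$status, kd_nM = x$kd,
                   kd_lower_bound_nM = x$kd_lower_bound, rss = x$rss,
                   n_sites = x$n_sites, depletion = x$depletion,
                   rna_conc_nM = x$rna_conc)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
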