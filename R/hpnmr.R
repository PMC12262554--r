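#' Quadratic pressure fits of chemical shifts
#'
#' Ordinary least squares of `shift_ppm` on `(1, p, p^2)` per
#' (residue, nucleus), the empirical model
#' `delta_i(p) = a_i + b_i p + c_i p^2` whose linear coefficient tracks
#' partial molar volume and whose quadratic coefficient tracks
#' compressibility changes. Standard errors come from the residual
#' variance; with exactly 3 distinct pressures the fit is exact and errors
#' are undefined (flagged).
#'
#' @param series data.frame with columns `residue`, `nucleus`
#'   (H / N / CO), `pressure_bar`, `shift_ppm`.
#' @return data.frame of class `quad_fit`: per (residue, nucleus) the
#'   coefficients `a`, `b`, `c`, their standard errors, `resid_sd`, `n`,
#'   and `exact` (TRUE when errors are undefined).
#' @export
fit_pressure_quadratic <- function(series) {
  need <- c("residue", "nucleus", "pressure_bar", "shift_ppm")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0L)
    stop("fit_pressure_quadratic: missing column(s): ",
         paste(miss, collapse = ", "))
  key <- interaction(series$residue, series$nucleus, drop = TRUE)
  out <- lapply(split(series, key), function(g) {
    p <- g$pressure_bar
    if (length(unique(p)) < 3L)
      stop("fit_pressure_quadratic: residue ", g$residue[1], " nucleus ",
           g$nucleus[1], " has < 3 distinct pressures (rank-deficient design)")
    X <- cbind(1, p, p^2)
    fit <- stats::lm.fit(X, g$shift_ppm)
    cf <- fit$coefficients
    n <- length(p)
    exact <- n == 3L
    if (exact) {
      se <- rep(NA_real_, 3); rsd <- NA_real_
    } else {
      rss <- sum(fit$residuals^2)
      s2 <- rss / (n - 3L)
      XtXi <- chol2inv(chol(crossprod(X)))
      se <- sqrt(diag(XtXi) * s2)
      rsd <- sqrt(s2)
    }
    data.frame(residue = g$residue[1], nucleus = g$nucleus[1],
               a = cf[1], b = cf[2], c = cf[3],
               se_a = se[1], se_b = se[2], se_c = se[3],
               resid_sd = rsd, n = n, exact = exact)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$nucleus, res$residue), ]
  class(res) <- c("quad_fit", "data.frame")
  res
}

#' Per-nucleus nonlinearity threshold flags
#'
#' Within each nucleus, flags residues whose absolute quadratic coefficient
#' exceeds `mean(|c|) + z * SD(|c|)` across residues. The default
#' `z = 1.645` captures roughly the top 10 percent under a normal model.
#'
#' @param fits a `quad_fit` from [fit_pressure_quadratic()].
#' @param z threshold multiplier.
#' @return data.frame: `residue`, `nucleus`, `abs_c`, `threshold`,
#'   `flagged`.
#' @export
nucleus_threshold <- function(fits, z = 1.645) {
  stopifnot(inherits(fits, "quad_fit"))
  out <- lapply(split(as.data.frame(fits), fits$nucleus), function(g) {
    ac <- abs(g$c)
    thr <- mean(ac) + z * stats::sd(ac)
    data.frame(residue = g$residue, nucleus = g$nucleus[1], abs_c = ac,
               threshold = thr, flagged = ac > thr)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composite nonlinearity score per peptide group
#'
#' Normalizes |c| within each nucleus (z-score across residues, or a
#' robust median/MAD variant) and sums the contributions of amide 1H and
#' 15N of residue i with the carbonyl 13C' of residue i-1 -- the three
#' nuclei one HNCO peak reports on. A missing nucleus contributes 0 and
#' clears the completeness flag.
#'
#' @param fits a `quad_fit`.
#' @param normalization "zscore" or "robust" (median/MAD).
#' @return data.frame of class `score_table`: `residue`, `z_H`, `z_N`,
#'   `z_CO_prev`, `composite`, `complete`.
#' @export
composite_score <- function(fits, normalization = c("zscore", "robust")) {
  stopifnot(inherits(fits, "quad_fit"))
  normalization <- match.arg(normalization)
  df <- as.data.frame(fits)
  norm_one <- function(g) {
    ac <- abs(g$c)
    if (length(ac) < 2L)
      stop("composite_score: need >= 2 residues per nucleus")
    if (normalization == "zscore") {
      s <- stats::sd(ac)
      zv <- if (s > 0) (ac - mean(ac)) / s else rep(0, length(ac))
    } else {
      s <- stats::mad(ac)
      zv <- if (s > 0) (ac - stats::median(ac)) / s else rep(0, length(ac))
    }
    stats::setNames(zv, g$residue)
  }
  zs <- lapply(split(df, df$nucleus), norm_one)
  residues <- sort(unique(df$residue))
  get_z <- function(nuc, res) {
    v <- zs[[nuc]]
    if (is.null(v)) return(rep(NA_real_, length(res)))
    unname(v[as.character(res)])
  }
  z_H <- get_z("H", residues)
  z_N <- get_z("N", residues)
  z_CO_prev <- get_z("CO", residues - 1L)
  comp <- ifelse(is.na(z_H), 0, z_H) + ifelse(is.na(z_N), 0, z_N) +
    ifelse(is.na(z_CO_prev), 0, z_CO_prev)
  res <- data.frame(residue = residues, z_H = z_H, z_N = z_N,
                    z_CO_prev = z_CO_prev, composite = comp,
                    complete = !(is.na(z_H) | is.na(z_N) | is.na(z_CO_prev)))
  class(res) <- c("score_table", "data.frame")
  res
}

#' Top pressure-sensitive residues by composite score
#'
#' Residues whose composite nonlinearity score exceeds
#' `mean + z * SD` over residues, sorted by decreasing score.
#'
#' @param scores a `score_table` from [composite_score()].
#' @param z threshold multiplier; `Inf` returns an empty set.
#' @return data.frame subset of `scores` with a `threshold` column.
#' @export
top_residues <- function(scores, z = 1.645) {
  stopifnot(inherits(scores, "score_table"))
  s <- stats::sd(scores$composite)
  thr <- mean(scores$composite) + z * s
  sel <- !is.na(thr) & scores$composite > thr
  if (is.na(thr)) sel <- rep(FALSE, nrow(scores))
  out <- as.data.frame(scores)[sel, , drop = FALSE]
  out <- out[order(-out$composite), , drop = FALSE]
  out$threshold <- rep(thr, nrow(out))
  rownames(out) <- NULL
  out
}
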