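#' Fit a Factor Analysis model by expectation-maximization
#'
#' Gaussian factor model `x ~ N(mean, Lambda Lambda' + diag(Psi))` fit on
#' the channel covariance by EM, initialized from the principal
#' eigenvectors.  The log-likelihood is non-decreasing across iterations;
#' if `max_iter` is reached before the relative improvement falls below
#' `tol` a warning is raised.  Zero-variance channels are dropped with a
#' message (their loadings are reported as zero).
#'
#' @param rates A [rate_array] or numeric matrix `T x N`.
#' @param d Latent dimensionality (default 10).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return An object of class `fa_model`: `mean` (length N), `loading`
#'   (`N x d`), `psi` (length N noise variances), `loglik` (per-iteration
#'   trace) and `converged`.
#' @export
fit_factor_analysis <- function(rates, d = 10L, max_iter = 500L,
                                tol = 1e-8) {
  X <- if (inherits(rates, "rate_array")) rates$rates else as.matrix(rates)
  n <- nrow(X)
  N <- ncol(X)
  if (n <= d) stop("need more time bins than latent dimensions")
  mu <- colMeans(X)
  v <- apply(X, 2L, stats::var) * (n - 1) / n
  dead <- which(v <= 0)
  keep <- setdiff(seq_len(N), dead)
  if (length(dead))
    message("dropping ", length(dead), " zero-variance channel(s) from FA fit")
  if (length(keep) <= d) stop("too few non-degenerate channels")
  Xc <- sweep(X[, keep, drop = FALSE], 2L, mu[keep])
  S <- crossprod(Xc) / n
  Nk <- length(keep)

  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 1e-12)
  Lam <- eg$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(d)] - mean(ev[-seq_len(d)]), 1e-6)), d)
  Psi <- pmax(diag(S) - rowSums(Lam^2), 1e-6)

  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    PiL <- Lam / Psi                       # Psi^-1 Lambda
    G <- solve(diag(d) + crossprod(Lam, PiL))   # (I + L' Psi^-1 L)^-1
    beta <- G %*% t(PiL)                   # d x N posterior map
    SbT <- S %*% t(beta)                   # N x d
    Ezz <- G + beta %*% SbT                # E[zz'] under the model
    Lam_new <- SbT %*% solve(Ezz)
    Psi_new <- pmax(diag(S) - rowSums(Lam_new * SbT), 1e-8)

    # log-likelihood of the current (pre-update) parameters via Woodbury:
    # tr(Sigma^-1 S) = tr(Psi^-1 S) - tr((Psi^-1 L) G (Psi^-1 L)' S)
    ldet <- sum(log(Psi)) - determinant(G, logarithm = TRUE)$modulus[1]
    trc <- sum(diag(S) / Psi) - sum((PiL %*% G) * (S %*% PiL))
    ll <- c(ll, -n / 2 * (Nk * log(2 * pi) + ldet + trc))
    Lam <- Lam_new
    Psi <- Psi_new
    if (it > 1L && abs(ll[it] - ll[it - 1L]) <
        tol * (abs(ll[it - 1L]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("factor analysis EM hit max_iter before converging")
  loading <- matrix(0, N, d)
  loading[keep, ] <- Lam
  psi <- rep(1e-6, N)
  psi[keep] <- Psi
  structure(list(mean = mu, loading = loading, psi = psi, d = d,
                 kept_channels = keep, loglik = ll, converged = converged),
            class = "fa_model")
}

#' Posterior-mean latent projection under a Factor Analysis model
#'
#' `z(t) = Lambda' (Lambda Lambda' + diag(Psi))^-1 (x(t) - mean)`, the
#' linear map extracting the most probable latent state per time bin.
#'
#' @param model A [fit_factor_analysis()] model.
#' @param rates A [rate_array] or matrix on the same channels.
#' @return Latent matrix `T x d`.
#' @export
fa_project <- function(model, rates) {
  X <- if (inherits(rates, "rate_array")) rates$rates else as.matrix(rates)
  k <- model$kept_channels
  Lam <- model$loading[k, , drop = FALSE]
  Psi <- model$psi[k]
  Xc <- sweep(X[, k, drop = FALSE], 2L, model$mean[k])
  # Woodbury: L'(LL' + Psi)^-1 = (I + L' Psi^-1 L)^-1 L' Psi^-1
  PiL <- Lam / Psi
  G <- solve(diag(model$d) + crossprod(Lam, PiL))
  Xc %*% PiL %*% t(G)
}

#' @export
latent_project <- function(model, rates) UseMethod("latent_project")

#' Project rates into a model's latent space
#'
#' Generic over latent models: [fit_factor_analysis()] models use the
#' posterior mean, [fit_adan_latent()] models use the trained encoder.
#'
#' @param model A fitted latent model.
#' @param rates A [rate_array] or matrix.
#' @return Latent matrix `T x d`.
#' @rdname latent_project
#' @export
latent_project.fa_model <- function(model, rates) fa_project(model, rates)

#' Orthogonal Procrustes alignment of two loading matrices
#'
#' Finds the orthogonal matrix (rotations and reflections allowed)
#' minimizing `||src O - ref||_F`, via the SVD of `src' ref`.
#'
#' @param src,ref Matrices of equal shape `N x d`.
#' @return An object of class `procrustes_map` with the orthogonal matrix
#'   `O` (`d x d`) and the Frobenius `residual` of the aligned difference.
#' @export
orthogonal_procrustes <- function(src, ref) {
  src <- as.matrix(src)
  ref <- as.matrix(ref)
  if (!all(dim(src) == dim(ref))) stop("src and ref must have equal shapes")
  M <- crossprod(src, ref)
  sv <- svd(M)
  if (min(sv$d) < 1e-10 * max(sv$d))
    warning("rank-deficient cross-product: Procrustes solution is degenerate")
  O <- sv$u %*% t(sv$v)
  structure(list(O = O, residual = norm(src %*% O - ref, "F")),
            class = "procrustes_map")
}

#' Procrustes Alignment of Factors (PAF)
#'
#' The linear baseline aligner: fits a Factor Analysis model to the day-k
#' rates, computes the orthogonal map carrying the day-k loadings onto the
#' day-0 loadings, and returns the day-k posterior latents expressed in
#' day-0 latent coordinates, ready to feed the frozen day-0 latent
#' decoder.  All recorded electrodes are used (no stability-based
#' electrode pruning), and the factor sign/order indeterminacy is absorbed
#' entirely by the Procrustes map.  Requires the day-k session to keep the
#' day-0 channel set.
#'
#' @param day0_model The day-0 [fit_factor_analysis()] model.
#' @param dayk_session A day-k [session_recording] (or matrix/[rate_array]
#'   of rates).
#' @param d Latent dimensionality (must match the day-0 model).
#' @return Latent matrix `T x d` in day-0 coordinates, with attribute
#'   `"aligner"` holding the fitted `paf_aligner` (day-k FA model plus the
#'   Procrustes map) for application to further data via [paf_project()].
#' @export
paf_align <- function(day0_model, dayk_session, d = day0_model$d) {
  rates <- if (inherits(dayk_session, "session_recording"))
    dayk_session$rates$rates else
      if (inherits(dayk_session, "rate_array")) dayk_session$rates else
        as.matrix(dayk_session)
  if (ncol(rates) != nrow(day0_model$loading))
    stop(sprintf(
      "channel-count mismatch: day-k has %d channels, day-0 model has %d (PAF requires an unchanged channel set)",
      ncol(rates), nrow(day0_model$loading)))
  dayk_model <- fit_factor_analysis(rates, d = d)
  pm <- orthogonal_procrustes(dayk_model$loading, day0_model$loading)
  aligner <- structure(list(day0_model = day0_model, dayk_model = dayk_model,
                            map = pm), class = "paf_aligner")
  out <- paf_project(aligner, rates)
  attr(out, "aligner") <- aligner
  out
}

#' Apply a fitted PAF aligner to new day-k rates
#'
#' @param aligner A `paf_aligner` (from the `"aligner"` attribute of
#'   [paf_align()]).
#' @param rates Day-k rates ([rate_array] or matrix).
#' @return Latent matrix in day-0 coordinates.
#' @export
paf_project <- function(aligner, rates) {
  z <- fa_project(aligner$dayk_model, rates)
  z %*% aligner$map$O
}
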