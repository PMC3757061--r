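#' Intrinsic-flexibility analytics on structure ensembles
#'
#' RMSD/RMSF profiles, essential dynamics (PCA of the positional
#' covariance), essential-subspace overlap and functional mode analysis.
#' All operate on the node representative atoms (Calpha for amino
#' acids) after optimal rigid-body superposition (Kabsch, via bio3d).
#'
#' @name ensemble-analytics
NULL

# node-representative (Calpha) coordinate block, frames x 3n
ca_xyz <- function(ens) {
  rep_atoms <- node_rep_atoms(ens)
  cols <- as.numeric(t(outer(rep_atoms - 1, 1:3, function(a, k) 3 * a + k)))
  ens$xyz[, cols, drop = FALSE]
}

# superpose every row of X (frames x 3n) onto the reference row vector,
# or onto the iteratively refined mean when ref is NULL
superpose_xyz <- function(X, ref = NULL) {
  n <- ncol(X)
  if (is.null(ref)) {
    X1 <- bio3d::fit.xyz(X[1, ], X, fixed.inds = 1:n, mobile.inds = 1:n)
    ref <- colMeans(X1)
  }
  bio3d::fit.xyz(ref, X, fixed.inds = 1:n, mobile.inds = 1:n)
}

#' Calpha RMSD time series
#'
#' Root-mean-square deviation of each frame from a reference frame
#' after optimal rigid-body superposition.
#'
#' @param ens a [structure_ensemble()].
#' @param ref reference frame index (default 1).
#' @return numeric vector (Angstrom) per frame, >= 0.
#' @export
rmsd_series <- function(ens, ref = 1) {
  X <- ca_xyz(ens)
  n <- ncol(X)
  fitted <- bio3d::fit.xyz(X[ref, ], X, fixed.inds = 1:n, mobile.inds = 1:n)
  d2 <- sweep(fitted, 2, X[ref, ])^2
  sqrt(rowSums(d2) / (n / 3))
}

#' Calpha RMSF profile
#'
#' Per-node root-mean-square fluctuation about the mean structure after
#' ensemble superposition to the mean:
#' RMSF_i = sqrt(<|x_i - <x_i>|^2>).
#'
#' @param ens a [structure_ensemble()].
#' @param fit superpose to the mean first (default TRUE).
#' @return named numeric vector (Angstrom) per node.
#' @export
rmsf_profile <- function(ens, fit = TRUE) {
  X <- ca_xyz(ens)
  if (fit && nrow(X) > 1) X <- superpose_xyz(X)
  mu <- colMeans(X)
  d2 <- sweep(X, 2, mu)^2
  per_coord <- colMeans(d2)
  n <- ncol(X) / 3
  out <- sqrt(per_coord[seq(1, 3 * n, 3)] + per_coord[seq(2, 3 * n, 3)] +
              per_coord[seq(3, 3 * n, 3)])
  stats::setNames(out, node_table(ens)$node)
}

#' Essential dynamics: PCA of the positional covariance
#'
#' Diagonalizes the covariance matrix of the superposed Calpha
#' positions.  The essential subspace is the minimal set of leading
#' modes whose eigenvalues account for at least `variance` of the total
#' variance (default 90%).
#'
#' @param ens a [structure_ensemble()].
#' @param variance cumulative variance fraction defining the essential
#'   subspace (default 0.90).
#' @param fit superpose to the mean first (default TRUE).
#' @return an object of class `essential_subspace`: list with
#'   `values` (eigenvalues, Angstrom^2, descending), `vectors`
#'   (3n x modes, orthonormal), `n_modes` (retained count),
#'   `cum_variance` (fraction covered by the retained modes),
#'   `projections` (frames x modes), `trace`, `mean`.
#' @export
pca_ensemble <- function(ens, variance = 0.90, fit = TRUE) {
  X <- ca_xyz(ens)
  if (nrow(X) < 2) stop("PCA needs at least 2 frames")
  if (fit) X <- superpose_xyz(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  tr <- sum(diag(C))
  cum <- cumsum(vals) / sum(vals)
  n_modes <- which(cum >= variance)[1]
  structure(list(values = vals, vectors = e$vectors, n_modes = n_modes,
                 cum_variance = cum[n_modes],
                 projections = Xc %*% e$vectors, trace = tr, mean = mu),
            class = "essential_subspace")
}

#' @export
print.essential_subspace <- function(x, ...) {
  cat("Essential subspace:", x$n_modes, "modes covering",
      round(100 * x$cum_variance, 1), "% of the positional variance\n")
  cat("  total fluctuation (trace):", signif(x$trace, 5), "A^2\n")
  invisible(x)
}

#' Root-mean-square inner product of two essential subspaces
#'
#' RMSIP over the retained modes of the two subspaces (truncated to the
#' smaller mode count): sqrt( (1/D) sum_i sum_j (v_i . w_j)^2 ).
#' 1 for identical subspaces, 0 for orthogonal ones.
#'
#' @param es_a,es_b `essential_subspace` objects on the same atom set.
#' @return overlap in \[0,1\].
#' @export
subspace_overlap <- function(es_a, es_b) {
  d <- min(es_a$n_modes, es_b$n_modes)
  A <- es_a$vectors[, seq_len(d), drop = FALSE]
  B <- es_b$vectors[, seq_len(d), drop = FALSE]
  M <- crossprod(A, B)
  min(sqrt(sum(M^2) / d), 1)
}

#' Functional mode analysis
#'
#' Finds the collective mode maximally correlated with a scalar
#' structural observable by ordinary least squares of the observable on
#' the projections onto the first `n` principal components, and reports
#' the Pearson correlation between model and data both on the training
#' data and under k-fold cross-validation (a guard against overfitting
#' when many components are used).
#'
#' @param ens a [structure_ensemble()], or an `essential_subspace`
#'   already computed on it.
#' @param observable numeric vector, one value per frame (e.g. a SASA
#'   time series).
#' @param n number of principal components to use.
#' @param k_folds cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @return an object of class `fma_model`: list with `coefficients`
#'   (PC regression weights), `mode` (the maximally correlated
#'   collective direction, unit 3n vector), `fitted`, `r_train`,
#'   `r_cv`, `n`.
#' @export
fma <- function(ens, observable, n, k_folds = 5, seed = 1) {
  es <- if (inherits(ens, "essential_subspace")) ens else pca_ensemble(ens)
  P <- es$projections
  nf <- nrow(P)
  if (length(observable) != nf)
    stop("observable length (", length(observable),
         ") must equal the frame count (", nf, ")")
  if (n > ncol(P)) stop("n exceeds the ", ncol(P), " available modes")
  X <- P[, seq_len(n), drop = FALSE]
  df <- data.frame(y = observable, X)
  fit <- stats::lm(y ~ ., data = df)
  beta <- stats::coef(fit)[-1]
  beta[is.na(beta)] <- 0
  mode <- es$vectors[, seq_len(n), drop = FALSE] %*% beta
  nv <- sqrt(sum(mode^2))
  if (nv > 0) mode <- mode / nv
  r_train <- if (stats::sd(fit$fitted.values) == 0) 0 else
    stats::cor(fit$fitted.values, observable)
  # k-fold CV
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = nf))
  pred <- numeric(nf)
  for (k in seq_len(k_folds)) {
    te <- fold == k
    fk <- stats::lm(y ~ ., data = df[!te, , drop = FALSE])
    pred[te] <- stats::predict(fk, newdata = df[te, , drop = FALSE])
  }
  r_cv <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, observable)
  structure(list(coefficients = beta, mode = as.numeric(mode),
                 fitted = fit$fitted.values, r_train = r_train,
                 r_cv = r_cv, n = n),
            class = "fma_model")
}

#' @export
print.fma_model <- function(x, ...) {
  cat("Functional mode analysis on", x$n, "principal components\n")
  cat("  model-data correlation: r_train =", round(x$r_train, 3),
      ", r_cv =", round(x$r_cv, 3), "\n")
  invisible(x)
}
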